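# ChIP-qPCR / RT-qPCR quantification (delta-delta-Ct), spike-in antibody
# specificity, and the study's elementary statistics.

#' Simulate a qPCR plate
#'
#' Ct values follow `base_ct - log2(quantity) + N(0, noise_sd_ct)`. The
#' design table gives, per (locus, condition), the true input-relative
#' quantity and the IP/input enrichment ratio; IP rows get
#' `quantity * ip_over_input`.
#'
#' @param design `data.frame` with columns `locus`, `condition`,
#'   `quantity` (input-relative abundance) and `ip_over_input` (IP
#'   enrichment over input).
#' @param replicates Number of biological replicates.
#' @param noise_sd_ct Gaussian Ct noise SD in cycles (default 0).
#' @param seed Integer seed (required when `noise_sd_ct > 0`).
#' @param base_ct Baseline cycle threshold (default 25).
#' @param antibody Label for the assay/antibody column.
#' @return A `qpcr_plate` `data.frame` with columns `locus`, `channel`
#'   (`IP`/`input`), `antibody`, `condition`, `replicate`, `ct`.
#' @export
simulate_qpcr <- function(design, replicates, noise_sd_ct = 0, seed = NULL,
                          base_ct = 25, antibody = "H3K27me3") {
  stopifnot(all(c("locus", "condition", "quantity", "ip_over_input") %in%
                  names(design)))
  make_rows <- function() {
    rows <- lapply(seq_len(nrow(design)), function(i) {
      d <- design[i, ]
      do.call(rbind, lapply(seq_len(replicates), function(r) {
        noise <- if (noise_sd_ct > 0) stats::rnorm(2, sd = noise_sd_ct) else c(0, 0)
        data.frame(
          locus = d$locus, channel = c("input", "IP"), antibody = antibody,
          condition = d$condition, replicate = r,
          ct = c(base_ct - log2(d$quantity) + noise[1],
                 base_ct - log2(d$quantity * d$ip_over_input) + noise[2]),
          stringsAsFactors = FALSE
        )
      }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("qpcr_plate", class(out))
    out
  }
  if (noise_sd_ct > 0) run_seeded(seed, make_rows()) else make_rows()
}

#' Per-replicate normalized ChIP enrichment (delta-delta-Ct)
#'
#' For each replicate and condition, the IP/input quantity at a locus is
#' `2^(Ct_input - Ct_IP)`; the normalized enrichment is the target locus's
#' quantity divided by the internal-control locus's (e.g. H3K27me3 at the
#' reporter normalized to the constitutively marked ubx gene). Replicates
#' lacking a matched input row are dropped with a message.
#'
#' @param plate A `qpcr_plate`.
#' @param target_locus,control_locus Locus labels.
#' @param antibody Optional antibody/assay filter.
#' @return `data.frame` with `condition`, `replicate`, `enrichment`.
#' @export
ddct_enrichment <- function(plate, target_locus, control_locus,
                            antibody = NULL) {
  if (!is.null(antibody)) plate <- plate[plate$antibody == antibody, ]
  quantity <- function(locus, condition, replicate) {
    sel <- plate$locus == locus & plate$condition == condition &
      plate$replicate == replicate
    ip <- plate$ct[sel & plate$channel == "IP"]
    input <- plate$ct[sel & plate$channel == "input"]
    if (length(ip) != 1L || length(input) != 1L) return(NA_real_)
    2^(input - ip)
  }
  keys <- unique(plate[plate$locus == target_locus, c("condition", "replicate")])
  enr <- vapply(seq_len(nrow(keys)), function(i) {
    qt <- quantity(target_locus, keys$condition[i], keys$replicate[i])
    qc <- quantity(control_locus, keys$condition[i], keys$replicate[i])
    qt / qc
  }, numeric(1))
  keep <- !is.na(enr)
  if (any(!keep)) {
    message(sum(!keep), " replicate(s) dropped: missing matched IP/input rows")
  }
  out <- data.frame(condition = keys$condition[keep],
                    replicate = keys$replicate[keep],
                    enrichment = enr[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Percent change in enrichment between conditions
#'
#' Reports the loss (as a percentage) of the mean enrichment in the
#' `plus` condition relative to `minus`, with a two-sided ratio t-test:
#' a paired t-test on natural-log per-replicate ratios (`paired = TRUE`,
#' the "ratio paired t-test"), or Welch's unpaired t-test on logs.
#'
#' @param ratios_minus,ratios_plus Per-replicate enrichments for the
#'   reference (`minus`) and test (`plus`) conditions.
#' @param paired Paired replicates? (default `TRUE`).
#' @return An `enrichment_result` list: `mean_minus`, `mean_plus`,
#'   `percent_change` (positive = loss in `plus`), `p_value`, `method`.
#' @export
percent_change <- function(ratios_minus, ratios_plus, paired = TRUE) {
  stopifnot(all(ratios_minus > 0), all(ratios_plus > 0))
  mean_minus <- mean(ratios_minus)
  mean_plus <- mean(ratios_plus)
  if (paired) {
    stopifnot(length(ratios_minus) == length(ratios_plus))
    lr <- log(ratios_plus) - log(ratios_minus)
    p <- if (stats::sd(lr) == 0) 1 else stats::t.test(lr, mu = 0)$p.value
    method <- "two-sided paired t-test on log ratios"
  } else {
    a <- log(ratios_plus); b <- log(ratios_minus)
    p <- if (stats::sd(c(a, b)) == 0) 1 else
      stats::t.test(a, b, var.equal = FALSE)$p.value
    method <- "two-sided Welch t-test on log values"
  }
  structure(list(mean_minus = mean_minus, mean_plus = mean_plus,
                 percent_change = (1 - mean_plus / mean_minus) * 100,
                 p_value = p, method = method),
            class = "enrichment_result")
}

#' Spike-in antibody specificity
#'
#' Per barcoded nucleosome mark, recovery is the IP/input quantity
#' `2^(Ct_input - Ct_IP)`; specificity is each mark's recovery as a
#' percentage of the on-target mark's recovery. Marks without barcode rows
#' are reported absent (`NA`), not zero.
#'
#' @param plate `data.frame` with columns `mark`, `channel` (`IP`/`input`),
#'   `ct` (one spike-in barcode row per mark and channel).
#' @param on_target The antibody's nominal target mark (default
#'   `"H3K27me3"`).
#' @return `data.frame` with `mark`, `recovery`, `specificity_pct`.
#' @export
spikein_specificity <- function(plate, on_target = "H3K27me3") {
  marks <- unique(plate$mark)
  recovery <- vapply(marks, function(m) {
    ip <- plate$ct[plate$mark == m & plate$channel == "IP"]
    input <- plate$ct[plate$mark == m & plate$channel == "input"]
    if (length(ip) != 1L || length(input) != 1L) return(NA_real_)
    2^(input - ip)
  }, numeric(1))
  if (!on_target %in% marks || is.na(recovery[on_target])) {
    stop("on-target mark has no complete spike-in rows")
  }
  data.frame(mark = marks, recovery = unname(recovery),
             specificity_pct = unname(recovery / recovery[on_target] * 100),
             stringsAsFactors = FALSE)
}

#' Two-sided Pearson chi-square on a 2 x k table
#'
#' No continuity correction. Columns with a zero margin are pooled into
#' the nearest remaining column with a warning; a warning is also issued
#' when any expected count is below 1.
#'
#' @param counts 2 x k matrix of category counts.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_square_2xk <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 2L)
  zero_cols <- colSums(counts) == 0
  if (any(zero_cols)) {
    warning("zero-margin categories pooled: ",
            paste(which(zero_cols), collapse = ", "))
    counts <- counts[, !zero_cols, drop = FALSE]
  }
  if (ncol(counts) < 2L) {
    return(list(statistic = 0, df = 0L, p_value = 1))
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected < 1)) warning("expected cell count below 1")
  fit <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(fit$statistic), df = unname(fit$parameter),
       p_value = if (unname(fit$statistic) == 0) 1 else unname(fit$p.value))
}

#' Relative viability from cross counts
#'
#' `viability = (observed_test / observed_reference) / expected_ratio x
#' 100` — e.g. adult males carrying a mutant allele versus wild-type
#' siblings at an expected 1:1 Mendelian ratio.
#'
#' @param observed_test,observed_reference Offspring counts.
#' @param expected_ratio Expected test:reference ratio (default 1).
#' @return Percentage viability.
#' @export
relative_viability <- function(observed_test, observed_reference,
                               expected_ratio = 1) {
  if (observed_reference <= 0) stop("reference count must be positive")
  (observed_test / observed_reference) / expected_ratio * 100
}

#' Relative reduction between two viabilities
#' @param viability_a,viability_b Percent viabilities (a is the reduced one).
#' @return `(1 - a/b) x 100`.
#' @export
viability_reduction <- function(viability_a, viability_b) {
  (1 - viability_a / viability_b) * 100
}

#' RNAi knockdown level by 2^-ddCt
#'
#' Relative expression of `gene` versus a housekeeping gene, RNAi versus
#' control condition: `ddCt = (Ct_gene - Ct_hk)_RNAi - (Ct_gene -
#' Ct_hk)_control`; relative expression is `2^-ddCt` (per replicate,
#' averaged).
#'
#' @param plate `data.frame` with columns `gene`, `condition`, `replicate`,
#'   `ct` (expression plates have no IP/input split).
#' @param gene Target gene label.
#' @param housekeeping Internal-control gene label (e.g. tubulin).
#' @param control_condition,rnai_condition Condition labels.
#' @return List with `per_replicate` (vector of 2^-ddCt) and
#'   `relative_expression` (mean).
#' @export
knockdown_level <- function(plate, gene, housekeeping,
                            control_condition = "control",
                            rnai_condition = "RNAi") {
  dct <- function(condition, r) {
    g <- plate$ct[plate$gene == gene & plate$condition == condition &
                    plate$replicate == r]
    h <- plate$ct[plate$gene == housekeeping & plate$condition == condition &
                    plate$replicate == r]
    if (length(g) != 1L || length(h) != 1L) return(NA_real_)
    g - h
  }
  reps <- sort(unique(plate$replicate))
  per_rep <- vapply(reps, function(r) {
    2^(-(dct(rnai_condition, r) - dct(control_condition, r)))
  }, numeric(1))
  per_rep <- per_rep[!is.na(per_rep)]
  list(per_replicate = per_rep, relative_expression = mean(per_rep))
}

#' Write / read a qPCR plate as TSV
#' @param plate A `qpcr_plate`.
#' @param path TSV path.
#' @return `path` invisibly, or the plate.
#' @export
write_qpcr_tsv <- function(plate, path) {
  utils::write.table(plate, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_qpcr_tsv
#' @export
read_qpcr_tsv <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  class(out) <- c("qpcr_plate", class(out))
  out
}
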