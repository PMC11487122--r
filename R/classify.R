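# Pathway classification: the cut-proximity read filter and the HR / NHEJ /
# MMEJ class definitions applied to junction calls.

#' Classifier thresholds
#'
#' Defaults mirror the reporter assay's analysis settings: reads are kept
#' when their junction lies within 10 bp of the expected cut site; the HR
#' signature is the 23-nt deletion that removes the I-SceI site; NHEJ
#' covers indels up to 25 bp; MMEJ is a pure deletion with >= 2 bp of
#' junction microhomology.
#'
#' @param max_cut_distance Retention boundary for the cut-proximity filter
#'   (bp, inclusive).
#' @param hr_deletion_size HR-signature deletion length (bp).
#' @param nhej_max_indel Largest indel labelled NHEJ (bp).
#' @param mmej_min_mh Minimal microhomology for MMEJ (bp).
#' @param tide_indel_window Decomposition window for trace analysis (bp).
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(max_cut_distance = 10L,
                              hr_deletion_size = 23L,
                              nhej_max_indel = 25L,
                              mmej_min_mh = 2L,
                              tide_indel_window = 25L) {
  cfg <- list(max_cut_distance = as.integer(max_cut_distance),
              hr_deletion_size = as.integer(hr_deletion_size),
              nhej_max_indel = as.integer(nhej_max_indel),
              mmej_min_mh = as.integer(mmej_min_mh),
              tide_indel_window = as.integer(tide_indel_window))
  stopifnot(cfg$max_cut_distance >= 0L, cfg$hr_deletion_size > 0L,
            cfg$nhej_max_indel > 0L, cfg$mmej_min_mh > 0L,
            cfg$tide_indel_window > 0L)
  class(cfg) <- "classifier_config"
  cfg
}

#' Cut-proximity read filter
#'
#' Keeps unmodified calls and calls whose junction equivalence region lies
#' within `max_cut_distance` bp of the cut; drops unalignable reads. Events
#' far from the cut do not reflect I-SceI-induced repair and are excluded.
#'
#' @param calls `data.frame` of junction calls.
#' @param config A [classifier_config()].
#' @return The retained calls, with attributes `n_input`,
#'   `n_dropped_distance` and `n_dropped_unalignable`.
#' @export
apply_cut_filter <- function(calls, config = classifier_config()) {
  if (nrow(calls) == 0L) {
    out <- calls
    attr(out, "n_input") <- 0L
    attr(out, "n_dropped_distance") <- 0L
    attr(out, "n_dropped_unalignable") <- 0L
    return(out)
  }
  unalignable <- calls$call_class == "unalignable"
  keep <- !unalignable &
    (calls$call_class == "unmodified" |
       calls$distance_to_cut <= config$max_cut_distance)
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_input") <- nrow(calls)
  attr(out, "n_dropped_distance") <- sum(!keep & !unalignable)
  attr(out, "n_dropped_unalignable") <- sum(unalignable)
  out
}

#' Classify one junction call into a repair pathway
#'
#' HR: a pure deletion of the HR-signature length whose shift-equivalence
#' class contains the HR interval (the -23 product is HR by definition,
#' regardless of incidental microhomology). MMEJ: any other pure deletion
#' with microhomology >= `mmej_min_mh`. NHEJ: remaining insertions,
#' deletions and deletions-with-insert up to `nhej_max_indel`. Larger
#' indels are labelled `other` (excluded from the repaired set but kept
#' auditable); unmodified calls stay `unmodified`.
#'
#' @param call A `junction_call` row (retained by the cut filter).
#' @param config A [classifier_config()].
#' @param ref A `reference_construct`.
#' @return One of `"unmodified"`, `"hr"`, `"nhej"`, `"mmej"`, `"other"`.
#' @export
classify_call <- function(call, config = classifier_config(), ref) {
  cls <- call$call_class
  if (cls %in% c("unmodified", "unalignable")) return("unmodified")
  hr_start <- unname(ref$hr_deletion_interval["start"])
  if (cls == "deletion") {
    if (call$del_size == config$hr_deletion_size &&
        call$shift_start <= hr_start && hr_start < call$shift_end) {
      return("hr")
    }
    if (call$mh_length >= config$mmej_min_mh) return("mmej")
  }
  indel_size <- max(call$del_size, call$insert_size)
  if (indel_size <= config$nhej_max_indel) return("nhej")
  "other"
}

#' Classify a table of junction calls
#'
#' @param calls `data.frame` of junction calls (retained by the filter).
#' @param config A [classifier_config()].
#' @param ref A `reference_construct`.
#' @return `calls` with an added `pathway` column.
#' @export
classify_calls <- function(calls, config = classifier_config(), ref) {
  calls$pathway <- vapply(seq_len(nrow(calls)), function(i) {
    classify_call(calls[i, ], config, ref)
  }, character(1))
  calls
}

#' Summarise repair pathways
#'
#' Applies the cut filter, classifies retained calls, and tabulates counts,
#' percentages and histograms. Denominators: `pct_repaired` over retained
#' reads; `pct_hr_of_repaired` / `pct_nhej_of_repaired` /
#' `pct_mmej_of_repaired` over repaired (HR+NHEJ+MMEJ) reads;
#' `pct_mmej_of_deletions` over pure-deletion repair products.
#'
#' @param calls `data.frame` of junction calls (unfiltered).
#' @param config A [classifier_config()].
#' @param ref A `reference_construct`.
#' @return A `pathway_summary` list of counts, percentages and histograms.
#' @export
summarize_pathways <- function(calls, config = classifier_config(), ref) {
  retained <- apply_cut_filter(calls, config)
  classified <- classify_calls(retained, config, ref)
  n_total <- attr(retained, "n_input")
  n_unalignable <- attr(retained, "n_dropped_unalignable")
  tab <- table(factor(classified$pathway,
                      levels = c("unmodified", "hr", "nhej", "mmej", "other")))
  n_retained <- nrow(classified)
  n_repaired <- sum(tab[c("hr", "nhej", "mmej")])
  deletions <- classified[classified$call_class == "deletion" &
                            classified$pathway %in% c("hr", "nhej", "mmej"), ,
                          drop = FALSE]
  pure_dels <- classified[classified$call_class == "deletion" &
                            classified$pathway %in% c("nhej", "mmej"), ,
                          drop = FALSE]
  pct <- function(num, den) if (den > 0) num / den * 100 else 0
  del_hist <- table(deletions$del_size)
  mh_hist <- table(pure_dels$mh_length)
  out <- list(
    n_total = n_total,
    n_retained = n_retained,
    n_unalignable = n_unalignable,
    n_dropped_distance = attr(retained, "n_dropped_distance"),
    n_unmodified = unname(tab["unmodified"]),
    n_hr = unname(tab["hr"]),
    n_nhej = unname(tab["nhej"]),
    n_mmej = unname(tab["mmej"]),
    n_other = unname(tab["other"]),
    pct_repaired = pct(n_repaired, n_retained),
    pct_hr_of_repaired = pct(unname(tab["hr"]), n_repaired),
    pct_nhej_of_repaired = pct(unname(tab["nhej"]), n_repaired),
    pct_mmej_of_repaired = pct(unname(tab["mmej"]), n_repaired),
    pct_mmej_of_deletions = pct(nrow(pure_dels[pure_dels$pathway == "mmej", ]),
                                nrow(pure_dels)),
    deletion_size_histogram = del_hist,
    mh_histogram = mh_hist
  )
  class(out) <- "pathway_summary"
  out
}

#' @export
print.pathway_summary <- function(x, ...) {
  cat("Repair pathway summary\n")
  cat(sprintf("  reads: %d total, %d retained, %d unalignable, %d off-target\n",
              x$n_total, x$n_retained, x$n_unalignable, x$n_dropped_distance))
  cat(sprintf("  unmodified %d | HR %d | NHEJ %d | MMEJ %d | other %d\n",
              x$n_unmodified, x$n_hr, x$n_nhej, x$n_mmej, x$n_other))
  cat(sprintf("  %% repaired: %.1f; of repaired: HR %.1f%%, NHEJ %.1f%%, MMEJ %.1f%%\n",
              x$pct_repaired, x$pct_hr_of_repaired, x$pct_nhej_of_repaired,
              x$pct_mmej_of_repaired))
  cat(sprintf("  %% of pure deletions with >=2 bp microhomology: %.1f\n",
              x$pct_mmej_of_deletions))
  invisible(x)
}
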