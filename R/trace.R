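# TIDE-style trace decomposition: an aggregate per-position 4-channel
# signal downstream of the cut is modelled as a non-negative mixture of
# indel-shifted reference indicator profiles; the -23 component is the HR
# signature, other components up to +/-25 bp are NHEJ-type indels.

# 4-channel indicator profile (positions x A/C/G/T) of `sequence` starting
# at 0-based position `from`, for `npos` positions
indicator_profile <- function(sequence, from, npos) {
  bases <- strsplit(seq_sub(sequence, from, from + npos), "")[[1]]
  prof <- matrix(0, nrow = npos, ncol = 4,
                 dimnames = list(NULL, DNA_BASES))
  prof[cbind(seq_len(npos), match(bases, DNA_BASES))] <- 1
  prof
}

# profile downstream of the cut for an indel of signed size `offset`
# (negative = deletion, positive = insertion of unknown bases modelled as
# uniform 0.25 over the inserted stretch)
offset_profile <- function(ref, offset, npos) {
  cut <- ref$cut_index
  if (offset <= 0) {
    indicator_profile(ref$sequence, cut - offset, npos)
  } else {
    n_ins <- min(offset, npos)
    ins <- matrix(0.25, nrow = n_ins, ncol = 4,
                  dimnames = list(NULL, DNA_BASES))
    rest <- npos - n_ins
    if (rest > 0) {
      rbind(ins, indicator_profile(ref$sequence, cut, rest))
    } else {
      ins
    }
  }
}

#' Build the library of indel-shifted candidate profiles
#'
#' One candidate per signed indel size in `-window..window`; deletions
#' remove bases at the cut, insertions prepend ambiguity-averaged (0.25 per
#' channel) positions. The `-23` candidate equals the HR-product profile.
#'
#' @param ref A `reference_construct`.
#' @param window Decomposition half-width in bp (default 25).
#' @param npos Number of downstream positions; defaults to the largest grid
#'   on which every candidate is defined.
#' @return A `shift_library`: list with `profiles` (named list of
#'   position-by-channel matrices), `offsets`, `npos`.
#' @export
build_shift_library <- function(ref, window = 25L, npos = NULL) {
  cut <- ref$cut_index
  max_npos <- nchar(ref$sequence) - cut - window
  if (is.null(npos)) npos <- max_npos
  stopifnot(npos >= 1, npos <= max_npos)
  offsets <- seq.int(-window, window)
  profiles <- lapply(offsets, offset_profile, ref = ref, npos = npos)
  names(profiles) <- as.character(offsets)
  structure(list(profiles = profiles, offsets = offsets, npos = npos,
                 window = as.integer(window)),
            class = "shift_library")
}

#' Simulate an aggregate sequencing trace
#'
#' Weighted sum of indel-shifted reference profiles plus Gaussian channel
#' noise — a proxy for the averaged Sanger chromatogram of a pool of repair
#' products.
#'
#' @param weights Named numeric vector: signed indel offset -> weight
#'   (non-negative, summing to <= 1; e.g. `c("0" = 0.7, "-23" = 0.3)`).
#' @param ref A `reference_construct`.
#' @param window Half-width used for the position grid (default 25).
#' @param noise_sd Gaussian noise SD per channel (default 0).
#' @param seed Integer seed; required when `noise_sd > 0`.
#' @return A `trace_profile`: list with `positions` (0-based offsets
#'   downstream of the cut) and `signal` (positions x 4 channel matrix).
#' @export
simulate_trace <- function(weights, ref, window = 25L, noise_sd = 0,
                           seed = NULL) {
  w <- as.numeric(weights)
  if (any(w < 0)) stop("trace weights must be non-negative")
  if (sum(w) > 1 + 1e-9) stop("trace weights must sum to <= 1")
  lib <- build_shift_library(ref, window)
  signal <- matrix(0, nrow = lib$npos, ncol = 4,
                   dimnames = list(NULL, DNA_BASES))
  for (i in seq_along(weights)) {
    off <- names(weights)[i]
    if (!off %in% names(lib$profiles)) {
      stop("offset outside decomposition window: ", off)
    }
    signal <- signal + w[i] * lib$profiles[[off]]
  }
  if (noise_sd > 0) {
    signal <- run_seeded(seed, {
      signal + matrix(stats::rnorm(length(signal), sd = noise_sd),
                      nrow = nrow(signal))
    })
  }
  structure(list(positions = seq_len(lib$npos) - 1L, signal = signal),
            class = "trace_profile")
}

#' Decompose a trace over the shift library
#'
#' Solves `min || signal - sum_d w_d * candidate_d ||^2` subject to
#' `w_d >= 0` (Lawson-Hanson non-negative least squares). Weights below
#' 0.1% of the total are zeroed and the remainder renormalized; R-squared
#' is computed from the unpruned fit.
#'
#' @param trace A `trace_profile`.
#' @param library A `shift_library` on the same position grid.
#' @return A `decomposition_result`: list with `weights` (named by signed
#'   offset), `r_squared`, `total_editing` (= 1 - weight at offset 0).
#' @export
decompose_trace <- function(trace, library) {
  b <- as.vector(trace$signal)
  if (all(b == 0)) stop("empty trace")
  stopifnot(nrow(trace$signal) == library$npos)
  A <- vapply(library$profiles, as.vector, numeric(length(b)))
  fit <- pracma::lsqnonneg(A, b)
  w <- stats::setNames(fit$x, names(library$profiles))
  rss <- fit$resid.norm
  tss <- sum((b - mean(b))^2)
  r2 <- if (tss > 0) max(0, min(1, 1 - rss / tss)) else 1
  total <- sum(w)
  if (total > 0) {
    w[w < 0.001 * total] <- 0
    w <- w / sum(w)
  }
  structure(list(weights = w, r_squared = r2,
                 total_editing = unname(1 - w["0"])),
            class = "decomposition_result")
}

#' Indel spectrum report from a decomposition
#'
#' The -23 component is the HR signature; all other edited components are
#' NHEJ-type. Percentages are of total editing.
#'
#' @param result A `decomposition_result`.
#' @param hr_offset Signed offset of the HR signature (default -23).
#' @return List with `pct_hr`, `pct_nhej`, `pct_total_edited`.
#' @export
spectrum_report <- function(result, hr_offset = -23L) {
  total <- result$total_editing
  if (total <= 0) {
    return(list(pct_hr = 0, pct_nhej = 0, pct_total_edited = 0))
  }
  w_hr <- unname(result$weights[as.character(hr_offset)])
  if (is.na(w_hr)) w_hr <- 0
  list(pct_hr = w_hr / total * 100,
       pct_nhej = max(0, total - w_hr) / total * 100,
       pct_total_edited = total * 100)
}

#' Write / read a trace profile as TSV (position, A, C, G, T)
#' @param trace A `trace_profile`.
#' @param path TSV path.
#' @return `path` invisibly, or the `trace_profile`.
#' @export
write_trace_tsv <- function(trace, path) {
  df <- data.frame(position = trace$positions, trace$signal)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_tsv
#' @export
read_trace_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  signal <- as.matrix(df[, DNA_BASES])
  dimnames(signal) <- list(NULL, DNA_BASES)
  structure(list(positions = df$position, signal = signal),
            class = "trace_profile")
}
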