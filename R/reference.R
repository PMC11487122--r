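#' Anchor and primer sequences of the DR-white reporter amplicon
#'
#' The left/right flank sequences jointly compose the 18-bp I-SceI
#' recognition site and define the cut coordinate; the primers delimit the
#' PCR amplicon used to genotype repair products.
#'
#' @format Named character vector with elements `left_flank`, `right_flank`,
#'   `left_primer`, `right_primer`.
#' @export
drwhite_anchors <- c(
  left_flank   = "TTGAGCTGTAGGGATAA",
  right_flank  = "CAGGGTAATAGCTCTTTG",
  left_primer  = "GACTGGACTCATTTACCGCCC",
  right_primer = "TTGGTAGGACACTGGGCAC"
)

# length of the HR-signature deletion: loss of the I-SceI site scores as a
# 23-nt deletion relative to the uncut reporter
HR_DELETION_SIZE <- 23L
# placement of the 23-nt window around the cut: [cut-9, cut+14) keeps the
# full 18-nt recognition site (last 9 nt of the left flank + first 9 nt of
# the right flank) inside the deleted window
HR_WINDOW_LEFT <- 9L

new_reference_construct <- function(sequence, cut_index, hr_start, hr_end,
                                    anchors = drwhite_anchors) {
  structure(
    list(
      sequence = sequence,
      cut_index = as.integer(cut_index),
      hr_deletion_interval = c(start = as.integer(hr_start),
                               end = as.integer(hr_end)),
      left_flank = unname(anchors["left_flank"]),
      right_flank = unname(anchors["right_flank"]),
      left_primer = unname(anchors["left_primer"]),
      right_primer = unname(anchors["right_primer"])
    ),
    class = "reference_construct"
  )
}

#' Build a synthetic DR-white reporter amplicon
#'
#' Assembles `left_primer + arm + left_flank + right_flank + arm +
#' revcomp(right_primer)` with random arms of length `arm_length`. The cut
#' index sits at the boundary between the two flanks (the I-SceI cleavage
#' position), and the HR-signature deletion interval is the 23-nt window
#' `[cut - 9, cut + 14)`, which contains the whole 18-nt recognition site.
#' Random arms are resampled until neither flank occurs in them, so each
#' flank occurs exactly once in the amplicon.
#'
#' @param arm_length Length in bp of each random arm (>= 30).
#' @param seed Integer seed; required, every construct is a pure function of
#'   `(arm_length, seed)`.
#' @return A `reference_construct`: list with `sequence`, `cut_index`
#'   (0-based inter-base), `hr_deletion_interval` (0-based half-open),
#'   flank and primer sequences.
#' @examples
#' ref <- build_reference(arm_length = 50, seed = 1)
#' substr(ref$sequence, ref$cut_index - 8, ref$cut_index + 9) # I-SceI site
#' @export
build_reference <- function(arm_length, seed) {
  if (arm_length < 30) stop("arm_length must be >= 30")
  run_seeded(seed, {
    anchors <- drwhite_anchors
    flanks <- anchors[c("left_flank", "right_flank")]
    sample_arm <- function() {
      for (i in seq_len(100L)) {
        arm <- random_dna(arm_length)
        if (!any(vapply(flanks, grepl, logical(1), x = arm, fixed = TRUE))) {
          return(arm)
        }
      }
      stop("could not sample a flank-free arm in 100 attempts")
    }
    ref <- NULL
    for (attempt in seq_len(100L)) {
      arm1 <- sample_arm()
      arm2 <- sample_arm()
      sequence <- paste0(anchors["left_primer"], arm1, anchors["left_flank"],
                         anchors["right_flank"], arm2,
                         revcomp(anchors["right_primer"]))
      cut_index <- nchar(anchors["left_primer"]) + arm_length +
        nchar(anchors["left_flank"])
      cand <- new_reference_construct(
        sequence, cut_index,
        hr_start = cut_index - HR_WINDOW_LEFT,
        hr_end = cut_index - HR_WINDOW_LEFT + HR_DELETION_SIZE,
        anchors = anchors
      )
      # junction-spanning flank copies are possible even with flank-free
      # arms; retry the assembly if full validation fails
      ok <- tryCatch({validate_reference(cand); TRUE},
                     error = function(e) FALSE)
      if (ok) { ref <- cand; break }
    }
    if (is.null(ref)) stop("could not assemble a valid amplicon in 100 attempts")
    ref
  })
}

validate_reference <- function(ref) {
  stopifnot(inherits(ref, "reference_construct"))
  hr <- ref$hr_deletion_interval
  stopifnot(hr["end"] - hr["start"] == HR_DELETION_SIZE,
            hr["start"] <= ref$cut_index, ref$cut_index < hr["end"])
  if (count_occurrences(ref$left_flank, ref$sequence) != 1L ||
      count_occurrences(ref$right_flank, ref$sequence) != 1L) {
    stop("flanks must each occur exactly once in the amplicon")
  }
  lf_end <- regexpr(ref$left_flank, ref$sequence, fixed = TRUE)[1] - 1L +
    nchar(ref$left_flank)
  rf_start <- regexpr(ref$right_flank, ref$sequence, fixed = TRUE)[1] - 1L
  stopifnot(lf_end == ref$cut_index, rf_start == ref$cut_index)
  stopifnot(startsWith(ref$sequence, ref$left_primer),
            endsWith(ref$sequence, revcomp(ref$right_primer)))
  invisible(ref)
}

#' @export
print.reference_construct <- function(x, ...) {
  cat("DR-white reference construct\n")
  cat("  amplicon length:", nchar(x$sequence), "nt\n")
  cat("  cut index (0-based, inter-base):", x$cut_index, "\n")
  cat(sprintf("  HR deletion interval: [%d, %d)\n",
              x$hr_deletion_interval["start"], x$hr_deletion_interval["end"]))
  invisible(x)
}

#' Write / read a reference construct as FASTA
#'
#' The cut index and HR interval are stored in the FASTA header so the
#' construct round-trips through the file.
#'
#' @param ref A `reference_construct`.
#' @param path FASTA file path.
#' @return `write_reference_fasta` returns `path` invisibly;
#'   `read_reference_fasta` returns the `reference_construct`.
#' @export
write_reference_fasta <- function(ref, path) {
  header <- sprintf("drwhite_amplicon cut=%d hr=%d-%d", ref$cut_index,
                    ref$hr_deletion_interval["start"],
                    ref$hr_deletion_interval["end"])
  dna <- Biostrings::DNAStringSet(ref$sequence)
  names(dna) <- header
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  header <- names(dna)[1]
  cut <- as.integer(sub(".*cut=(\\d+).*", "\\1", header))
  hr_start <- as.integer(sub(".*hr=(\\d+)-\\d+.*", "\\1", header))
  hr_end <- as.integer(sub(".*hr=\\d+-(\\d+).*", "\\1", header))
  new_reference_construct(as.character(dna[[1]]), cut, hr_start, hr_end)
}
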