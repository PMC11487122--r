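# Internal helpers. All genomic coordinates in this package are 0-based,
# half-open [start, end); the cut site is an inter-base index.

#' @importFrom withr with_seed
run_seeded <- function(seed, expr) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("a seed is required (reproducibility contract)", call. = FALSE)
  }
  seed <- as.integer(seed)
  withr::with_seed(seed, expr)
}

# substring in 0-based half-open coordinates
seq_sub <- function(x, start, end) {
  if (start >= end) return("")
  substr(x, start + 1L, end)
}

seq_len_nt <- function(x) nchar(x)

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

count_occurrences <- function(pattern, subject) {
  length(gregexpr(pattern, subject, fixed = TRUE)[[1]]) -
    (gregexpr(pattern, subject, fixed = TRUE)[[1]][1] == -1L)
}

# apply a deletion + insertion to a sequence (0-based, half-open interval)
apply_indel <- function(sequence, del_start, del_end, insert_seq = "") {
  paste0(seq_sub(sequence, 0L, del_start), insert_seq,
         seq_sub(sequence, del_end, nchar(sequence)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
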