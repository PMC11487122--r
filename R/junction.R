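# Junction calling: anchor each read on primer-proximal 15-mers outside the
# HR-deletion window, compare the inter-anchor segment against the
# reference, and reduce any single indel to its left-aligned placement with
# microhomology (placement-ambiguity) length.

ANCHOR_LENGTH <- 15L
# gap between the HR window edge and the anchor, so deletions up to ~30 bp
# and junctions up to ~20 bp from the cut stay between the anchors
ANCHOR_BUFFER <- 12L

anchor_coords <- function(ref) {
  hr <- ref$hr_deletion_interval
  left_end <- unname(hr["start"]) - ANCHOR_BUFFER
  right_start <- unname(hr["end"]) + ANCHOR_BUFFER
  list(
    left = c(start = left_end - ANCHOR_LENGTH, end = left_end),
    right = c(start = right_start, end = right_start + ANCHOR_LENGTH)
  )
}

#' Locate the anchor sequences of a read
#'
#' Anchors are 15-mers taken from the reference just outside the 23-nt
#' HR-deletion window (the printed SIQ flank sequences compose the I-SceI
#' site itself, which HR deletes, so anchoring on them would lose every HR
#' product). The rightmost match of the left anchor and the leftmost match
#' of the right anchor are used; up to one mismatch is tolerated per anchor.
#'
#' @param read Read sequence (character).
#' @param ref A `reference_construct`.
#' @return List with `left_end` (0-based end of the left anchor in the
#'   read), `right_start` (0-based start of the right anchor), and the
#'   matching reference coordinates, or `NULL` when either anchor is absent
#'   (the read is unalignable).
#' @export
anchor_read <- function(read, ref) {
  ac <- anchor_coords(ref)
  left_anchor <- seq_sub(ref$sequence, ac$left["start"], ac$left["end"])
  right_anchor <- seq_sub(ref$sequence, ac$right["start"], ac$right["end"])
  subject <- Biostrings::DNAString(read)
  find <- function(anchor) {
    hits <- Biostrings::matchPattern(anchor, subject, max.mismatch = 1L)
    if (length(hits) == 0L) return(NULL)
    # prefer exact hits over 1-mismatch hits
    exact <- Biostrings::matchPattern(anchor, subject, max.mismatch = 0L)
    if (length(exact) > 0L) exact else hits
  }
  lh <- find(left_anchor)
  rh <- find(right_anchor)
  if (is.null(lh) || is.null(rh)) return(NULL)
  left_end <- max(Biostrings::end(lh))        # rightmost, 1-based end
  right_start <- min(Biostrings::start(rh))   # leftmost, 1-based start
  if (right_start - 1L < left_end) return(NULL)
  list(
    left_end = left_end,                       # == 0-based half-open end
    right_start = right_start - 1L,            # 0-based start
    ref_left_end = unname(ac$left["end"]),
    ref_right_start = unname(ac$right["start"])
  )
}

#' Construct a junction call record
#'
#' One row describing a read's repair outcome in reference coordinates
#' (0-based, half-open). `shift_range` is the interval of equivalent
#' left-aligned-to-rightmost deletion start positions; its length is
#' `mh_length + 1` for deletions.
#'
#' @param read_id Read identifier.
#' @param call_class One of `unmodified`, `deletion`, `insertion`,
#'   `del_with_insert`, `unalignable`.
#' @param del_start,del_end Deletion interval (left-aligned), or `NA`.
#' @param insert_seq Inserted sequence (empty string if none).
#' @param mh_length Microhomology (placement ambiguity) length in bp.
#' @param shift_start,shift_end Half-open interval of equivalent deletion
#'   (or insertion-point) start positions.
#' @param distance_to_cut Minimal gap in bp between the indel's
#'   equivalence region and the cut index (0 when touching).
#' @return A one-row `data.frame` of class `junction_call`.
#' @export
junction_call <- function(read_id, call_class,
                          del_start = NA_integer_, del_end = NA_integer_,
                          insert_seq = "", mh_length = 0L,
                          shift_start = NA_integer_, shift_end = NA_integer_,
                          distance_to_cut = 0L) {
  stopifnot(call_class %in% c("unmodified", "deletion", "insertion",
                              "del_with_insert", "unalignable"))
  del_size <- if (is.na(del_start)) 0L else as.integer(del_end - del_start)
  out <- data.frame(
    read_id = as.character(read_id), call_class = call_class,
    del_start = as.integer(del_start), del_end = as.integer(del_end),
    del_size = del_size, insert_seq = insert_seq,
    insert_size = nchar(insert_seq), mh_length = as.integer(mh_length),
    shift_start = as.integer(shift_start), shift_end = as.integer(shift_end),
    distance_to_cut = as.integer(distance_to_cut),
    stringsAsFactors = FALSE
  )
  class(out) <- c("junction_call", class(out))
  out
}

longest_common_prefix <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- utf8ToInt(a)[seq_len(n)]
  bv <- utf8ToInt(b)[seq_len(n)]
  mism <- which(av != bv)
  if (length(mism) == 0L) n else mism[1] - 1L
}

longest_common_suffix <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- rev(utf8ToInt(a))[seq_len(n)]
  bv <- rev(utf8ToInt(b))[seq_len(n)]
  mism <- which(av != bv)
  if (length(mism) == 0L) n else mism[1] - 1L
}

#' Microhomology length of a deletion
#'
#' The maximal `m >= 0` with `ref[s, s+m) == ref[e, e+m)` for the
#' left-aligned placement `[s, e)` — equivalently, the number of
#' alternative placements of the same deletion that produce an identical
#' repaired sequence (the junction is `m`-fold ambiguous, `m + 1`
#' placements in total). The interval is left-aligned internally, so every
#' placement in the same equivalence class reports the same length.
#'
#' @param ref A `reference_construct` or plain sequence string.
#' @param del_start,del_end Deletion interval, 0-based half-open.
#' @return Integer microhomology length in bp.
#' @examples
#' microhomology_length("ACGTACGTAC", 2, 6)  # 4
#' @export
microhomology_length <- function(ref, del_start, del_end) {
  sequence <- if (inherits(ref, "reference_construct")) ref$sequence else ref
  n <- nchar(sequence)
  if (del_start < 0 || del_end > n || del_start >= del_end) {
    stop("deletion interval out of bounds")
  }
  la <- left_align_deletion(sequence, del_start, del_end)
  la$mh_length
}

# slide a deletion to its leftmost equivalent placement and measure the
# ambiguity run; returns left-aligned [start, end), mh, and shift range of
# equivalent start positions [shift_start, shift_end)
left_align_deletion <- function(sequence, del_start, del_end) {
  chars <- strsplit(sequence, "")[[1]]
  s <- del_start; e <- del_end
  while (s > 0L && chars[s] == chars[e]) { # chars[] is 1-based: ref[s-1]==ref[e-1]
    s <- s - 1L; e <- e - 1L
  }
  n <- nchar(sequence)
  m <- 0L
  while (s + m < n && e + m < n && chars[s + m + 1L] == chars[e + m + 1L]) {
    m <- m + 1L
  }
  # when e + m hits the sequence end the run may continue conceptually, but
  # placements beyond the sequence are not realizable; m counts realizable
  # alternative placements only if s+k, e+k stay in range, which the loop
  # enforces
  list(del_start = s, del_end = e, mh_length = m,
       shift_start = s, shift_end = s + m + 1L)
}

# distance between an equivalence region [a, b] (closed, in cut coords) and
# the cut index; 0 when the region contains or touches the cut
region_gap <- function(a, b, cut) {
  if (a <= cut && cut <= b) 0L else if (b < cut) cut - b else a - cut
}

#' Distance from a junction call to the expected cut site
#'
#' Uses the indel's whole shift-equivalence region (the union of all
#' equivalent placements), not just the left-aligned point, so a
#' microhomology-shiftable junction near the cut is retained regardless of
#' alignment convention. Returns 0 when the region contains or touches the
#' cut index.
#'
#' @param call A `junction_call` row.
#' @param ref A `reference_construct`.
#' @return Distance in bp (0 for unmodified reads).
#' @export
distance_to_cut <- function(call, ref) {
  cut <- ref$cut_index
  cls <- call$call_class
  if (cls %in% c("unmodified", "unalignable")) return(0L)
  if (cls == "deletion") {
    # union of placements [k, k + d) for k in [shift_start, shift_end - 1]
    a <- call$shift_start
    b <- call$shift_end - 1L + call$del_size
    return(region_gap(a, b, cut))
  }
  if (cls == "insertion") {
    return(region_gap(call$shift_start, call$shift_end - 1L, cut))
  }
  region_gap(call$del_start, call$del_end, cut)  # del_with_insert: fixed
}

#' Call the repair junction of an anchored read
#'
#' Compares the read's inter-anchor segment with the reference segment.
#' A pure length deficit explained by matching flanks is a deletion
#' (left-aligned, with microhomology); a pure excess is an insertion; a
#' mixed difference is a deletion-with-insert; identical segments are
#' unmodified. Reads whose anchors cannot be located are `unalignable`.
#'
#' @param read Read sequence (character).
#' @param ref A `reference_construct`.
#' @param read_id Identifier carried into the call.
#' @return A `junction_call` row (see [junction_call()]).
#' @export
call_junction <- function(read, ref, read_id = "read") {
  anc <- anchor_read(read, ref)
  if (is.null(anc)) {
    return(junction_call(read_id, "unalignable"))
  }
  read_seg <- seq_sub(read, anc$left_end, anc$right_start)
  ref_left <- anc$ref_left_end
  ref_seg <- seq_sub(ref$sequence, ref_left, anc$ref_right_start)
  n_read <- nchar(read_seg)
  n_ref <- nchar(ref_seg)

  if (n_read == n_ref && read_seg == ref_seg) {
    return(junction_call(read_id, "unmodified"))
  }
  p <- longest_common_prefix(read_seg, ref_seg)
  s <- longest_common_suffix(read_seg, ref_seg)

  if (n_read < n_ref && p + s >= n_read) {
    # pure deletion; left-align within the whole reference for a placement
    # choice independent of the anchor window
    d <- n_ref - n_read
    k <- max(0L, n_read - s)              # leftmost split inside the segment
    la <- left_align_deletion(ref$sequence, ref_left + k, ref_left + k + d)
    call <- junction_call(read_id, "deletion",
                          del_start = la$del_start, del_end = la$del_end,
                          mh_length = la$mh_length,
                          shift_start = la$shift_start,
                          shift_end = la$shift_end)
    call$distance_to_cut <- distance_to_cut(call, ref)
    return(call)
  }
  if (n_read > n_ref && p + s >= n_ref) {
    # pure insertion; insertion point ambiguous over [n_ref - s, p]
    i <- n_read - n_ref
    k_min <- max(0L, n_ref - s)
    k_max <- min(p, n_ref)
    ins <- seq_sub(read_seg, k_min, k_min + i)
    call <- junction_call(read_id, "insertion",
                          insert_seq = ins, mh_length = 0L,
                          shift_start = ref_left + k_min,
                          shift_end = ref_left + k_max + 1L)
    call$distance_to_cut <- distance_to_cut(call, ref)
    return(call)
  }
  # mixed difference: deleted reference block plus inserted read block
  del_a <- p
  del_b <- n_ref - s
  ins <- seq_sub(read_seg, p, n_read - s)
  call <- junction_call(read_id, "del_with_insert",
                        del_start = ref_left + del_a,
                        del_end = ref_left + del_b,
                        insert_seq = ins, mh_length = 0L,
                        shift_start = ref_left + del_a,
                        shift_end = ref_left + del_a + 1L)
  call$distance_to_cut <- distance_to_cut(call, ref)
  call
}

#' Call junctions for a set of reads
#'
#' @param reads Named character vector of read sequences (names become
#'   read ids) or a `DNAStringSet`.
#' @param ref A `reference_construct`.
#' @return A `data.frame` with one `junction_call` row per read.
#' @export
call_junctions <- function(reads, ref) {
  if (methods::is(reads, "DNAStringSet")) {
    nm <- names(reads) %||% as.character(seq_along(reads))
    reads <- stats::setNames(as.character(reads), nm)
  }
  if (is.null(names(reads))) names(reads) <- as.character(seq_along(reads))
  rows <- lapply(names(reads), function(id) {
    call_junction(reads[[id]], ref, read_id = id)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
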