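# Repair-event sampling: multinomial draws over outcome classes with
# junction geometry (placement, microhomology) realized against a concrete
# reference construct.

EVENT_CLASSES <- c("uncut", "hr", "nhej_deletion", "nhej_insertion",
                   "nhej_del_with_insert", "mmej_deletion")

#' Default repair-outcome mixture
#'
#' Proportions follow the reporter's typical pathway split (HR 20%, NHEJ
#' 75%, MMEJ 5% of repair products). Within NHEJ, 99.3% of products carry a
#' deletion — 99.1% pure deletions plus 0.2% deletions-with-insert — and
#' deletion sizes are geometric with P(1 bp) = 0.6, truncated at 25 bp, so
#' 1-bp deletions dominate. Insertions are 1-3 bp.
#'
#' @param hr,nhej,mmej,uncut Class proportions; must sum to 1.
#' @param deletion_fraction_within_nhej Fraction of NHEJ products that are
#'   pure deletions plus deletions-with-insert (default 0.993).
#' @return An `event_mixture` list with `proportions` (over the six event
#'   classes), `nhej_del_size_probs` and `nhej_ins_size_probs`.
#' @export
default_event_mixture <- function(hr = 0.20, nhej = 0.75, mmej = 0.05,
                                  uncut = 0,
                                  deletion_fraction_within_nhej = 0.993) {
  stopifnot(abs(hr + nhej + mmej + uncut - 1) < 1e-9)
  # split the non-pure-deletion NHEJ mass: most of the remainder is
  # insertions, a sliver is deletion-with-insert (itself deletion-containing)
  p_del <- deletion_fraction_within_nhej - 0.002
  p_dwi <- 0.002
  p_ins <- 1 - p_del - p_dwi
  sizes <- 1:25
  del_probs <- 0.6 * 0.4^(sizes - 1)
  del_probs <- del_probs / sum(del_probs)
  ins_probs <- c(0.7, 0.2, 0.1)  # 1-3 bp insertions
  mixture <- list(
    proportions = c(uncut = uncut, hr = hr,
                    nhej_deletion = nhej * p_del,
                    nhej_insertion = nhej * p_ins,
                    nhej_del_with_insert = nhej * p_dwi,
                    mmej_deletion = mmej),
    nhej_del_size_probs = stats::setNames(del_probs, sizes),
    nhej_ins_size_probs = stats::setNames(ins_probs, 1:3)
  )
  class(mixture) <- "event_mixture"
  mixture
}

check_mixture <- function(mixture) {
  stopifnot(inherits(mixture, "event_mixture"))
  p <- mixture$proportions
  if (abs(sum(p) - 1) > 1e-9) stop("mixture proportions must sum to 1")
  if (any(p < 0)) stop("mixture proportions must be non-negative")
  stopifnot(all(names(p) %in% EVENT_CLASSES))
  invisible(mixture)
}

# place a deletion of given size overlapping the cut and left-align it;
# accept only placements whose microhomology satisfies `mh_test`
place_deletion <- function(ref, size, mh_test, max_tries = 200L) {
  cut <- ref$cut_index
  for (i in seq_len(max_tries)) {
    start <- sample(seq.int(cut - size, cut), 1L)
    la <- left_align_deletion(ref$sequence, start, start + size)
    if (mh_test(la$mh_length) && !is_hr_equivalent(ref, la)) {
      return(la)
    }
  }
  NULL
}

is_hr_equivalent <- function(ref, la) {
  hr <- ref$hr_deletion_interval
  (la$del_end - la$del_start) == (hr["end"] - hr["start"]) &&
    la$shift_start <= hr["start"] && hr["start"] < la$shift_end
}

#' Sample repair events against a reference
#'
#' Draws `n` event classes from the mixture and realizes each as a concrete
#' junction on the reference: HR events delete the 23-nt HR interval; NHEJ
#' deletions are placed overlapping the cut and rejection-sampled to <= 1 bp
#' microhomology after left-alignment; MMEJ deletions are rejection-sampled
#' to >= 2 bp microhomology; insertions add 1-3 random bases at the cut.
#'
#' @param mixture An `event_mixture` (see [default_event_mixture()]).
#' @param ref A `reference_construct`.
#' @param n Number of events (>= 1).
#' @param seed Integer seed (required).
#' @return `data.frame` with columns `event_id`, `event_class`,
#'   `del_start`, `del_end` (0-based half-open, left-aligned; `NA` if no
#'   deletion), `insert_seq`, `mh_length`.
#' @export
sample_events <- function(mixture, ref, n, seed) {
  check_mixture(mixture)
  stopifnot(n >= 1)
  run_seeded(seed, {
    classes <- sample(names(mixture$proportions), n, replace = TRUE,
                      prob = mixture$proportions)
    del_sizes <- as.integer(names(mixture$nhej_del_size_probs))
    ins_sizes <- as.integer(names(mixture$nhej_ins_size_probs))
    hr <- ref$hr_deletion_interval
    rows <- lapply(seq_len(n), function(i) {
      cls <- classes[i]
      del_start <- NA_integer_; del_end <- NA_integer_
      insert_seq <- ""; mh <- 0L
      if (cls == "hr") {
        del_start <- unname(hr["start"]); del_end <- unname(hr["end"])
        mh <- microhomology_length(ref, del_start, del_end)
      } else if (cls == "nhej_deletion") {
        la <- NULL
        while (is.null(la)) {
          size <- sample(del_sizes, 1L, prob = mixture$nhej_del_size_probs)
          la <- place_deletion(ref, size, function(m) m <= 1L)
        }
        del_start <- la$del_start; del_end <- la$del_end; mh <- la$mh_length
      } else if (cls == "mmej_deletion") {
        la <- NULL
        while (is.null(la)) {
          size <- sample(4:25, 1L)
          la <- place_deletion(ref, size, function(m) m >= 2L)
        }
        del_start <- la$del_start; del_end <- la$del_end; mh <- la$mh_length
      } else if (cls == "nhej_insertion") {
        size <- sample(ins_sizes, 1L, prob = mixture$nhej_ins_size_probs)
        insert_seq <- random_dna(size)
      } else if (cls == "nhej_del_with_insert") {
        size <- sample(1:10, 1L)
        start <- sample(seq.int(ref$cut_index - size, ref$cut_index), 1L)
        del_start <- start; del_end <- start + size
        ins_size <- sample(1:3, 1L)
        repeat {
          insert_seq <- random_dna(ins_size)
          # avoid inserts that exactly restore the deleted bases
          if (insert_seq != seq_sub(ref$sequence, del_start,
                                    del_start + ins_size)) break
        }
      }
      data.frame(event_id = sprintf("event_%05d", i), event_class = cls,
                 del_start = del_start, del_end = del_end,
                 insert_seq = insert_seq, mh_length = mh,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Reconstruct the repaired amplicon of an event
#'
#' @param event One row of the table returned by [sample_events()].
#' @param ref A `reference_construct`.
#' @return Character: the repaired amplicon sequence.
#' @export
event_to_sequence <- function(event, ref) {
  sequence <- ref$sequence
  if (!is.na(event$del_start)) {
    apply_indel(sequence, event$del_start, event$del_end, event$insert_seq)
  } else if (nzchar(event$insert_seq)) {
    apply_indel(sequence, ref$cut_index, ref$cut_index, event$insert_seq)
  } else {
    sequence
  }
}

#' Sequence sampled events into reads
#'
#' Each event's repaired amplicon is emitted as one single-end read (the
#' default read length is the whole repaired amplicon, emulating merged
#' paired-end data) with independent per-base substitution errors. A truth
#' table links each read to its generating event.
#'
#' @param events Table from [sample_events()].
#' @param ref A `reference_construct`.
#' @param read_length Read length in bp, or `NULL` for the full repaired
#'   amplicon. Must not exceed the amplicon length.
#' @param substitution_rate Per-base substitution probability in [0, 0.1].
#' @param seed Integer seed (required).
#' @return List with `reads` (named character vector, names = read ids) and
#'   `truth` (the events table plus `read_id`).
#' @export
events_to_reads <- function(events, ref, read_length = NULL,
                            substitution_rate = 0, seed) {
  if (substitution_rate < 0 || substitution_rate > 0.1) {
    stop("substitution_rate must be in [0, 0.1]")
  }
  if (!is.null(read_length) && read_length > nchar(ref$sequence)) {
    stop("read_length must not exceed the amplicon length")
  }
  run_seeded(seed, {
    reads <- character(nrow(events))
    ids <- sub("^event", "read", events$event_id)
    for (i in seq_len(nrow(events))) {
      sq <- event_to_sequence(events[i, ], ref)
      if (!is.null(read_length)) sq <- substr(sq, 1L, read_length)
      if (substitution_rate > 0) {
        chars <- strsplit(sq, "")[[1]]
        hit <- stats::runif(length(chars)) < substitution_rate
        if (any(hit)) {
          chars[hit] <- vapply(chars[hit], function(b) {
            sample(setdiff(DNA_BASES, b), 1L)
          }, character(1))
          sq <- paste(chars, collapse = "")
        }
      }
      reads[i] <- sq
    }
    names(reads) <- ids
    truth <- events
    truth$read_id <- ids
    list(reads = reads, truth = truth)
  })
}

#' Write simulated reads as FASTQ (Phred+33, constant Q30)
#'
#' @param reads Named character vector of read sequences.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(unname(reads))
  names(dna) <- names(reads)
  quals <- Biostrings::BStringSet(vapply(nchar(reads), function(n) {
    strrep("?", n)  # "?" is Phred+33 Q30
  }, character(1)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read amplicon reads from FASTQ
#'
#' @param path FASTQ path.
#' @return Named character vector of read sequences.
#' @export
read_reads_fastq <- function(path) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(dna), names(dna))
}

#' Write / read an event truth table as TSV
#' @param truth Truth table from [events_to_reads()].
#' @param path TSV path.
#' @return `path` invisibly, or the table.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
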