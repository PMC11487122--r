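# Anchoring, junction calling, microhomology, and cut distance.

ref <- build_reference(arm_length = 50, seed = 1)
hr_start <- unname(ref$hr_deletion_interval["start"])
hr_end <- unname(ref$hr_deletion_interval["end"])

delete_interval <- function(sequence, s, e, insert = "") {
  paste0(substr(sequence, 1, s), insert,
         substr(sequence, e + 1, nchar(sequence)))
}

test_that("anchoring finds both anchors on reference and HR reads", {
  anc <- anchor_read(ref$sequence, ref)
  expect_false(is.null(anc))
  expect_identical(anc$left_end, anc$ref_left_end)
  expect_identical(anc$right_start, anc$ref_right_start)
  hr_read <- delete_interval(ref$sequence, hr_start, hr_end)
  anc_hr <- anchor_read(hr_read, ref)
  expect_false(is.null(anc_hr))
  expect_identical((anc$right_start - anc$left_end) -
                     (anc_hr$right_start - anc_hr$left_end), 23L)
  set.seed(990)  # unrelated to the reference's arm seed
  expect_null(anchor_read(random_sequence(150), ref))
  # one mismatch inside an anchor is tolerated
  mm <- ref$sequence
  pos <- anc$ref_left_end - 5L  # inside the left anchor
  substr(mm, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                  substr(mm, pos, pos))[1]
  expect_false(is.null(anchor_read(mm, ref)))
})

test_that("call_junction recovers engineered indels", {
  # unmodified
  expect_identical(call_junction(ref$sequence, ref)$call_class, "unmodified")
  # the HR product is a left-alignable 23-nt deletion over the HR interval
  hr_call <- call_junction(delete_interval(ref$sequence, hr_start, hr_end), ref)
  expect_identical(hr_call$call_class, "deletion")
  expect_identical(hr_call$del_size, 23L)
  expect_true(hr_call$shift_start <= hr_start &&
                hr_start < hr_call$shift_end)
  expect_identical(hr_call$distance_to_cut, 0L)
  # 1-bp deletion immediately left of the cut
  one <- call_junction(delete_interval(ref$sequence, ref$cut_index - 1L,
                                       ref$cut_index), ref)
  expect_identical(one$call_class, "deletion")
  expect_identical(one$del_size, 1L)
  expect_identical(one$distance_to_cut, 0L)
  # "GG" inserted at the cut: reference's right flank starts with C, so the
  # insert is unambiguous
  ins <- call_junction(delete_interval(ref$sequence, ref$cut_index,
                                       ref$cut_index, insert = "GG"), ref)
  expect_identical(ins$call_class, "insertion")
  expect_identical(ins$insert_seq, "GG")
  expect_identical(ins$del_size, 0L)
  # deletion plus insert; "CC" shares no boundary bases with the deleted
  # "TAA" or its flanks, so the call cannot simplify
  dwi <- call_junction(delete_interval(ref$sequence, ref$cut_index - 3L,
                                       ref$cut_index, insert = "CC"), ref)
  expect_identical(dwi$call_class, "del_with_insert")
  expect_identical(dwi$del_size, 3L)
  expect_identical(dwi$insert_seq, "CC")
})

test_that("microhomology matches hand-built repeats and errors out of bounds", {
  # deleting any 4 bases of the periodic ACGTACGTAC leaves "ACGTAC": all 7
  # placements are equivalent, so the ambiguity length is 6
  expect_identical(microhomology_length("ACGTACGTAC", 2, 6), 6L)
  expect_identical(oracle_mh("ACGTACGTAC", 2, 6), 6L)
  # a TAC repeat: deleting one unit leaves a 3-fold-ambiguous junction
  expect_identical(microhomology_length("GGTACTACAA", 2, 5), 3L)
  expect_identical(oracle_mh("GGTACTACAA", 2, 5), 3L)
  expect_identical(microhomology_length("AACCGGTT", 2, 4), 0L)
  expect_error(microhomology_length("ACGT", 2, 9), "out of bounds")
  expect_error(microhomology_length("ACGT", 3, 3), "out of bounds")
})

test_that("microhomology equals the brute-force placement oracle on 1000 random cases", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(30:80, 1)
    sq <- random_sequence(n)
    d <- sample(1:10, 1)
    s <- sample(0:(n - d - 1), 1)
    expect_identical(microhomology_length(sq, s, s + d),
                     oracle_mh(sq, s, s + d),
                     info = sprintf("seq=%s del=[%d,%d)", sq, s, s + d))
  }
})

test_that("microhomology is invariant across equivalent placements", {
  set.seed(202)
  for (i in 1:200) {
    sq <- random_sequence(60)
    d <- sample(1:8, 1)
    s <- sample(0:(60 - d - 1), 1)
    m <- microhomology_length(sq, s, s + d)
    if (m > 0) {
      base <- oracle_leftmost_start(sq, s, s + d)
      for (k in base + 0:m) {
        expect_identical(microhomology_length(sq, k, k + d), m)
      }
    }
  }
})

test_that("cut distance uses the shift-equivalence region", {
  cut <- ref$cut_index
  # spanning deletion
  expect_identical(
    distance_to_cut(junction_call("r", "deletion", cut - 3L, cut + 3L,
                                  mh_length = 0L, shift_start = cut - 3L,
                                  shift_end = cut - 2L), ref), 0L)
  # 1-bp deletion 12 right of the cut, no microhomology
  expect_identical(
    distance_to_cut(junction_call("r", "deletion", cut + 12L, cut + 13L,
                                  mh_length = 0L, shift_start = cut + 12L,
                                  shift_end = cut + 13L), ref), 12L)
  # the region is the union of equivalent placements: a 1-bp deletion
  # left-aligned 2 right of the cut keeps distance 2 however far its
  # ambiguity run extends rightward ...
  expect_identical(
    distance_to_cut(junction_call("r", "deletion", cut + 2L, cut + 3L,
                                  mh_length = 3L, shift_start = cut + 2L,
                                  shift_end = cut + 6L), ref), 2L)
  # ... while a run that starts left of the cut touches it
  expect_identical(
    distance_to_cut(junction_call("r", "deletion", cut - 2L, cut - 1L,
                                  mh_length = 2L, shift_start = cut - 2L,
                                  shift_end = cut + 1L), ref), 0L)
  expect_identical(
    distance_to_cut(junction_call("r", "unmodified"), ref), 0L)
})

test_that("zero-error round trip recovers the generating events", {
  mix <- default_event_mixture(hr = 0.2, nhej = 0.6, mmej = 0.1, uncut = 0.1)
  ev <- sample_events(mix, ref, 2000, seed = 31)
  sim <- events_to_reads(ev, ref, substitution_rate = 0, seed = 32)
  calls <- call_junctions(sim$reads, ref)
  merged <- merge(calls, sim$truth, by = "read_id")
  class_map <- c(uncut = "unmodified", hr = "deletion",
                 nhej_deletion = "deletion", nhej_insertion = "insertion",
                 nhej_del_with_insert = "del_with_insert",
                 mmej_deletion = "deletion")
  agree <- mean(merged$call_class == class_map[merged$event_class])
  expect_gte(agree, 0.99)
  # deletions: recovered interval is in the same shift-equivalence class
  dels <- merged[merged$call_class == "deletion" &
                   merged$event_class %in% c("hr", "nhej_deletion",
                                             "mmej_deletion"), ]
  same_class <- vapply(seq_len(nrow(dels)), function(i) {
    d <- dels[i, ]
    d$del_size == (d$del_end.y - d$del_start.y) &&
      d$shift_start <= d$del_start.y && d$del_start.y < d$shift_end
  }, logical(1))
  expect_gte(mean(same_class), 0.99)
  expect_true(all(dels$mh_length.x == dels$mh_length.y))
})

test_that("re-calling a call's reconstructed read is idempotent", {
  mix <- default_event_mixture()
  ev <- sample_events(mix, ref, 200, seed = 33)
  sim <- events_to_reads(ev, ref, seed = 34)
  calls <- call_junctions(sim$reads, ref)
  for (i in seq_len(nrow(calls))) {
    call <- calls[i, ]
    rebuilt <- if (call$call_class == "unmodified") {
      ref$sequence
    } else if (call$call_class == "insertion") {
      delete_interval(ref$sequence, call$shift_start, call$shift_start,
                      insert = call$insert_seq)
    } else {
      delete_interval(ref$sequence, call$del_start, call$del_end,
                      insert = call$insert_seq)
    }
    recalled <- call_junction(rebuilt, ref, read_id = call$read_id)
    rownames(recalled) <- NULL
    rownames(call) <- NULL
    expect_identical(recalled, call)
  }
})
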