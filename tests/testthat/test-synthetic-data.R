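# Event sampling, read emission, trace / track / plate / ROI generators.

ref <- build_reference(arm_length = 50, seed = 1)

test_that("degenerate mixtures produce only the requested class", {
  mix <- default_event_mixture(hr = 1, nhej = 0, mmej = 0)
  ev <- sample_events(mix, ref, 100, seed = 2)
  expect_identical(unique(ev$event_class), "hr")
  expect_true(all(ev$del_start == ref$hr_deletion_interval["start"]))
})

test_that("class counts match the mixture within 4 binomial SDs", {
  mix <- default_event_mixture()
  n <- 10000
  ev <- sample_events(mix, ref, n, seed = 3)
  counts <- table(factor(ev$event_class, levels = names(mix$proportions)))
  for (cls in c("hr", "mmej_deletion")) {
    p <- mix$proportions[cls]
    sd4 <- 4 * sqrt(n * p * (1 - p))
    expect_lt(abs(counts[cls] - n * p), sd4)
  }
  n_nhej <- sum(counts[c("nhej_deletion", "nhej_insertion",
                         "nhej_del_with_insert")])
  p_nhej <- sum(mix$proportions[c("nhej_deletion", "nhej_insertion",
                                  "nhej_del_with_insert")])
  expect_lt(abs(n_nhej - n * p_nhej), 4 * sqrt(n * p_nhej * (1 - p_nhej)))
  # chi-square goodness of fit over all classes
  present <- counts[mix$proportions > 0]
  gof <- suppressWarnings(
    chisq.test(present, p = mix$proportions[mix$proportions > 0] /
                 sum(mix$proportions[mix$proportions > 0])))
  expect_gt(gof$p.value, 0.001)
})

test_that("sampled event geometry honors class constraints", {
  ev <- sample_events(default_event_mixture(), ref, 3000, seed = 4)
  mmej <- ev[ev$event_class == "mmej_deletion", ]
  expect_true(all(mmej$mh_length >= 2))
  # constraint re-verified against the reference, not the stored field
  expect_true(all(vapply(seq_len(nrow(mmej)), function(i) {
    microhomology_length(ref, mmej$del_start[i], mmej$del_end[i]) >= 2
  }, logical(1))))
  nhej_del <- ev[ev$event_class == "nhej_deletion", ]
  expect_true(all(nhej_del$mh_length <= 1))
  expect_true(all(nhej_del$del_end - nhej_del$del_start <= 25))
  expect_error(sample_events(structure(list(proportions = c(hr = 0.5)),
                                       class = "event_mixture"),
                             ref, 10, seed = 1),
               "sum to 1")
})

test_that("zero-error reads reproduce the repaired amplicons exactly", {
  ev <- sample_events(default_event_mixture(uncut = 0.2, hr = 0.2,
                                            nhej = 0.55, mmej = 0.05),
                      ref, 50, seed = 6)
  sim <- events_to_reads(ev, ref, substitution_rate = 0, seed = 7)
  uncut_reads <- sim$reads[sim$truth$event_class == "uncut"]
  expect_true(all(uncut_reads == ref$sequence))
  hr_ids <- sim$truth$read_id[sim$truth$event_class == "hr"]
  hr_expected <- paste0(
    substr(ref$sequence, 1, ref$hr_deletion_interval["start"]),
    substr(ref$sequence, ref$hr_deletion_interval["end"] + 1,
           nchar(ref$sequence)))
  expect_true(all(sim$reads[hr_ids] == hr_expected))
  # truth-table consistency: rebuilding each read from its event matches
  rebuilt <- vapply(seq_len(nrow(sim$truth)), function(i) {
    event_to_sequence(sim$truth[i, ], ref)
  }, character(1))
  expect_identical(unname(sim$reads), rebuilt)
})

test_that("substitution errors appear at the configured rate", {
  ev <- sample_events(default_event_mixture(hr = 0, nhej = 0, mmej = 0,
                                            uncut = 1), ref, 1000, seed = 8)
  rate <- 0.001
  sim <- events_to_reads(ev, ref, substitution_rate = rate, seed = 5)
  n_mismatch <- sum(vapply(sim$reads, function(r) {
    sum(utf8ToInt(r) != utf8ToInt(ref$sequence))
  }, numeric(1)))
  n_bases <- sum(nchar(sim$reads))
  expect_lt(abs(n_mismatch - n_bases * rate),
            4 * sqrt(n_bases * rate * (1 - rate)))
  expect_error(events_to_reads(ev, ref, substitution_rate = 0.5, seed = 1),
               "substitution_rate")
})

test_that("generators are pure functions of parameters and seed", {
  mix <- default_event_mixture()
  expect_identical(sample_events(mix, ref, 100, seed = 11),
                   sample_events(mix, ref, 100, seed = 11))
  ev <- sample_events(mix, ref, 20, seed = 11)
  expect_identical(events_to_reads(ev, ref, seed = 12),
                   events_to_reads(ev, ref, seed = 12))
  expect_identical(simulate_focus_tracks("atrip_control", 50, seed = 13),
                   simulate_focus_tracks("atrip_control", 50, seed = 13))
  expect_identical(simulate_roi_intensities("damaged_control", 50, seed = 14),
                   simulate_roi_intensities("damaged_control", 50, seed = 14))
  expect_error(sample_events(mix, ref, 10), "seed")
})

test_that("reads round-trip through FASTQ with Q30 qualities", {
  ev <- sample_events(default_event_mixture(), ref, 20, seed = 15)
  sim <- events_to_reads(ev, ref, seed = 16)
  fq <- tempfile(fileext = ".fastq")
  write_reads_fastq(sim$reads, fq)
  back <- read_reads_fastq(fq)
  expect_identical(back, sim$reads)
  quals <- readLines(fq)[seq(4, 80, by = 4)]
  expect_true(all(strsplit(paste(quals, collapse = ""), "")[[1]] == "?"))
})

test_that("focus track presets reproduce their movement probabilities", {
  presets <- focus_track_presets()
  for (name in names(presets)) {
    tracks <- simulate_focus_tracks(name, 2000, seed = 11)
    expect_true(all(vapply(tracks, function(tr) tr$states$state[1] == "inside",
                           logical(1))))
    p <- presets[[name]]$p_out
    frac <- fraction_outside_at(tracks, 10)$pct_outside / 100
    expect_lt(abs(frac - p), 4 * sqrt(p * (1 - p) / 2000))
  }
  expect_error(simulate_focus_tracks("nope", 10, seed = 1), "available")
})

test_that("track state machine honors its invariants", {
  tracks <- simulate_focus_tracks("mu2_isceI_control", 300, seed = 21,
                                  horizon_min = 120)
  for (tr in tracks) {
    st <- tr$states
    expect_true(all(diff(st$time_min) == 5))
    ridx <- which(st$state == "resolved")
    if (length(ridx) > 0) {   # resolved is absorbing
      expect_identical(ridx, seq.int(min(ridx), nrow(st)))
    }
  }
  # no-exit preset: everything inside at 10 min; no resolution at Inf median
  frozen <- simulate_focus_tracks(list(p_out = 0, p_nd = 0,
                                       median_resolution_min = Inf),
                                  100, seed = 22)
  expect_true(all(vapply(frozen, state_at, character(1), lag_minutes = 10) ==
                    "inside"))
  expect_false(any(vapply(frozen, function(tr)
    any(tr$states$state == "resolved"), logical(1))))
})

test_that("qPCR plate generator encodes quantities in Ct and is noiseless at sd 0", {
  design <- data.frame(locus = c("a", "b"), condition = "x",
                       quantity = c(1, 1), ip_over_input = c(2, 2))
  plate <- simulate_qpcr(design, replicates = 2)
  cts <- tapply(plate$ct, plate$locus, unique)
  expect_identical(cts[["a"]], cts[["b"]])  # equal quantities, identical Ct
  # doubling quantity lowers Ct by one cycle
  design2 <- data.frame(locus = "a", condition = "x", quantity = 2,
                        ip_over_input = 2)
  plate2 <- simulate_qpcr(design2, replicates = 1)
  expect_equal(plate2$ct[plate2$channel == "input"],
               plate$ct[plate$locus == "a" & plate$channel == "input" &
                          plate$replicate == 1] - 1)
})

test_that("ROI generator matches its preset ratio; empty table allowed", {
  tb <- simulate_roi_intensities("damaged_control", 300, seed = 2)
  r <- roi_relative_enrichment(tb)
  # delta-method SD of the mean per-cell ratio: ratio * sdlog / sqrt(n)
  sd_mean <- 0.90 * 0.10 / sqrt(300)
  expect_lt(abs(r$mean_ratio - 0.90), 4 * sd_mean)
  noiseless <- simulate_roi_intensities(list(ratio = 1, noise_sdlog = 0),
                                        50, seed = 3)
  expect_true(all(noiseless$dsb_mean_intensity ==
                    noiseless$domain_mean_intensity))
  empty <- simulate_roi_intensities("damaged_control", 0, seed = 1)
  expect_identical(nrow(empty), 0L)
})
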