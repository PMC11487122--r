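# End-to-end orchestration: simulate -> call -> classify / decompose /
# dynamics / chip on synthetic data, with per-stage seeds derived from one
# base seed and a reproducible JSON report.

#' Default pipeline configuration
#'
#' Per-stage seeds are derived deterministically from `seed` (kept below
#' 2^31); every stochastic stage has its own explicit seed so stages can
#' be re-run independently.
#'
#' @param seed Base integer seed.
#' @param out_dir Output directory (created if missing), or `NULL` to skip
#'   writing artifacts.
#' @param n_reads Number of simulated repair events/reads.
#' @param n_tracks Number of focus tracks per preset.
#' @param n_cells Number of ROI cells per preset.
#' @param arm_length Reference arm length in bp.
#' @param mixture Event mixture (default [default_event_mixture()]).
#' @param config Classifier thresholds (default [classifier_config()]).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, out_dir = NULL, n_reads = 2000L,
                       n_tracks = 2000L, n_cells = 300L, arm_length = 50L,
                       mixture = default_event_mixture(),
                       config = classifier_config()) {
  seed <- as.integer(seed)
  structure(list(
    seed = seed,
    seeds = list(reference = seed, events = seed + 1L, reads = seed + 2L,
                 tracks = seed + 3L, roi = seed + 4L, qpcr = seed + 5L,
                 trace = seed + 6L),
    out_dir = out_dir, n_reads = as.integer(n_reads),
    n_tracks = as.integer(n_tracks), n_cells = as.integer(n_cells),
    arm_length = as.integer(arm_length), mixture = mixture, config = config
  ), class = "run_config")
}

#' Run the full synthetic pipeline
#'
#' Builds the reference, simulates reads, calls and classifies junctions,
#' decomposes a matching synthetic trace, simulates and summarises focus
#' tracks for every preset, computes the ROI relative-enrichment statistic,
#' and runs the ChIP-qPCR enrichment comparison — all from the
#' configuration's seeds, so identical configurations give identical
#' reports.
#'
#' @param config A [run_config()].
#' @return A `pipeline_report` list with one element per analysis family.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  ref <- build_reference(config$arm_length, seed = config$seeds$reference)
  events <- sample_events(config$mixture, ref, config$n_reads,
                          seed = config$seeds$events)
  sim <- events_to_reads(events, ref, substitution_rate = 0,
                         seed = config$seeds$reads)
  calls <- call_junctions(sim$reads, ref)
  pathway <- summarize_pathways(calls, config$config, ref)

  lib <- build_shift_library(ref, config$config$tide_indel_window)
  trace <- simulate_trace(c("0" = 0.4, "-23" = 0.12, "-1" = 0.43,
                            "-2" = 0.05),
                          ref, window = config$config$tide_indel_window)
  decomposition <- spectrum_report(decompose_trace(trace, lib))

  track_summaries <- lapply(names(focus_track_presets()), function(p) {
    tracks <- simulate_focus_tracks(p, config$n_tracks,
                                    seed = config$seeds$tracks)
    s <- fraction_outside_at(tracks, lag = 10)
    list(preset = p, pct_outside = s$pct_outside,
         accumulation_pct = accumulation_fraction(tracks))
  })
  names(track_summaries) <- names(focus_track_presets())

  roi <- lapply(names(roi_presets()), function(p) {
    tb <- simulate_roi_intensities(p, config$n_cells, seed = config$seeds$roi)
    roi_relative_enrichment(tb)[c("mean_ratio", "pct_drop")]
  })
  names(roi) <- names(roi_presets())

  design <- data.frame(
    locus = rep(c("3xp3", "ubx"), each = 2),
    condition = rep(c("minus_iscei", "plus_iscei"), 2),
    quantity = 1,
    ip_over_input = c(4, 4 * 0.72, 4, 4)  # 28% H3K27me3 loss at the target
  )
  plate <- simulate_qpcr(design, replicates = 13, noise_sd_ct = 0.2,
                         seed = config$seeds$qpcr)
  enr <- ddct_enrichment(plate, "3xp3", "ubx")
  chip <- percent_change(enr$enrichment[enr$condition == "minus_iscei"],
                         enr$enrichment[enr$condition == "plus_iscei"],
                         paired = TRUE)

  report <- list(
    seed = config$seed,
    reference = list(amplicon_length = nchar(ref$sequence),
                     cut_index = ref$cut_index),
    pathway = unclass(pathway)[c("n_total", "n_retained", "n_hr", "n_nhej",
                                 "n_mmej", "n_unmodified", "pct_repaired",
                                 "pct_hr_of_repaired", "pct_nhej_of_repaired",
                                 "pct_mmej_of_deletions")],
    trace_decomposition = decomposition,
    focus_movement = track_summaries,
    roi = roi,
    chip = unclass(chip)[c("mean_minus", "mean_plus", "percent_change",
                           "p_value")]
  )
  class(report) <- "pipeline_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_reference_fasta(ref, file.path(config$out_dir, "reference.fasta"))
    write_reads_fastq(sim$reads, file.path(config$out_dir, "reads.fastq"))
    write_truth_tsv(sim$truth, file.path(config$out_dir, "truth.tsv"))
    utils::write.table(calls, file.path(config$out_dir, "junction_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_qpcr_tsv(plate, file.path(config$out_dir, "qpcr_plate.tsv"))
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, force = TRUE)
  }
  report
}

#' Validate pipeline input files
#'
#' Light-weight conformity checks for FASTA/FASTQ/TSV inputs; reports
#' malformed records with line numbers and never mutates inputs.
#'
#' @param paths Character vector of file paths.
#' @return `data.frame` of diagnostics (`path`, `line`, `message`); empty
#'   when all inputs conform.
#' @export
validate_inputs <- function(paths) {
  diags <- list()
  note <- function(path, line, msg) {
    diags[[length(diags) + 1L]] <<- data.frame(
      path = path, line = line, message = msg, stringsAsFactors = FALSE)
  }
  for (path in paths) {
    if (!file.exists(path)) {
      note(path, NA_integer_, "file not found")
      next
    }
    lines <- readLines(path, warn = FALSE)
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("fastq", "fq")) {
      if (length(lines) %% 4 != 0) {
        note(path, length(lines), "truncated FASTQ record (line count not a multiple of 4)")
      }
      n_rec <- length(lines) %/% 4
      for (i in seq_len(n_rec)) {
        block <- lines[(i - 1) * 4 + 1:4]
        if (!startsWith(block[1], "@")) {
          note(path, (i - 1) * 4 + 1, paste0("record ", i, ": header must start with @"))
        } else if (!startsWith(block[3], "+")) {
          note(path, (i - 1) * 4 + 3, paste0("record ", i, ": separator must start with +"))
        } else if (nchar(block[2]) != nchar(block[4])) {
          note(path, (i - 1) * 4 + 4, paste0("record ", i, ": sequence/quality length mismatch"))
        }
      }
    } else if (ext %in% c("fasta", "fa")) {
      if (length(lines) == 0 || !startsWith(lines[1], ">")) {
        note(path, 1L, "FASTA must start with a > header")
      }
    } else if (ext %in% c("tsv", "txt")) {
      if (length(lines) == 0) {
        note(path, 0L, "empty table")
      } else {
        ncol_header <- length(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
        body <- which(nzchar(lines))[-1]
        for (i in body) {
          n <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
          if (n != ncol_header) {
            note(path, i, sprintf("expected %d columns, found %d", ncol_header, n))
          }
        }
      }
    }
  }
  if (length(diags) == 0) {
    return(data.frame(path = character(0), line = integer(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, diags)
  rownames(out) <- NULL
  out
}
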