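# Focus-trajectory simulation and movement/kinetics statistics: each track
# is one DSB repair focus (e.g. Mu2 or ATRIP) followed from its appearance
# inside a polycomb body, sampled every 5-10 minutes.

TRACK_STATES <- c("inside", "outside", "not_detectable", "resolved")

#' Focus-track presets
#'
#' Calibrated to the reporter studies' printed movement percentages:
#' `mu2_isceI_control` 60% of foci outside the polycomb body 10 min after
#' appearance; `atrip_control` 77%; `atrip_dUtx` 53% (dUtx depletion delays
#' movement). Median resolution time defaults to 55 min for the mu2 preset
#' (within the observed 30-80 min range).
#'
#' @return Named list of preset parameter lists (`p_out`, `p_nd`,
#'   `median_resolution_min`).
#' @export
focus_track_presets <- function() {
  list(
    mu2_isceI_control = list(p_out = 0.60, p_nd = 0,
                             median_resolution_min = 55),
    atrip_control = list(p_out = 0.77, p_nd = 0,
                         median_resolution_min = 55),
    atrip_dUtx = list(p_out = 0.53, p_nd = 0,
                      median_resolution_min = 55)
  )
}

#' Simulate focus trajectories
#'
#' Every track starts `inside` at its appearance (t = 0). Its state at the
#' 10-minute timepoint is drawn from the preset's categorical distribution
#' (`outside` with `p_out`, `not_detectable` with `p_nd`, else `inside`);
#' outside-destined foci move out at 5 min with probability 1/2. After
#' 10 min the location persists and a per-interval resolution hazard,
#' calibrated so the median time to resolution matches the preset, may
#' switch the track to the absorbing `resolved` state.
#'
#' @param preset Preset name (see [focus_track_presets()]).
#' @param n Number of tracks.
#' @param seed Integer seed (required).
#' @param horizon_min Observation horizon in minutes (default 45).
#' @param interval_min Sampling interval, 5 or 10 minutes (default 5).
#' @return List of `focus_track` objects: each a list with `focus_id`,
#'   `appearance_time` and `states` (`data.frame` of `time_min`, `state`).
#' @export
simulate_focus_tracks <- function(preset, n, seed, horizon_min = 45,
                                  interval_min = 5) {
  if (is.list(preset)) {
    par <- preset  # ad-hoc preset: list(p_out, p_nd, median_resolution_min)
  } else {
    presets <- focus_track_presets()
    if (!preset %in% names(presets)) {
      stop("unknown preset '", preset, "'; available: ",
           paste(names(presets), collapse = ", "))
    }
    par <- presets[[preset]]
  }
  stopifnot(interval_min %in% c(5, 10))
  # geometric per-interval hazard after the 10-min point such that the
  # median resolution time equals the preset's value; infinite median means
  # no resolution
  t_med <- par$median_resolution_min
  hazard <- if (is.finite(t_med)) 1 - 0.5^(interval_min / (t_med - 10)) else 0
  run_seeded(seed, {
    lapply(seq_len(n), function(i) {
      times <- seq(0, horizon_min, by = interval_min)
      dest <- sample(c("outside", "not_detectable", "inside"), 1L,
                     prob = c(par$p_out, par$p_nd,
                              1 - par$p_out - par$p_nd))
      states <- character(length(times))
      resolved <- FALSE
      for (k in seq_along(times)) {
        t <- times[k]
        if (resolved) { states[k] <- "resolved"; next }
        if (t == 0) { states[k] <- "inside"; next }
        if (t < 10) {
          states[k] <- if (dest == "outside" && stats::runif(1) < 0.5)
            "outside" else "inside"
          next
        }
        if (t > 10 && stats::runif(1) < hazard) {
          resolved <- TRUE
          states[k] <- "resolved"
          next
        }
        states[k] <- dest
      }
      structure(list(focus_id = sprintf("focus_%04d", i),
                     appearance_time = 0,
                     states = data.frame(time_min = times, state = states,
                                         stringsAsFactors = FALSE)),
                class = "focus_track")
    })
  })
}

#' State of a track at a given lag after appearance
#'
#' Snaps to the sampled timepoint nearest to `appearance_time + lag`
#' (imaging intervals were 5-10 min); `resolved` persists beyond the last
#' observation.
#'
#' @param track A `focus_track`.
#' @param lag_minutes Query lag in minutes.
#' @return State string.
#' @export
state_at <- function(track, lag_minutes) {
  t_query <- track$appearance_time + lag_minutes
  st <- track$states
  if (t_query > max(st$time_min)) {
    last <- st$state[nrow(st)]
    return(if (last == "resolved") "resolved" else last)
  }
  idx <- which.min(abs(st$time_min - t_query))
  st$state[idx]
}

#' Movement summary at a query lag
#'
#' Tallies track states at `lag` minutes after appearance. The denominator
#' of `pct_outside` is all appeared foci (not-detectable and resolved foci
#' included, as a third category); `pct_outside_of_located` uses only foci
#' still located inside/outside at the lag.
#'
#' @param tracks List of `focus_track`s.
#' @param lag Query lag in minutes (default 10).
#' @return A `movement_summary` list of counts and percentages.
#' @export
fraction_outside_at <- function(tracks, lag = 10) {
  states <- vapply(tracks, state_at, character(1), lag_minutes = lag)
  n <- length(tracks)
  n_out <- sum(states == "outside")
  n_in <- sum(states == "inside")
  n_nd <- n - n_out - n_in
  structure(list(
    n_foci = n, lag_min = lag,
    n_outside_at_t = n_out, n_inside_at_t = n_in, n_nd_or_resolved_at_t = n_nd,
    pct_outside = if (n > 0) n_out / n * 100 else 0,
    pct_outside_of_located = if (n_out + n_in > 0)
      n_out / (n_out + n_in) * 100 else 0
  ), class = "movement_summary")
}

first_resolved_time <- function(track) {
  st <- track$states
  hit <- which(st$state == "resolved")
  if (length(hit) == 0L) NA_real_ else st$time_min[hit[1]]
}

#' Median focus resolution time
#'
#' Median of first-resolved times over all tracks; flagged undefined
#' (`NA` with attribute `defined = FALSE`) when fewer than half of the
#' tracks resolve within the observation horizon.
#'
#' @param tracks List of `focus_track`s.
#' @return Minutes (numeric) with attribute `defined`.
#' @export
median_resolution_time <- function(tracks) {
  times <- vapply(tracks, first_resolved_time, numeric(1))
  if (mean(!is.na(times)) < 0.5) {
    return(structure(NA_real_, defined = FALSE))
  }
  structure(stats::median(times, na.rm = TRUE), defined = TRUE)
}

#' Fraction of foci that never leave the polycomb body
#'
#' Percentage of tracks whose every observed pre-resolution state is
#' `inside` — foci that accumulate in the domain instead of moving out.
#'
#' @param tracks List of `focus_track`s.
#' @return Percentage.
#' @export
accumulation_fraction <- function(tracks) {
  stays <- vapply(tracks, function(tr) {
    pre <- tr$states$state[tr$states$state != "resolved"]
    all(pre == "inside")
  }, logical(1))
  mean(stays) * 100
}

#' Compare location-category counts between two conditions
#'
#' Two-sided Pearson chi-square (no continuity correction) on the 2 x k
#' table of (outside, inside, not-detectable-or-resolved) counts of two
#' movement summaries.
#'
#' @param summary_a,summary_b `movement_summary` objects.
#' @return List with `statistic`, `df`, `p_value` (see [chi_square_2xk()]).
#' @export
compare_conditions <- function(summary_a, summary_b) {
  counts <- rbind(
    c(outside = summary_a$n_outside_at_t, inside = summary_a$n_inside_at_t,
      nd_or_resolved = summary_a$n_nd_or_resolved_at_t),
    c(outside = summary_b$n_outside_at_t, inside = summary_b$n_inside_at_t,
      nd_or_resolved = summary_b$n_nd_or_resolved_at_t)
  )
  chi_square_2xk(counts)
}

#' Write / read focus tracks as TSV (focus_id, time_min, state)
#' @param tracks List of `focus_track`s.
#' @param path TSV path.
#' @return `path` invisibly, or the track list.
#' @export
write_tracks_tsv <- function(tracks, path) {
  df <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(focus_id = tr$focus_id, time_min = tr$states$time_min,
               state = tr$states$state, stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_tsv
#' @export
read_tracks_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  lapply(split(df, df$focus_id), function(d) {
    d <- d[order(d$time_min), ]
    structure(list(focus_id = d$focus_id[1],
                   appearance_time = min(d$time_min),
                   states = data.frame(time_min = d$time_min,
                                       state = d$state,
                                       stringsAsFactors = FALSE)),
              class = "focus_track")
  })
}
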