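# ROI intensity simulation and the DSB/domain relative-enrichment statistic
# (live-imaging H3K27me3 proxy: mean mintbody signal in a break-proximal
# ROI divided by the mean over the whole polycomb body).

#' ROI intensity presets
#'
#' `damaged_control`: true DSB/domain intensity ratio 0.90 (the ~10%
#' break-proximal H3K27me3 drop); `damaged_dUtx`: ratio 1.00 (dUtx
#' depletion abolishes the drop).
#'
#' @return Named list of presets (`ratio`, `noise_sdlog`).
#' @export
roi_presets <- function() {
  list(
    damaged_control = list(ratio = 0.90, noise_sdlog = 0.10),
    damaged_dUtx = list(ratio = 1.00, noise_sdlog = 0.10)
  )
}

#' Simulate per-cell ROI intensities
#'
#' Domain mean intensities are lognormal (arbitrary units, median 100);
#' the DSB-proximal mean is `ratio x domain_mean x` mean-one lognormal
#' noise, so the preset ratio is the expectation of the per-cell ratio.
#'
#' @param preset Preset name (see [roi_presets()]) or a list with `ratio`
#'   and `noise_sdlog`.
#' @param n_cells Number of cells (0 gives an empty table).
#' @param seed Integer seed (required).
#' @return `data.frame` with `cell_id`, `dsb_mean_intensity`,
#'   `domain_mean_intensity`.
#' @export
simulate_roi_intensities <- function(preset, n_cells, seed) {
  if (!is.list(preset)) {
    presets <- roi_presets()
    if (!preset %in% names(presets)) {
      stop("unknown preset '", preset, "'; available: ",
           paste(names(presets), collapse = ", "))
    }
    preset <- presets[[preset]]
  }
  if (n_cells == 0) {
    return(data.frame(cell_id = character(0),
                      dsb_mean_intensity = numeric(0),
                      domain_mean_intensity = numeric(0)))
  }
  run_seeded(seed, {
    domain <- stats::rlnorm(n_cells, meanlog = log(100), sdlog = 0.3)
    sdlog <- preset$noise_sdlog
    noise <- if (sdlog > 0) {
      stats::rlnorm(n_cells, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      rep(1, n_cells)
    }
    data.frame(cell_id = sprintf("cell_%04d", seq_len(n_cells)),
               dsb_mean_intensity = preset$ratio * domain * noise,
               domain_mean_intensity = domain,
               stringsAsFactors = FALSE)
  })
}

#' DSB/domain relative enrichment
#'
#' Per-cell ratio of the break-proximal mean intensity to the whole-domain
#' mean; `pct_drop = (1 - mean ratio) x 100`. Rows with non-positive
#' domain intensity are rejected with a message.
#'
#' @param table ROI intensity table (see [simulate_roi_intensities()]).
#' @return List with `ratios` (per-cell), `mean_ratio`, `pct_drop`,
#'   `n_rejected`.
#' @export
roi_relative_enrichment <- function(table) {
  bad <- table$domain_mean_intensity <= 0
  if (any(bad)) {
    message(sum(bad), " row(s) rejected: non-positive domain intensity")
  }
  tb <- table[!bad, , drop = FALSE]
  ratios <- tb$dsb_mean_intensity / tb$domain_mean_intensity
  mean_ratio <- if (length(ratios) > 0) mean(ratios) else NA_real_
  list(ratios = ratios, mean_ratio = mean_ratio,
       pct_drop = (1 - mean_ratio) * 100, n_rejected = sum(bad))
}
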