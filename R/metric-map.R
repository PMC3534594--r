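#' Entropy map over the two-rate hypothesis grid
#'
#' Exhaustively evaluates the gating metric — Shannon entropy of the
#' flow-encoded frame magnitudes over the metric ROI, accumulated across
#' cardiac phases — for every combination of first-half and second-half
#' heart rates on a regular grid (default 1 bpm steps over 110--180 bpm).
#' Evaluation order is deterministic (row-major over hr1 then hr2).
#'
#' A flatness statistic, the relative range \code{(max - min)/mean}, is
#' attached: maps with flatness below \code{flat_tol} carry no gating
#' information (e.g. a static, non-pulsatile object) and the argmin is then
#' flagged uninformative.
#'
#' @param acq a [SegmentedAcquisition-class].
#' @param roi metric [RegionOfInterest-class] surrounding the target vessel
#'   and its ghosting artefact.
#' @param hr_band_bpm search band, default \code{c(110, 180)}.
#' @param step_bpm grid step, default 1 bpm.
#' @param n_phases cardiac phase bins per candidate reconstruction.
#' @param flat_tol relative-range threshold below which the map is flagged
#'   flat/uninformative.
#' @return a [MetricMap-class].
#' @export
metricMap <- function(acq, roi, hr_band_bpm = c(110, 180), step_bpm = 1,
                      n_phases = 10L, flat_tol = 1e-3) {
  validObject(acq); validObject(roi)
  stopifnot(step_bpm > 0)
  if (hr_band_bpm[2] <= hr_band_bpm[1]) stop("degenerate heart-rate band")
  grid <- seq(hr_band_bpm[1], hr_band_bpm[2], by = step_bpm)
  t_mid <- max(acq@time_s) / 2
  vals <- entropyGrid(acq, roi, grid, grid, t_mid, n_phases)
  amin <- arrayInd(which.min(vals), dim(vals))
  flat <- (max(vals) - min(vals)) / mean(vals)
  if (flat < flat_tol)
    warning("metric map is flat: argmin is uninformative (no pulsatility?)")
  new("MetricMap", hr1_grid_bpm = grid, hr2_grid_bpm = grid, values = vals,
      argmin_bpm = c(grid[amin[1]], grid[amin[2]]), flatness = flat,
      n_phases = as.integer(n_phases))
}

# Thin wrapper over the compiled grid evaluator: entropy of the flow-encoded
# (encode 2) reconstruction for every (hr1, hr2) pair.
entropyGrid <- function(acq, roi, hr1_grid, hr2_grid, t_mid, n_phases) {
  sel <- acq@encode == 2L
  mask <- if (is(roi, "RegionOfInterest")) roi@mask else roi
  roi_xy <- which(mask, arr.ind = TRUE) - 1L  # 0-based (x, y) pixel indices
  .entropy_grid_cpp(acq@lines[sel, , drop = FALSE], acq@krow[sel],
                    acq@time_s[sel], t_mid, hr1_grid, hr2_grid,
                    as.integer(n_phases), roi_xy, acq@protocol@matrix_size)
}

#' @describeIn metricMap argmin of a computed map as a
#'   [TriggerHypothesis-class].
#' @param map a [MetricMap-class].
#' @param t_mid_s acquisition midpoint to attach.
#' @param band_bpm rate band to attach.
#' @export
argminHypothesis <- function(map, t_mid_s, band_bpm = c(110, 180)) {
  TriggerHypothesis(map@argmin_bpm[1], map@argmin_bpm[2], t_mid_s, band_bpm)
}

#' Export a metric map as CSV
#'
#' Long format: one row per (hr1, hr2) grid point with its entropy.
#'
#' @param map a [MetricMap-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeMetricMap <- function(map, path) {
  df <- expand.grid(hr1_bpm = map@hr1_grid_bpm, hr2_bpm = map@hr2_grid_bpm)
  df$entropy <- as.vector(map@values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

setMethod("show", "MetricMap", function(object) {
  cat(sprintf("MetricMap: %d x %d grid over [%g, %g] bpm, %d phases\n",
              length(object@hr1_grid_bpm), length(object@hr2_grid_bpm),
              min(object@hr1_grid_bpm), max(object@hr1_grid_bpm),
              object@n_phases))
  cat(sprintf("  argmin (hr1, hr2) = (%g, %g) bpm, entropy %.6f\n",
              object@argmin_bpm[1], object@argmin_bpm[2],
              min(object@values)))
  cat(sprintf("  flatness (max-min)/mean = %.3g%s\n", object@flatness,
              if (object@flatness < 1e-3) " [uninformative]" else ""))
})
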