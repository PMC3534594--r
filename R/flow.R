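#' Flow-versus-phase curve for a masked vessel
#'
#' Integrates the through-plane velocity over the lumen mask at each phase:
#' \code{flow = sum(v_cm_s) * pixel_area_cm2 * 60} in ml/min (positive along
#' the reference through-plane direction), the PC principle of summing the
#' velocities of all voxels across the vessel cross-section. The mask is
#' static across phases.
#'
#' @param vcine a [VelocityCine-class].
#' @param mask vessel [RegionOfInterest-class] (or logical matrix) inside
#'   the image bounds.
#' @param pixel_spacing_mm pixel spacing; defaults to the cine's.
#' @return a [FlowCurve-class].
#' @export
flowCurve <- function(vcine, mask, pixel_spacing_mm = NULL) {
  validObject(vcine)
  m <- if (is(mask, "RegionOfInterest")) mask@mask else mask
  d <- dim(vcine@velocity_cm_s)
  if (!identical(dim(m), d[1:2])) stop("mask does not match image bounds")
  if (!any(m)) stop("mask is empty")
  if (is.null(pixel_spacing_mm)) pixel_spacing_mm <- vcine@pixel_spacing_mm
  if (is.na(pixel_spacing_mm)) stop("pixel spacing unknown; supply it")
  area_px_cm2 <- (pixel_spacing_mm / 10)^2
  nph <- d[3]
  flow <- vapply(seq_len(nph), function(p)
    sum(vcine@velocity_cm_s[, , p][m]) * area_px_cm2 * 60, numeric(1))
  new("FlowCurve", phase_times_ms = vcine@phase_times_ms,
      flow_ml_min = flow, mean_flow_ml_min = mean(flow),
      vessel_area_cm2 = sum(m) * area_px_cm2, rr_ms = vcine@rr_ms)
}

#' Cycle-mean flow of a curve
#'
#' Arithmetic mean over the uniformly spaced phases (equal to the cyclic
#' trapezoidal integral divided by the period for uniform sampling).
#'
#' @param curve a [FlowCurve-class].
#' @return mean flow in ml/min.
#' @export
meanFlow <- function(curve) {
  validObject(curve)
  if (!length(curve@flow_ml_min)) stop("empty flow curve")
  mean(curve@flow_ml_min)
}

#' Write a flow curve as CSV
#'
#' Columns \code{phase_time_ms}, \code{flow_ml_min}; the cycle-mean is
#' recoverable as the column mean.
#'
#' @param curve a [FlowCurve-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFlowCurve <- function(curve, path) {
  utils::write.csv(data.frame(phase_time_ms = curve@phase_times_ms,
                              flow_ml_min = curve@flow_ml_min),
                   path, row.names = FALSE)
  invisible(path)
}

setMethod("show", "FlowCurve", function(object) {
  cat(sprintf("FlowCurve: %d phases, mean %.1f ml/min, area %.3f cm^2, R-R %.1f ms\n",
              length(object@flow_ml_min), object@mean_flow_ml_min,
              object@vessel_area_cm2, object@rr_ms))
})
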