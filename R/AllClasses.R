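#' @import methods
#' @importFrom stats approx coef cor cor.test lm pt rnorm runif sd setNames
#' @importFrom utils read.csv write.csv packageVersion
#' @useDynLib mogflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Vessel geometry and dynamics for the pulsatile phantom
#'
#' A single circular vessel carrying through-plane flow. The velocity across
#' the lumen follows a parabolic (Poiseuille) profile whose lumen-mean at
#' cardiac phase \eqn{\theta} equals \code{waveform(theta) * peak_velocity_cm_s}.
#'
#' @slot center_mm numeric(2), position of the lumen centre relative to the
#'   field-of-view centre, in mm.
#' @slot radius_mm lumen radius in mm (fetal target vessels are 2--5 mm).
#' @slot waveform name of a waveform template, see [waveformTemplate()].
#' @slot peak_velocity_cm_s scale applied to the unit-amplitude waveform so
#'   that the lumen-mean velocity at the waveform peak equals this value.
#' @slot lumen_signal magnitude signal of lumen tissue (arbitrary units).
#' @slot wall_thickness_mm static tissue sleeve (vessel wall plus adjacent
#'   soft tissue) surrounding the lumen; its signal matches the wall_signal
#'   slot and it carries no flow. Edge pixels then mix bright lumen with
#'   comparably bright static tissue, so their phase stays close to the
#'   area-weighted velocity rather than being dominated by the lumen.
#' @slot wall_signal magnitude of the sleeve tissue.
#' @export
setClass("VesselSpec",
  representation(center_mm = "numeric", radius_mm = "numeric",
                 waveform = "character", peak_velocity_cm_s = "numeric",
                 lumen_signal = "numeric", wall_thickness_mm = "numeric",
                 wall_signal = "numeric"))

setValidity("VesselSpec", function(object) {
  if (length(object@center_mm) != 2L) return("center_mm must have length 2")
  if (object@radius_mm <= 0) return("radius_mm must be positive")
  if (object@lumen_signal < 0) return("lumen_signal must be non-negative")
  if (object@wall_thickness_mm < 0) return("wall_thickness_mm must be >= 0")
  if (object@wall_signal < 0) return("wall_signal must be non-negative")
  if (!object@waveform %in% waveformNames())
    return(sprintf("unknown waveform '%s'", object@waveform))
  TRUE
})

#' Pulsatile-vessel phantom specification
#'
#' Describes the imaged slice: matrix size, field of view, vessels, static
#' background tissue signal, k-space noise level and the velocity-encoding
#' limit (VENC).
#'
#' @slot matrix_size integer, pixels per in-plane dimension (square matrix).
#' @slot fov_mm field of view in mm; pixel spacing is \code{fov_mm/matrix_size}.
#' @slot vessels list of [VesselSpec-class] objects, all inside the FOV.
#' @slot background_signal magnitude of static background tissue.
#' @slot noise_sd SD of complex Gaussian noise added per k-space sample
#'   (each of the real and imaginary parts).
#' @slot venc_cm_s velocity mapped to an inter-encode phase difference of
#'   \eqn{\pi}; velocities beyond it alias (wrap modulo 2 VENC).
#' @export
setClass("PhantomSpec",
  representation(matrix_size = "integer", fov_mm = "numeric",
                 vessels = "list", background_signal = "numeric",
                 noise_sd = "numeric", venc_cm_s = "numeric"))

setValidity("PhantomSpec", function(object) {
  if (object@matrix_size < 32L) return("matrix_size must be >= 32")
  if (object@fov_mm <= 0) return("fov_mm must be positive")
  if (object@venc_cm_s <= 0) return("venc_cm_s must be positive")
  if (object@noise_sd < 0) return("noise_sd must be non-negative")
  half <- object@fov_mm / 2
  for (v in object@vessels) {
    if (!is(v, "VesselSpec")) return("vessels must contain VesselSpec objects")
    if (any(abs(v@center_mm) + v@radius_mm + v@wall_thickness_mm > half))
      return("vessel extends outside the field of view")
  }
  TRUE
})

#' Heart-rate profile driving a simulated acquisition
#'
#' @slot model one of \code{"constant"}, \code{"two_level"},
#'   \code{"random_walk"}.
#' @slot hr1_bpm,hr2_bpm heart rates (bpm) for the first and second halves of
#'   the acquisition (\code{hr2_bpm} is ignored for \code{"constant"}).
#' @slot beat_to_beat_sd_bpm SD of the per-beat rate increments for the
#'   \code{"random_walk"} model.
#' @slot duration_s total acquisition duration in seconds.
#' @slot band_bpm numeric(2), physiological band the rates must lie in
#'   (default 110--180 bpm, the fetal search band).
#' @export
setClass("HeartRateProfile",
  representation(model = "character", hr1_bpm = "numeric", hr2_bpm = "numeric",
                 beat_to_beat_sd_bpm = "numeric", duration_s = "numeric",
                 band_bpm = "numeric"))

setValidity("HeartRateProfile", function(object) {
  if (!object@model %in% c("constant", "two_level", "random_walk"))
    return("model must be constant, two_level or random_walk")
  if (object@duration_s <= 0) return("duration_s must be positive")
  b <- object@band_bpm
  if (length(b) != 2L || b[1] >= b[2]) return("band_bpm must be (lo, hi)")
  rates <- c(object@hr1_bpm,
             if (object@model != "constant") object@hr2_bpm)
  if (any(rates < b[1] | rates > b[2]))
    return(sprintf("heart rates must lie within [%g, %g] bpm", b[1], b[2]))
  if (object@beat_to_beat_sd_bpm < 0) return("beat_to_beat_sd_bpm must be >= 0")
  TRUE
})

#' Segmented cine acquisition protocol
#'
#' Two velocity encodings (flow-compensated, flow-encoded) are interleaved
#' line by line, so the cine temporal resolution is
#' \code{2 * tr_ms * views_per_segment}. Each segment is acquired continuously
#' over \code{oversample_window_s}, which must exceed the longest plausible
#' R-R interval so every cardiac phase is sampled without a trigger.
#'
#' @slot tr_ms repetition time per k-space line, ms.
#' @slot views_per_segment k-space lines per segment per cardiac phase.
#' @slot matrix_size number of phase-encode lines; \code{n_segments =
#'   matrix_size / views_per_segment}.
#' @slot oversample_window_s continuous acquisition time per segment, s.
#' @export
setClass("AcquisitionProtocol",
  representation(tr_ms = "numeric", views_per_segment = "integer",
                 matrix_size = "integer", oversample_window_s = "numeric"))

setValidity("AcquisitionProtocol", function(object) {
  if (object@tr_ms <= 0) return("tr_ms must be positive")
  if (object@views_per_segment < 1L) return("views_per_segment must be >= 1")
  if (object@matrix_size %% object@views_per_segment != 0L)
    return("matrix_size must be a multiple of views_per_segment")
  if (object@oversample_window_s <= 0)
    return("oversample_window_s must be positive")
  TRUE
})

#' Ungated segmented k-space acquisition
#'
#' Container for timestamped complex k-space line measurements from a
#' continuously oversampled segmented PC cine scan, the protocol that produced
#' them, and (for simulations) the ground truth.
#'
#' @slot lines complex matrix, one k-space line (length \code{matrix_size})
#'   per row.
#' @slot segment integer, 0-based segment index per line.
#' @slot krow integer, 0-based phase-encode row index per line.
#' @slot encode integer per line: 1 = flow-compensated, 2 = flow-encoded.
#' @slot time_s acquisition timestamp of each line, seconds from scan start.
#' @slot protocol an [AcquisitionProtocol-class].
#' @slot ground_truth list with elements \code{beats}, \code{phantom},
#'   \code{profile}, \code{seed} for simulated data, else empty.
#' @export
setClass("SegmentedAcquisition",
  representation(lines = "matrix", segment = "integer", krow = "integer",
                 encode = "integer", time_s = "numeric",
                 protocol = "AcquisitionProtocol", ground_truth = "list"))

setValidity("SegmentedAcquisition", function(object) {
  n <- nrow(object@lines)
  if (!is.complex(object@lines)) return("lines must be a complex matrix")
  if (length(object@segment) != n || length(object@krow) != n ||
      length(object@encode) != n || length(object@time_s) != n)
    return("per-line vectors must match nrow(lines)")
  if (ncol(object@lines) != object@protocol@matrix_size)
    return("line length must equal protocol matrix_size")
  if (any(object@time_s < 0)) return("timestamps must be non-negative")
  if (!all(object@encode %in% 1:2)) return("encode must be 1 or 2")
  for (s in unique(object@segment))
    if (length(unique(object@encode[object@segment == s])) != 2L)
      return(sprintf("segment %d lacks one of the two encodes", s))
  TRUE
})

#' Two-interval heart-rate hypothesis for retrospective gating
#'
#' A constant heart rate is assigned to each half of the acquisition; cardiac
#' phase is continuous across the midpoint (the fractional phase carries
#' over, no trigger reset).
#'
#' @slot hr1_bpm,hr2_bpm hypothesised rates for the two halves, bpm.
#' @slot t_mid_s acquisition midpoint, s.
#' @slot band_bpm numeric(2) search band (default 110--180 bpm).
#' @export
setClass("TriggerHypothesis",
  representation(hr1_bpm = "numeric", hr2_bpm = "numeric", t_mid_s = "numeric",
                 band_bpm = "numeric"))

setValidity("TriggerHypothesis", function(object) {
  b <- object@band_bpm
  if (length(b) != 2L || b[1] >= b[2]) return("band_bpm must be (lo, hi)")
  r <- c(object@hr1_bpm, object@hr2_bpm)
  if (any(r < b[1] | r > b[2]))
    return(sprintf("rates must lie within [%g, %g] bpm", b[1], b[2]))
  if (object@t_mid_s <= 0) return("t_mid_s must be positive")
  TRUE
})

#' Entropy surface over the two-rate hypothesis grid
#'
#' @slot hr1_grid_bpm,hr2_grid_bpm ordered candidate rates for the two halves.
#' @slot values matrix of entropy values, rows indexing \code{hr1_grid_bpm}.
#' @slot argmin_bpm numeric(2), the (hr1, hr2) pair attaining the minimum.
#' @slot flatness relative range (max-min)/mean of the map; a flat map means
#'   the metric carries no gating information (e.g. a static object).
#' @slot n_phases cardiac phases used for each candidate reconstruction.
#' @export
setClass("MetricMap",
  representation(hr1_grid_bpm = "numeric", hr2_grid_bpm = "numeric",
                 values = "matrix", argmin_bpm = "numeric",
                 flatness = "numeric", n_phases = "integer"))

setValidity("MetricMap", function(object) {
  if (!all(is.finite(object@values))) return("metric values must be finite")
  if (!isTRUE(all.equal(min(object@values),
                        object@values[which.min(object@values)])))
    return("argmin must attain the minimum")
  if (nrow(object@values) != length(object@hr1_grid_bpm) ||
      ncol(object@values) != length(object@hr2_grid_bpm))
    return("values shape must match the grids")
  TRUE
})

#' Reconstructed complex cine series
#'
#' @slot frames complex array \code{[x, y, phase, encode]}.
#' @slot phase_times_ms frame centre times within the cardiac cycle, ms.
#' @slot rr_ms cardiac cycle length implied by the accepted trigger, ms.
#' @slot fill_count number of empty (row, phase, encode) k-space cells filled
#'   from the nearest occupied phase bin during binning.
#' @export
setClass("CineSeries",
  representation(frames = "array", phase_times_ms = "numeric",
                 rr_ms = "numeric", fill_count = "integer"))

setValidity("CineSeries", function(object) {
  d <- dim(object@frames)
  if (length(d) != 4L) return("frames must be [x, y, phase, encode]")
  if (d[3] < 1L) return("need at least one phase")
  if (length(object@phase_times_ms) != d[3])
    return("phase_times_ms must match the phase dimension")
  if (is.unsorted(object@phase_times_ms, strictly = TRUE))
    return("phase_times_ms must be strictly increasing")
  TRUE
})

#' Velocity cine derived from a two-encode reconstruction
#'
#' Velocity is the principal-value phase difference between the two encodes
#' scaled by VENC/\eqn{\pi}; no unwrapping is attempted, so \code{|velocity|
#' <= venc_cm_s} always holds and aliased inputs are flagged upstream.
#'
#' @slot velocity_cm_s array \code{[x, y, phase]} of through-plane velocity.
#' @slot magnitude array \code{[x, y, phase]}, mean of the encode magnitudes.
#' @slot venc_cm_s velocity-encoding limit.
#' @slot phase_times_ms frame centre times within the cycle, ms.
#' @slot rr_ms cycle length, ms.
#' @slot pixel_spacing_mm in-plane pixel spacing, mm.
#' @export
setClass("VelocityCine",
  representation(velocity_cm_s = "array", magnitude = "array",
                 venc_cm_s = "numeric", phase_times_ms = "numeric",
                 rr_ms = "numeric", pixel_spacing_mm = "numeric"))

setValidity("VelocityCine", function(object) {
  if (!identical(dim(object@velocity_cm_s), dim(object@magnitude)))
    return("velocity and magnitude shapes must agree")
  if (object@venc_cm_s <= 0) return("venc_cm_s must be positive")
  if (max(abs(object@velocity_cm_s)) > object@venc_cm_s + 1e-9)
    return("velocities must lie within [-venc, venc]")
  if (length(object@phase_times_ms) != dim(object@velocity_cm_s)[3])
    return("phase_times_ms must match the phase dimension")
  TRUE
})

#' Pixel region of interest
#'
#' @slot mask logical matrix, TRUE for pixels inside the region.
#' @slot role \code{"metric"} (entropy evaluation region surrounding the
#'   target vessel and its ghosting artefact) or \code{"vessel"} (lumen mask
#'   for flow integration).
#' @export
setClass("RegionOfInterest",
  representation(mask = "matrix", role = "character"))

setValidity("RegionOfInterest", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (!any(object@mask)) return("mask must contain at least one pixel")
  if (!object@role %in% c("metric", "vessel"))
    return("role must be 'metric' or 'vessel'")
  TRUE
})

#' Flow-versus-phase curve for one vessel
#'
#' @slot phase_times_ms phase centre times, ms.
#' @slot flow_ml_min flow at each phase, ml/min (positive = reference
#'   through-plane direction).
#' @slot mean_flow_ml_min cycle-mean flow over the uniformly spaced phases.
#' @slot vessel_area_cm2 mask area, cm^2.
#' @slot rr_ms cycle length, ms.
#' @export
setClass("FlowCurve",
  representation(phase_times_ms = "numeric", flow_ml_min = "numeric",
                 mean_flow_ml_min = "numeric", vessel_area_cm2 = "numeric",
                 rr_ms = "numeric"))

setValidity("FlowCurve", function(object) {
  if (length(object@flow_ml_min) != length(object@phase_times_ms))
    return("flow and phase times must have equal length")
  if (object@vessel_area_cm2 <= 0) return("vessel area must be positive")
  TRUE
})

#' Agreement summary for paired flow measurements
#'
#' Pearson correlation, least-squares regression of the second series on the
#' first, and Bland-Altman bias statistics. Differences are defined as
#' second minus first.
#'
#' @slot r Pearson correlation (signed).
#' @slot p_value two-sided p from the t statistic with n-2 df.
#' @slot slope,intercept regression of y on x.
#' @slot bias_mean mean(y - x).
#' @slot bias_sd sample SD (n-1 denominator) of y - x.
#' @slot loa_low,loa_high limits of agreement, bias_mean -/+ 1.96 bias_sd.
#' @slot n number of pairs.
#' @slot pair_means,pair_diffs per-pair (x+y)/2 and y-x, the Bland-Altman
#'   plot coordinates.
#' @slot role pairing role, e.g. \code{"method_comparison"},
#'   \code{"repeatability"}, \code{"inter_observer"},
#'   \code{"internal_validation"}.
#' @export
setClass("AgreementResult",
  representation(r = "numeric", p_value = "numeric", slope = "numeric",
                 intercept = "numeric", bias_mean = "numeric",
                 bias_sd = "numeric", loa_low = "numeric", loa_high = "numeric",
                 n = "integer", pair_means = "numeric", pair_diffs = "numeric",
                 role = "character"))

setValidity("AgreementResult", function(object) {
  if (length(object@r) && is.finite(object@r) && abs(object@r) > 1 + 1e-12)
    return("|r| must be <= 1")
  if (length(object@loa_low) && object@loa_high < object@loa_low)
    return("loa_high must be >= loa_low")
  TRUE
})
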