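#' Reconstruct a velocity cine under a given trigger hypothesis
#'
#' Convenience chain: [binMeasurements()] then [reconstructCine()] then
#' [velocityMaps()], with the cycle length taken from the first-interval
#' rate.
#'
#' @param acq a [SegmentedAcquisition-class].
#' @param hyp a [TriggerHypothesis-class].
#' @param n_phases number of phase bins.
#' @param venc_cm_s velocity-encoding limit; defaults to the simulated
#'   phantom's VENC when ground truth is present.
#' @return a [VelocityCine-class].
#' @export
reconstructAt <- function(acq, hyp, n_phases, venc_cm_s = NULL) {
  if (is.null(venc_cm_s)) {
    if (!length(acq@ground_truth) || is.null(acq@ground_truth$phantom))
      stop("venc_cm_s required when the acquisition has no ground truth")
    venc_cm_s <- acq@ground_truth$phantom@venc_cm_s
  }
  px <- if (length(acq@ground_truth) && !is.null(acq@ground_truth$phantom))
    pixelSpacing(acq@ground_truth$phantom) else NA_real_
  binned <- binMeasurements(acq, hyp, n_phases)
  cine <- reconstructCine(binned, rr_ms = 60000 / hyp@hr1_bpm)
  velocityMaps(cine, venc_cm_s, px)
}

#' Metric-optimised gating
#'
#' Full MOG search: an exhaustive coarse entropy map over the two-rate grid
#' (default 1 bpm over 110--180 bpm), an exhaustive fine grid (default
#' 0.1 bpm over +/- \code{refine_span_bpm} around the coarse argmin), and a
#' final local pattern search at the fine step (single-rate and joint
#' moves) until the metric improves by less than \code{tol} or
#' \code{max_iter} moves are exhausted. The fine stage is exhaustive rather
#' than a descent because the entropy surface is rugged at sub-bpm scale —
#' bin assignments flip discretely as the rates change — and the basin
#' around the true rates is only a few tenths of a bpm wide; local stepping
#' from the coarse argmin stalls on spurious dips of the surrounding
#' plateau. The accepted reconstruction is the one optimising the metric;
#' its velocity cine is interpolated to \code{n_phases_out} calculated
#' phases.
#'
#' @param acq a [SegmentedAcquisition-class].
#' @param roi metric [RegionOfInterest-class].
#' @param hr_band_bpm search band (bpm).
#' @param coarse_step_bpm coarse grid step (bpm).
#' @param refine_step_bpm refinement step (bpm).
#' @param refine_span_bpm half-width of the exhaustive fine grid around the
#'   coarse argmin (bpm).
#' @param n_phases phase bins used during the search.
#' @param n_phases_out calculated phases of the returned cine (default 15).
#' @param venc_cm_s velocity-encoding limit (defaults from ground truth).
#' @param tol metric-improvement convergence tolerance.
#' @param max_iter maximum pattern-search moves; non-convergence is
#'   reported with a warning and the best hypothesis so far returned.
#' @return list with \code{hypothesis} ([TriggerHypothesis-class]),
#'   \code{cine} ([VelocityCine-class] at \code{n_phases_out} phases),
#'   \code{map} (the coarse [MetricMap-class]), \code{entropy} (final metric
#'   value) and \code{fill_count}.
#' @export
mogOptimize <- function(acq, roi, hr_band_bpm = c(110, 180),
                        coarse_step_bpm = 1, refine_step_bpm = 0.1,
                        refine_span_bpm = 2, n_phases = 10L,
                        n_phases_out = 15L, venc_cm_s = NULL, tol = 1e-6,
                        max_iter = 50L) {
  map <- metricMap(acq, roi, hr_band_bpm, coarse_step_bpm, n_phases)
  t_mid <- max(acq@time_s) / 2
  hr <- map@argmin_bpm
  best <- min(map@values)
  # exhaustive fine grid around the coarse argmin
  fgrid <- function(centre) {
    g <- seq(centre - refine_span_bpm, centre + refine_span_bpm,
             by = refine_step_bpm)
    g[g >= hr_band_bpm[1] & g <= hr_band_bpm[2]]
  }
  g1 <- fgrid(hr[1]); g2 <- fgrid(hr[2])
  fine <- entropyGrid(acq, roi, g1, g2, t_mid, n_phases)
  fi <- arrayInd(which.min(fine), dim(fine))
  if (min(fine) < best) {
    hr <- c(g1[fi[1]], g2[fi[2]])
    best <- min(fine)
  }
  eval1 <- function(h1, h2)
    entropyGrid(acq, roi, h1, h2, t_mid, n_phases)[1, 1]
  moves <- refine_step_bpm *
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    cand <- sweep(moves, 2, hr, "+")
    ok <- cand[, 1] >= hr_band_bpm[1] & cand[, 1] <= hr_band_bpm[2] &
          cand[, 2] >= hr_band_bpm[1] & cand[, 2] <= hr_band_bpm[2]
    cand <- cand[ok, , drop = FALSE]
    vals <- apply(cand, 1L, function(h) eval1(h[1], h[2]))
    k <- which.min(vals)
    if (vals[k] < best - tol) {
      hr <- cand[k, ]; best <- vals[k]
    } else {
      if (vals[k] < best) { hr <- cand[k, ]; best <- vals[k] }
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("refinement did not converge; returning best hypothesis so far")
  hyp <- TriggerHypothesis(hr[1], hr[2], t_mid, hr_band_bpm)
  binned <- binMeasurements(acq, hyp, n_phases)
  vcine <- reconstructAt(acq, hyp, n_phases, venc_cm_s)
  if (n_phases_out > n_phases) vcine <- interpolatePhases(vcine, n_phases_out)
  list(hypothesis = hyp, cine = vcine, map = map, entropy = best,
       fill_count = binned$fill_count)
}

#' Interpolate a velocity cine to more calculated phases
#'
#' Per-pixel periodic linear interpolation in phase time; output phase times
#' are uniform over the cycle (bin centres). The protocol's roughly 10 true
#' phases are typically interpolated to 15 calculated phases.
#'
#' @param vcine a [VelocityCine-class].
#' @param n_out number of output phases, at least the current count.
#' @return a [VelocityCine-class] with \code{n_out} phases.
#' @export
interpolatePhases <- function(vcine, n_out) {
  validObject(vcine)
  n_in <- dim(vcine@velocity_cm_s)[3]
  if (n_out < 2L) stop("n_out must be at least 2")
  if (n_out < n_in) stop("n_out must be at least the current phase count")
  if (n_out == n_in) return(vcine)
  rr <- vcine@rr_ms
  t_in <- vcine@phase_times_ms
  t_out <- (seq_len(n_out) - 0.5) / n_out * rr
  # extend one frame each side (cyclically) so interpolation wraps
  t_ext <- c(t_in[n_in] - rr, t_in, t_in[1] + rr)
  interp <- function(a) {
    d <- dim(a)
    flat <- matrix(a, d[1] * d[2], d[3])
    ext <- cbind(flat[, n_in], flat, flat[, 1])
    out <- matrix(0, nrow(flat), n_out)
    for (j in seq_len(n_out)) {
      k <- findInterval(t_out[j], t_ext)
      w <- (t_out[j] - t_ext[k]) / (t_ext[k + 1] - t_ext[k])
      out[, j] <- (1 - w) * ext[, k] + w * ext[, k + 1]
    }
    array(out, c(d[1], d[2], n_out))
  }
  new("VelocityCine", velocity_cm_s = interp(vcine@velocity_cm_s),
      magnitude = interp(vcine@magnitude), venc_cm_s = vcine@venc_cm_s,
      phase_times_ms = t_out, rr_ms = rr,
      pixel_spacing_mm = vcine@pixel_spacing_mm)
}

setMethod("show", "VelocityCine", function(object) {
  d <- dim(object@velocity_cm_s)
  cat(sprintf("VelocityCine: %dx%d, %d phases, VENC %g cm/s, R-R %.1f ms\n",
              d[1], d[2], d[3], object@venc_cm_s, object@rr_ms))
  cat(sprintf("  velocity range [%.1f, %.1f] cm/s\n",
              min(object@velocity_cm_s), max(object@velocity_cm_s)))
})

setMethod("show", "CineSeries", function(object) {
  d <- dim(object@frames)
  cat(sprintf("CineSeries: %dx%d, %d phases x %d encodes, R-R %.1f ms, %d filled cells\n",
              d[1], d[2], d[3], d[4], object@rr_ms, object@fill_count))
})

#' Export a velocity cine to NIfTI
#'
#' One file per quantity (velocity in cm/s, magnitude), cardiac phase as the
#' 4th dimension, pixel spacing recorded in the header when known.
#'
#' @param vcine a [VelocityCine-class].
#' @param prefix output path prefix; writes \code{<prefix>_velocity.nii.gz}
#'   and \code{<prefix>_magnitude.nii.gz}.
#' @return character vector of the written paths, invisibly.
#' @export
writeVelocityCine <- function(vcine, prefix) {
  d <- dim(vcine@velocity_cm_s)
  px <- if (is.na(vcine@pixel_spacing_mm)) 1 else vcine@pixel_spacing_mm
  wrap <- function(a) {
    arr <- array(a, c(d[1], d[2], 1L, d[3]))  # x, y, z=1, phase
    img <- RNifti::asNifti(arr)
    img <- RNifti::`pixdim<-`(img, c(px, px, 1, diff(range(vcine@phase_times_ms)) /
                                       max(1, d[3] - 1)))
    img
  }
  paths <- c(paste0(prefix, "_velocity.nii.gz"),
             paste0(prefix, "_magnitude.nii.gz"))
  RNifti::writeNifti(wrap(vcine@velocity_cm_s), paths[1])
  RNifti::writeNifti(wrap(vcine@magnitude), paths[2])
  invisible(paths)
}

#' Read a velocity cine from NIfTI
#'
#' Inverse of [writeVelocityCine()] for externally reconstructed stacks:
#' expects velocity (cm/s) and magnitude volumes with phase as the 4th
#' dimension.
#'
#' @param prefix path prefix used by [writeVelocityCine()].
#' @param venc_cm_s velocity-encoding limit of the data.
#' @param rr_ms cycle length (ms).
#' @param pixel_spacing_mm in-plane pixel spacing (mm); taken from the
#'   header when NA.
#' @return a [VelocityCine-class].
#' @export
readVelocityCine <- function(prefix, venc_cm_s, rr_ms,
                             pixel_spacing_mm = NA_real_) {
  v <- RNifti::readNifti(paste0(prefix, "_velocity.nii.gz"))
  m <- RNifti::readNifti(paste0(prefix, "_magnitude.nii.gz"))
  if (is.na(pixel_spacing_mm))
    pixel_spacing_mm <- RNifti::pixdim(v)[1]
  d <- dim(v)
  nph <- d[length(d)]
  v <- array(as.numeric(v), c(d[1], d[2], nph))
  m <- array(as.numeric(m), c(d[1], d[2], nph))
  new("VelocityCine", velocity_cm_s = v, magnitude = m,
      venc_cm_s = venc_cm_s,
      phase_times_ms = (seq_len(nph) - 0.5) / nph * rr_ms,
      rr_ms = rr_ms, pixel_spacing_mm = pixel_spacing_mm)
}
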