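#' Region-of-interest constructors
#'
#' \code{rectROI} builds a rectangular region from 0-based, half-open pixel
#' bounds (\code{x0 <= x < x1}, x being the first array dimension);
#' \code{maskROI} wraps an explicit logical mask.
#'
#' @param x0,x1,y0,y1 0-based half-open bounds.
#' @param dim image dimensions, e.g. \code{c(64, 64)}.
#' @param role \code{"metric"} or \code{"vessel"}.
#' @param mask logical matrix.
#' @return a [RegionOfInterest-class].
#' @export
rectROI <- function(x0, x1, y0, y1, dim, role = "metric") {
  stopifnot(x0 >= 0, y0 >= 0, x1 <= dim[1], y1 <= dim[2], x1 > x0, y1 > y0)
  m <- matrix(FALSE, dim[1], dim[2])
  m[(x0 + 1):x1, (y0 + 1):y1] <- TRUE
  new("RegionOfInterest", mask = m, role = role)
}

#' @rdname rectROI
#' @export
maskROI <- function(mask, role = "vessel") {
  new("RegionOfInterest", mask = mask, role = role)
}

#' Bin k-space measurements by hypothetical cardiac phase
#'
#' Each measurement is assigned to phase bin
#' \code{floor(phase_fraction * n_phases)} under the hypothesis (half-open
#' bins). Multiple hits in one (k-row, phase, encode) cell are
#' complex-averaged; empty cells are filled from the nearest occupied phase
#' bin of the same k-row and encode (cyclic distance, forward bin preferred
#' on ties) and the number of fills is reported.
#'
#' @param acq a [SegmentedAcquisition-class].
#' @param hyp a [TriggerHypothesis-class]; every segment's oversample window
#'   should cover at least one full hypothetical cycle, otherwise fills are
#'   unavoidable.
#' @param n_phases number of cardiac phase bins.
#' @return list with \code{kspace} (complex array \code{[krow, col, phase,
#'   encode]}), \code{counts} (hits per \code{[krow, phase, encode]} cell),
#'   and \code{fill_count}.
#' @export
binMeasurements <- function(acq, hyp, n_phases) {
  validObject(acq); validObject(hyp)
  stopifnot(n_phases >= 1)
  n <- acq@protocol@matrix_size
  phase <- hypothesisPhase(acq@time_s, hyp)
  bin <- pmin(floor(phase * n_phases), n_phases - 1L)
  counts <- array(0L, c(n, n_phases, 2L))
  ksp <- array(complex(real = 0, imaginary = 0), c(n, n, n_phases, 2L))
  cell <- acq@krow + n * (bin + n_phases * (acq@encode - 1L))  # 0-based
  agg_re <- rowsum(Re(acq@lines), cell)
  agg_im <- rowsum(Im(acq@lines), cell)
  ids <- as.integer(rownames(agg_re))
  cnt <- as.integer(table(factor(cell, levels = ids)))
  krow_i <- ids %% n
  rest <- ids %/% n
  bin_i <- rest %% n_phases
  enc_i <- rest %/% n_phases
  counts[cbind(krow_i + 1L, bin_i + 1L, enc_i + 1L)] <- cnt
  for (k in seq_along(ids)) {
    ksp[krow_i[k] + 1L, , bin_i[k] + 1L, enc_i[k] + 1L] <-
      complex(real = agg_re[k, ], imaginary = agg_im[k, ]) / cnt[k]
  }
  # fill empty cells from the nearest occupied cyclic phase neighbour
  fill_count <- 0L
  for (e in 1:2) for (r in seq_len(n)) {
    occ <- which(counts[r, , e] > 0L)
    if (!length(occ))
      stop(sprintf("k-row %d, encode %d has no measurements in any bin",
                   r - 1L, e))
    if (length(occ) == n_phases) next
    for (b in setdiff(seq_len(n_phases), occ)) {
      for (d in seq_len(n_phases)) {          # +d then -d: forward preferred
        fwd <- (b - 1L + d) %% n_phases + 1L
        bwd <- (b - 1L - d) %% n_phases + 1L
        src <- if (fwd %in% occ) fwd else if (bwd %in% occ) bwd else NA_integer_
        if (!is.na(src)) break
      }
      ksp[r, , b, e] <- ksp[r, , src, e]
      fill_count <- fill_count + 1L
    }
  }
  list(kspace = ksp, counts = counts, fill_count = fill_count)
}

#' Reconstruct a cine series from binned k-space
#'
#' Applies an inverse 2D Fourier transform per phase and encode; frame times
#' sit at bin centres of the first-interval R-R implied by the hypothesis.
#'
#' @param binned result of [binMeasurements()].
#' @param rr_ms cardiac cycle length to attach as frame timing (ms).
#' @return a [CineSeries-class].
#' @export
reconstructCine <- function(binned, rr_ms) {
  d <- dim(binned$kspace)
  n <- d[1]; n_phases <- d[3]
  frames <- array(complex(real = 0, imaginary = 0), d)
  for (e in 1:2) for (p in seq_len(n_phases))
    frames[, , p, e] <- stats::fft(binned$kspace[, , p, e],
                                   inverse = TRUE) / (n * n)
  new("CineSeries", frames = frames,
      phase_times_ms = (seq_len(n_phases) - 0.5) / n_phases * rr_ms,
      rr_ms = rr_ms, fill_count = binned$fill_count)
}

#' Phase-difference velocity maps from a two-encode cine
#'
#' \code{v = venc * Arg(enc2 * Conj(enc1)) / pi} per pixel (principal value;
#' no unwrapping), magnitude the mean of the two encode magnitudes.
#'
#' @param cine a [CineSeries-class] with exactly two encodes.
#' @param venc_cm_s velocity-encoding limit (cm/s).
#' @param pixel_spacing_mm pixel spacing to attach for flow integration.
#' @return a [VelocityCine-class].
#' @export
velocityMaps <- function(cine, venc_cm_s, pixel_spacing_mm = NA_real_) {
  validObject(cine)
  stopifnot(venc_cm_s > 0)
  if (dim(cine@frames)[4] != 2L) stop("exactly two encodes required")
  e1 <- cine@frames[, , , 1, drop = FALSE]
  e2 <- cine@frames[, , , 2, drop = FALSE]
  dphi <- Arg(e2 * Conj(e1))
  v <- array(venc_cm_s * dphi / pi, dim(cine@frames)[1:3])
  m <- array((Mod(e1) + Mod(e2)) / 2, dim(cine@frames)[1:3])
  new("VelocityCine", velocity_cm_s = v, magnitude = m,
      venc_cm_s = venc_cm_s, phase_times_ms = cine@phase_times_ms,
      rr_ms = cine@rr_ms, pixel_spacing_mm = pixel_spacing_mm)
}

#' Shannon entropy of image magnitudes over a region of interest
#'
#' Over all ROI pixels of all supplied frames, with magnitudes \eqn{m_j},
#' \eqn{p_j = m_j / \sum m} and \eqn{E = -\sum p_j \log p_j}. The metric is
#' zero when exactly one pixel is non-zero, maximal (\eqn{\log N}) for a
#' uniform region, and invariant to global intensity scaling. Mis-gating
#' ghosts spread signal across the region and raise the entropy, which is
#' what makes it a gating metric.
#'
#' @param images numeric or complex array \code{[x, y]} or \code{[x, y,
#'   phase]}; complex input is reduced to its magnitude.
#' @param roi a [RegionOfInterest-class] (or logical matrix) selecting the
#'   in-plane pixels.
#' @return non-negative scalar entropy (nats).
#' @export
imageEntropy <- function(images, roi) {
  mask <- if (is(roi, "RegionOfInterest")) roi@mask else roi
  if (!any(mask)) stop("ROI is empty")
  if (is.complex(images)) images <- Mod(images)
  if (length(dim(images)) == 2L) dim(images) <- c(dim(images), 1L)
  d <- dim(images)
  if (!identical(dim(mask), d[1:2])) stop("ROI does not match image shape")
  m <- abs(images[rep(mask, d[3])])
  s <- sum(m)
  if (s == 0) stop("entropy undefined: all ROI magnitudes are zero")
  p <- m[m > 0] / s
  -sum(p * log(p))
}
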