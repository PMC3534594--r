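#' Standard simulation study conditions
#'
#' One place defining the synthetic acquisition used throughout the package
#' validation: a 6 mm artery-like vessel (peak lumen-mean velocity 60 cm/s,
#' arterial waveform) on a dark background, imaged at 1.25 mm pixels
#' (64 x 64 over 80 mm), VENC 150 cm/s, TR 6.55 ms, one view per segment
#' (64 segments, matching the roughly 48-segment fetal scans at reduced
#' matrix size) with a 0.7 s oversample window — a 44.8 s scan. The metric
#' ROI is the column strip through the vessel across all phase-encode rows,
#' covering the vessel and its mis-gating ghost band.
#'
#' @param snr lumen signal-to-noise ratio of a single reconstructed frame
#'   (\code{Inf} for noiseless); converted to a k-space noise SD via
#'   [noiseSdForSNR()].
#' @return list with \code{spec} ([PhantomSpec-class]), \code{protocol}
#'   ([AcquisitionProtocol-class]), \code{roi} (metric
#'   [RegionOfInterest-class]), \code{mask} (true lumen
#'   [RegionOfInterest-class]) and \code{duration_s} (profile duration
#'   covering the scan).
#' @examples
#' st <- simStudy(snr = 20)
#' prof <- HeartRateProfile("constant", 140, duration_s = st$duration_s)
#' @export
simStudy <- function(snr = Inf) {
  spec <- PhantomSpec()
  spec@noise_sd <- noiseSdForSNR(spec, snr)
  protocol <- AcquisitionProtocol(tr_ms = 6.55, views_per_segment = 1L,
                                  matrix_size = 64L,
                                  oversample_window_s = 0.7)
  n <- spec@matrix_size
  px <- pixelSpacing(spec)
  v <- spec@vessels[[1]]
  # column strip: all phase-encode rows x vessel columns (plus margin)
  yc <- (v@center_mm[2] + spec@fov_mm / 2) / px
  y0 <- max(0L, floor(yc - v@radius_mm / px - 3))
  y1 <- min(n, ceiling(yc + v@radius_mm / px + 3))
  roi <- rectROI(0, n, y0, y1, dim = c(n, n), role = "metric")
  list(spec = spec, protocol = protocol, roi = roi, mask = lumenMask(spec),
       duration_s = totalScanTime(protocol))
}
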