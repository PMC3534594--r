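#' Total scan time of a segmented oversampled acquisition
#'
#' \code{n_segments * oversample_window_s}; e.g. 48 segments at a 0.7 s
#' window give roughly 34 s, the typical per-vessel scan time of the fetal
#' protocol.
#'
#' @param protocol an [AcquisitionProtocol-class].
#' @return scan time in seconds.
#' @export
totalScanTime <- function(protocol) nSegments(protocol) * protocol@oversample_window_s

#' Simulate an ungated segmented two-encode PC acquisition
#'
#' Each segment is acquired continuously over its oversample window; within
#' the window, lines cycle through the segment's \code{views_per_segment}
#' phase-encode rows with the two velocity encodings interleaved line by
#' line, timestamps advancing by TR per line. Every line is sampled from the
#' discrete Fourier transform of the phantom rendered at the true cardiac
#' phase of its timestamp (beat times from [simulateBeats()]), with complex
#' Gaussian noise of SD \code{spec@noise_sd} added per sample.
#'
#' Frames are rendered at cardiac phase quantised to \code{1/phase_quant} of
#' a cycle (default 1/720, well below the temporal resolution of any
#' realistic protocol), so repeated phases share one render.
#'
#' @param spec a [PhantomSpec-class]; its \code{matrix_size} must match the
#'   protocol.
#' @param profile a [HeartRateProfile-class] whose duration covers the scan.
#' @param protocol an [AcquisitionProtocol-class]; the oversample window must
#'   exceed the longest simulated R-R interval.
#' @param seed integer seed controlling beats and noise; identical seeds give
#'   bit-identical acquisitions.
#' @param phase_quant cardiac-phase quantisation for frame rendering.
#' @return a [SegmentedAcquisition-class] with ground truth recorded.
#' @export
acquire <- function(spec, profile, protocol, seed = 1L, phase_quant = 720L) {
  validObject(spec); validObject(profile); validObject(protocol)
  if (spec@matrix_size != protocol@matrix_size)
    stop("phantom and protocol matrix sizes differ")
  total <- totalScanTime(protocol)
  if (profile@duration_s < total)
    stop(sprintf("profile duration (%.2f s) shorter than scan time (%.2f s)",
                 profile@duration_s, total))
  set.seed(as.integer(seed))
  beats <- simulateBeats(profile, seed)
  if (max(diff(beats)) >= protocol@oversample_window_s)
    stop("oversample window must exceed the longest simulated R-R interval")

  vps <- protocol@views_per_segment
  nseg <- nSegments(protocol)
  tr_s <- protocol@tr_ms / 1000
  nlines <- floor(protocol@oversample_window_s / tr_s)
  l <- rep(seq_len(nlines) - 1L, times = nseg)
  seg <- rep(seq_len(nseg) - 1L, each = nlines)
  encode <- l %% 2L + 1L
  view <- (l %/% 2L) %% vps
  krow <- seg * vps + view
  time_s <- seg * protocol@oversample_window_s + l * tr_s
  phase <- cardiacPhase(time_s, beats)
  iq <- as.integer(round(phase * phase_quant)) %% phase_quant

  n <- spec@matrix_size
  geom <- phantomGeometry(spec)
  # flow-compensated image is phase-independent (static magnitude, no
  # velocity phase): one k-space render serves every encode-1 line
  k1 <- stats::fft(phantomFrame(spec, 0, geom)$enc1)
  lines <- matrix(complex(real = 0, imaginary = 0), length(l), n)
  idx1 <- which(encode == 1L)
  lines[idx1, ] <- k1[krow[idx1] + 1L, , drop = FALSE]
  for (q in unique(iq[encode == 2L])) {
    k2 <- stats::fft(phantomFrame(spec, q / phase_quant, geom)$enc2)
    sel <- which(encode == 2L & iq == q)
    lines[sel, ] <- k2[krow[sel] + 1L, , drop = FALSE]
  }
  if (spec@noise_sd > 0) {
    nv <- length(lines)
    lines <- lines + complex(real = rnorm(nv, 0, spec@noise_sd),
                             imaginary = rnorm(nv, 0, spec@noise_sd))
  }
  new("SegmentedAcquisition", lines = lines, segment = as.integer(seg),
      krow = as.integer(krow), encode = as.integer(encode), time_s = time_s,
      protocol = protocol,
      ground_truth = list(beats = beats, phantom = spec, profile = profile,
                          seed = as.integer(seed)))
}

#' @describeIn acquire number of k-space line measurements in an acquisition.
#' @param acq a [SegmentedAcquisition-class].
#' @export
nMeasurements <- function(acq) nrow(acq@lines)

setMethod("show", "SegmentedAcquisition", function(object) {
  p <- object@protocol
  cat(sprintf(paste0("SegmentedAcquisition: %d lines, %dx%d matrix, ",
                     "%d segments x %.2f s window\n"),
              nrow(object@lines), p@matrix_size, p@matrix_size,
              nSegments(p), p@oversample_window_s))
  cat(sprintf("  TR %.2f ms, %d views/segment, temporal resolution %.1f ms\n",
              p@tr_ms, p@views_per_segment, temporalResolution(p)))
  if (length(object@ground_truth))
    cat(sprintf("  simulated ground truth: %d beats, seed %d\n",
                length(object@ground_truth$beats), object@ground_truth$seed))
})

#' Write / read an acquisition as plain text
#'
#' The measurement table is written as CSV (segment, krow, encode, time_s and
#' interleaved re_*/im_* columns for the complex line) with a YAML sidecar
#' (\code{<path>.meta.yaml}) carrying the protocol, seed and ground-truth
#' beat times. The round trip is lossless to the printed precision (17
#' significant digits).
#'
#' @param acq a [SegmentedAcquisition-class].
#' @param path CSV output path.
#' @return \code{writeAcquisition} returns \code{path} invisibly;
#'   \code{readAcquisition} returns the [SegmentedAcquisition-class].
#' @export
writeAcquisition <- function(acq, path) {
  validObject(acq)
  n <- ncol(acq@lines)
  df <- data.frame(segment = acq@segment, krow = acq@krow,
                   encode = acq@encode, time_s = acq@time_s)
  re <- Re(acq@lines); im <- Im(acq@lines)
  colnames(re) <- sprintf("re_%d", seq_len(n))
  colnames(im) <- sprintf("im_%d", seq_len(n))
  utils::write.csv(format(cbind(df, re, im), digits = 17, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  p <- acq@protocol
  meta <- list(protocol = list(tr_ms = p@tr_ms,
                               views_per_segment = p@views_per_segment,
                               matrix_size = p@matrix_size,
                               oversample_window_s = p@oversample_window_s),
               seed = if (length(acq@ground_truth)) acq@ground_truth$seed,
               beats = if (length(acq@ground_truth)) acq@ground_truth$beats)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"), precision = 17L)
  invisible(path)
}

#' @rdname writeAcquisition
#' @export
readAcquisition <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  df <- utils::read.csv(path, check.names = FALSE)
  n <- meta$protocol$matrix_size
  lines <- matrix(complex(
    real = as.numeric(as.matrix(df[sprintf("re_%d", seq_len(n))])),
    imaginary = as.numeric(as.matrix(df[sprintf("im_%d", seq_len(n))]))),
    nrow(df), n)
  gt <- if (!is.null(meta$beats))
    list(beats = as.numeric(meta$beats), seed = meta$seed) else list()
  new("SegmentedAcquisition", lines = lines,
      segment = as.integer(df$segment), krow = as.integer(df$krow),
      encode = as.integer(df$encode), time_s = as.numeric(df$time_s),
      protocol = AcquisitionProtocol(
        tr_ms = meta$protocol$tr_ms,
        views_per_segment = meta$protocol$views_per_segment,
        matrix_size = meta$protocol$matrix_size,
        oversample_window_s = meta$protocol$oversample_window_s),
      ground_truth = gt)
}
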