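#' Construct a segmented acquisition protocol
#'
#' Defaults follow the fetal PC protocol: TR 6.55 ms, 4 views per segment
#' (temporal resolution 52.4 ms with the two interleaved encodes) and a
#' 0.7 s oversample window, longer than the longest R-R in the 110--180 bpm
#' band.
#'
#' @param tr_ms repetition time per line (ms).
#' @param views_per_segment lines per segment per cardiac phase.
#' @param matrix_size number of phase-encode rows.
#' @param oversample_window_s continuous acquisition time per segment (s).
#' @return an [AcquisitionProtocol-class].
#' @export
AcquisitionProtocol <- function(tr_ms = 6.55, views_per_segment = 4L,
                                matrix_size = 64L, oversample_window_s = 0.7) {
  new("AcquisitionProtocol", tr_ms = tr_ms,
      views_per_segment = as.integer(views_per_segment),
      matrix_size = as.integer(matrix_size),
      oversample_window_s = oversample_window_s)
}

#' Cine temporal resolution of a protocol
#'
#' With the two velocity encodings interleaved line by line, one cine frame
#' consumes \code{2 * tr_ms * views_per_segment} of scan time; e.g. TR
#' 6.55 ms with 4 views per segment gives 52.4 ms.
#'
#' @param protocol an [AcquisitionProtocol-class], or a TR in ms when
#'   \code{views_per_segment} is given.
#' @param views_per_segment used when \code{protocol} is a plain TR.
#' @return temporal resolution in ms.
#' @examples
#' temporalResolution(6.55, 4)   # 52.4 ms
#' @export
temporalResolution <- function(protocol, views_per_segment = NULL) {
  if (is(protocol, "AcquisitionProtocol")) {
    validObject(protocol)
    return(2 * protocol@tr_ms * protocol@views_per_segment)
  }
  stopifnot(is.numeric(protocol), protocol > 0,
            !is.null(views_per_segment), views_per_segment >= 1)
  2 * protocol * views_per_segment
}

#' Number of true cardiac phases resolved per R-R interval
#'
#' \code{round(rr_ms / temporal_resolution)}: an R-R of 520 ms at 52.4 ms
#' resolution yields 10 true phases, typically interpolated up to 15
#' calculated phases for display.
#'
#' @param rr_ms R-R interval (ms).
#' @param protocol an [AcquisitionProtocol-class] or a temporal resolution
#'   in ms.
#' @return integer number of phases.
#' @export
nTruePhases <- function(rr_ms, protocol) {
  res <- if (is(protocol, "AcquisitionProtocol"))
    temporalResolution(protocol) else protocol
  stopifnot(rr_ms > 0, res > 0)
  as.integer(round(rr_ms / res))
}

#' @describeIn AcquisitionProtocol number of segments,
#'   \code{matrix_size / views_per_segment}.
#' @param protocol an [AcquisitionProtocol-class].
#' @export
nSegments <- function(protocol) protocol@matrix_size %/% protocol@views_per_segment
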