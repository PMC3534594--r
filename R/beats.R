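#' Construct a heart-rate profile
#'
#' @param model \code{"constant"}, \code{"two_level"} or \code{"random_walk"}.
#' @param hr1_bpm rate for the first half of the acquisition (and throughout,
#'   for \code{"constant"}).
#' @param hr2_bpm rate for the second half (\code{"two_level"}).
#' @param beat_to_beat_sd_bpm SD of per-beat rate increments
#'   (\code{"random_walk"}).
#' @param duration_s acquisition duration (s).
#' @param band_bpm physiological band; rates outside it are rejected.
#' @return a [HeartRateProfile-class].
#' @export
HeartRateProfile <- function(model = "constant", hr1_bpm = 140,
                             hr2_bpm = hr1_bpm, beat_to_beat_sd_bpm = 0,
                             duration_s = 12, band_bpm = c(110, 180)) {
  new("HeartRateProfile", model = model, hr1_bpm = hr1_bpm, hr2_bpm = hr2_bpm,
      beat_to_beat_sd_bpm = beat_to_beat_sd_bpm, duration_s = duration_s,
      band_bpm = as.numeric(band_bpm))
}

#' Simulate ground-truth beat times
#'
#' Beat (R-wave) times covering \code{[0, duration_s]}, starting at 0.
#' For \code{"constant"} the inter-beat interval is exactly
#' \code{60/hr1_bpm}; for \code{"two_level"} it switches to \code{60/hr2_bpm}
#' at the acquisition midpoint; for \code{"random_walk"} the per-beat rate
#' performs a Gaussian random walk with increment SD
#' \code{beat_to_beat_sd_bpm}, reflected at the physiological band edges.
#' Deterministic for a given seed.
#'
#' @param profile a [HeartRateProfile-class].
#' @param seed integer RNG seed (only used by \code{"random_walk"}).
#' @return numeric vector of strictly increasing beat times (s); the last
#'   beat is at or beyond \code{duration_s}.
#' @examples
#' simulateBeats(HeartRateProfile("constant", 120, duration_s = 2))
#' @export
simulateBeats <- function(profile, seed = 1L) {
  validObject(profile)
  dur <- profile@duration_s
  beats <- 0
  t <- 0
  rate <- profile@hr1_bpm
  if (profile@model == "random_walk") set.seed(as.integer(seed))
  repeat {
    rate <- switch(profile@model,
      constant = profile@hr1_bpm,
      two_level = if (t < dur / 2) profile@hr1_bpm else profile@hr2_bpm,
      random_walk = {
        r <- rate + rnorm(1L, 0, profile@beat_to_beat_sd_bpm)
        lo <- profile@band_bpm[1]; hi <- profile@band_bpm[2]
        # reflect at the band edges to keep the walk bounded
        if (r < lo) r <- lo + (lo - r)
        if (r > hi) r <- hi - (r - hi)
        min(max(r, lo), hi)
      })
    t <- t + 60 / rate
    beats <- c(beats, t)
    if (t >= dur) break
  }
  beats
}

#' Cardiac phase fraction from beat times
#'
#' Linear phase within each R-R interval: for \code{beat_j <= t < beat_{j+1}},
#' \code{phase = (t - beat_j) / (beat_{j+1} - beat_j)}.
#'
#' @param t times (s), within the span of \code{beats}.
#' @param beats strictly increasing beat times.
#' @return phase fractions in \eqn{[0, 1)}.
#' @export
cardiacPhase <- function(t, beats) {
  stopifnot(!is.unsorted(beats, strictly = TRUE))
  j <- findInterval(t, beats, rightmost.closed = FALSE)
  if (any(j < 1L | j >= length(beats)))
    stop("times must lie within the span of the beat times")
  (t - beats[j]) / (beats[j + 1L] - beats[j])
}
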