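#' Construct a two-interval trigger hypothesis
#'
#' @param hr1_bpm,hr2_bpm hypothesised heart rates for the first and second
#'   halves of the acquisition.
#' @param t_mid_s acquisition midpoint (s).
#' @param band_bpm allowed rate band (default the fetal search band
#'   110--180 bpm).
#' @return a [TriggerHypothesis-class].
#' @export
TriggerHypothesis <- function(hr1_bpm, hr2_bpm = hr1_bpm, t_mid_s,
                              band_bpm = c(110, 180)) {
  new("TriggerHypothesis", hr1_bpm = hr1_bpm, hr2_bpm = hr2_bpm,
      t_mid_s = t_mid_s, band_bpm = as.numeric(band_bpm))
}

#' Hypothetical cardiac phase at arbitrary times
#'
#' Under a two-interval hypothesis the cumulative cardiac phase is piecewise
#' linear and continuous: \code{t * hr1/60} up to the midpoint, then the
#' fractional phase carries over and advances at \code{hr2/60} (no trigger
#' reset at the boundary).
#'
#' @param t times (s).
#' @param hyp a [TriggerHypothesis-class].
#' @return fractional cardiac phase in \eqn{[0, 1)} at each time.
#' @export
hypothesisPhase <- function(t, hyp) {
  cum <- ifelse(t <= hyp@t_mid_s, t * hyp@hr1_bpm / 60,
                hyp@t_mid_s * hyp@hr1_bpm / 60 +
                  (t - hyp@t_mid_s) * hyp@hr2_bpm / 60)
  cum - floor(cum)
}

#' Hypothetical trigger times
#'
#' Triggers start at \eqn{t = 0} with interval \code{60/hr1} until the
#' midpoint and \code{60/hr2} thereafter; the trigger spanning the midpoint
#' is placed where the continuous cumulative phase next crosses an integer.
#'
#' @param hyp a [TriggerHypothesis-class].
#' @param duration_s total acquisition duration (s).
#' @return trigger times in \eqn{[0, duration_s]}.
#' @examples
#' hypotheticalTriggers(TriggerHypothesis(120, 120, t_mid_s = 1), 2)
#' @export
hypotheticalTriggers <- function(hyp, duration_s) {
  validObject(hyp)
  stopifnot(duration_s > 0)
  rr1 <- 60 / hyp@hr1_bpm
  trig <- seq(0, hyp@t_mid_s, by = rr1)
  # fractional phase accrued at t_mid carries into the second interval
  phase_mid <- hyp@t_mid_s * hyp@hr1_bpm / 60
  frac <- phase_mid - floor(phase_mid)
  rr2 <- 60 / hyp@hr2_bpm
  t_next <- hyp@t_mid_s + (1 - frac) * rr2
  if (frac == 0) t_next <- hyp@t_mid_s  # midpoint is itself a trigger
  if (t_next > duration_s) return(trig)
  second <- seq(t_next, duration_s + 1e-9, by = rr2)
  unique(c(trig, second[second > max(trig)]))
}
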