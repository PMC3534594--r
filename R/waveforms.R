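#' Periodic velocity waveform templates
#'
#' Unit-amplitude velocity waveforms on cardiac phase \eqn{[0, 1)} emulating
#' the qualitative flow patterns of the major fetal vessels: brisk systolic
#' forward flow returning to baseline in the great arteries, a later systolic
#' peak continuing into early diastole in the ductus, a substantial continuous
#' diastolic component in the descending aorta, a biphasic caval pattern with
#' a brief reversal during atrial contraction, continuous venous flow, and an
#' antegrade-systolic/retrograde-diastolic branch pulmonary pattern.
#'
#' Each template is normalised so \code{max(abs(v)) == 1}; scaling to physical
#' velocity happens in [VesselSpec-class] via \code{peak_velocity_cm_s}.
#'
#' @param name one of the values returned by [waveformNames()].
#' @return a vectorised function \code{v(phase)} periodic with period 1.
#' @examples
#' w <- waveformTemplate("arterial_systolic")
#' w(c(0, 0.15, 0.5))
#' @export
waveformTemplate <- function(name) {
  name <- match.arg(name, waveformNames())
  raw <- switch(name,
    arterial_systolic = function(p) {
      # systolic raised-cosine pulse (ejection ~ first 35% of the cycle)
      # plus a small mid-diastolic forward bump
      sys <- ifelse(p < 0.35, 0.5 * (1 - cos(2 * pi * p / 0.35)), 0)
      dia <- 0.08 * exp(-((p - 0.7) / 0.08)^2)
      sys + dia
    },
    ductal_late_systolic = function(p) {
      # peak later in systole, decaying through early diastole
      ifelse(p < 0.15, 0.6 * (p / 0.15)^2,
             ifelse(p < 0.45, 0.6 + 0.4 * sin(pi * (p - 0.15) / 0.30),
                    pmax(0, 0.6 * exp(-(p - 0.45) / 0.18) - 0.02)))
    },
    dao_continuous_diastolic = function(p) {
      0.45 + 0.55 * exp(-((p - 0.18) / 0.10)^2) + 0.1 * exp(-((p - 0.75) / 0.2)^2)
    },
    svc_biphasic_reversal = function(p) {
      # systolic and diastolic peaks; brief reversal at atrial contraction
      0.9 * exp(-((p - 0.2) / 0.1)^2) + 0.7 * exp(-((p - 0.6) / 0.1)^2) -
        0.35 * exp(-((p - 0.92) / 0.05)^2)
    },
    venous_continuous = function(p) 0.75 + 0.25 * cos(2 * pi * (p - 0.2)),
    branch_pa_retrograde = function(p) {
      exp(-((p - 0.18) / 0.09)^2) - 0.25 * exp(-((p - 0.6) / 0.15)^2)
    })
  grid <- seq(0, 1, length.out = 4096L)
  scale <- max(abs(raw(grid)))
  function(phase) raw(phase - floor(phase)) / scale
}

#' @rdname waveformTemplate
#' @export
waveformNames <- function() {
  c("arterial_systolic", "ductal_late_systolic", "dao_continuous_diastolic",
    "svc_biphasic_reversal", "venous_continuous", "branch_pa_retrograde")
}

#' Cycle-mean of a waveform template
#'
#' Mean of \code{v(phase)} over one cycle, computed by dense midpoint
#' quadrature. Used to derive analytic ground-truth mean flows for
#' simulated vessels.
#'
#' @param name waveform template name.
#' @param n quadrature points.
#' @return scalar mean value.
#' @export
waveformMean <- function(name, n = 8192L) {
  w <- waveformTemplate(name)
  mean(w((seq_len(n) - 0.5) / n))
}
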