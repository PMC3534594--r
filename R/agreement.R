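#' Pearson correlation for paired flow measurements
#'
#' Product-moment correlation with the two-sided p-value from
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on n-2 df (via [stats::cor.test()]).
#'
#' @param x,y paired measurement series (same length, finite).
#' @return list with \code{r}, \code{p_value}, \code{n}.
#' @export
pearsonAgreement <- function(x, y) {
  checkPairs(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: a series has zero variance")
  if (length(x) >= 3L) {
    ct <- stats::cor.test(x, y)
    list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
  } else {
    list(r = stats::cor(x, y), p_value = NA_real_, n = length(x))
  }
}

checkPairs <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < 2L) stop("need at least 2 pairs")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("measurements must be finite")
  invisible(TRUE)
}

#' Bland-Altman agreement of paired measurements
#'
#' Differences are second minus first (\code{y - x}). Returns the mean
#' difference (bias), its sample SD, and limits of agreement at
#' \code{bias +/- 1.96 * SD}, plus the per-pair (mean, difference)
#' coordinates for plotting.
#'
#' @param x,y paired series.
#' @param role pairing role label.
#' @return an [AgreementResult-class] with the Bland-Altman slots set
#'   (regression/correlation slots empty; see [agreementReport()] for the
#'   combined summary).
#' @export
blandAltman <- function(x, y, role = "method_comparison") {
  checkPairs(x, y)
  d <- y - x
  bias <- mean(d)
  bsd <- stats::sd(d)
  new("AgreementResult", r = NA_real_, p_value = NA_real_,
      slope = NA_real_, intercept = NA_real_,
      bias_mean = bias, bias_sd = bsd,
      loa_low = bias - 1.96 * bsd, loa_high = bias + 1.96 * bsd,
      n = length(x), pair_means = (x + y) / 2, pair_diffs = d, role = role)
}

#' Combined agreement report
#'
#' Pearson correlation, least-squares regression of \code{y} on \code{x},
#' and Bland-Altman bias statistics in one [AgreementResult-class].
#'
#' @param x,y paired series (first and second measurement).
#' @param role pairing role: \code{"method_comparison"},
#'   \code{"repeatability"}, \code{"inter_observer"} or
#'   \code{"internal_validation"}.
#' @return an [AgreementResult-class].
#' @export
agreementReport <- function(x, y, role = "method_comparison") {
  ba <- blandAltman(x, y, role)
  pe <- pearsonAgreement(x, y)
  fit <- stats::lm(y ~ x)
  initialize(ba, r = pe$r, p_value = pe$p_value,
             slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]))
}

#' @describeIn agreementReport write the report as a one-row CSV.
#' @param result an [AgreementResult-class].
#' @param path output CSV path.
#' @export
writeAgreement <- function(result, path) {
  utils::write.csv(data.frame(
    role = result@role, n = result@n, r = result@r,
    p_value = result@p_value, slope = result@slope,
    intercept = result@intercept, bias_mean = result@bias_mean,
    bias_sd = result@bias_sd, loa_low = result@loa_low,
    loa_high = result@loa_high), path, row.names = FALSE)
  invisible(path)
}

setMethod("show", "AgreementResult", function(object) {
  cat(sprintf("AgreementResult (%s), n = %d\n", object@role, object@n))
  if (is.finite(object@r))
    cat(sprintf("  R = %.3f (p = %.3g); y = %.3f x + %.2f\n", object@r,
                object@p_value, object@slope, object@intercept))
  cat(sprintf("  bias %.2f +/- %.2f; limits of agreement [%.2f, %.2f]\n",
              object@bias_mean, object@bias_sd, object@loa_low,
              object@loa_high))
})
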