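#' Fetal weight from segmented MR volume
#'
#' Density-based conversion of a segmented fetal volume to weight:
#' \code{weight_g = 0.12 + 1.031 * volume_ml}.
#'
#' @param volume_ml fetal volume in ml (non-negative).
#' @return estimated weight in grams.
#' @examples
#' mrWeightFromVolume(1000)  # 1031.12 g
#' @export
mrWeightFromVolume <- function(volume_ml) {
  if (any(volume_ml < 0)) stop("volume must be non-negative")
  0.12 + 1.031 * volume_ml
}

#' Index absolute flows to fetal weight
#'
#' @param flow_ml_min flow(s) in ml/min.
#' @param weight_kg fetal weight in kg (positive).
#' @return flows in ml/min/kg (unrounded; round only for table display).
#' @export
indexFlows <- function(flow_ml_min, weight_kg) {
  if (any(weight_kg <= 0)) stop("weight must be positive")
  flow_ml_min / weight_kg
}

# half-away-from-zero integer rounding, matching printed table behaviour
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Read a per-subject flow table
#'
#' CSV schema, one row per subject: \code{subject}, \code{ga_weeks},
#' \code{weight_kg}, then mean flows \code{mpa}, \code{dao}, \code{da},
#' \code{aao}, \code{svc}, \code{uv} and optionally \code{rpa}, \code{lpa}
#' (empty where the branch pulmonary arteries could not be targeted). Units
#' are declared by the \code{units} argument and only recorded, not
#' converted. The cohort of twelve late-gestation fetuses is shipped at
#' \code{system.file("extdata", "table1_fetal_flows.csv", package =
#' "mogflow")} with flows already indexed (ml/min/kg).
#'
#' @param path CSV path; defaults to the shipped cohort table.
#' @param units unit string recorded in the \code{"units"} attribute.
#' @return data.frame of subject records.
#' @export
readSubjectTable <- function(path = system.file("extdata",
                                                "table1_fetal_flows.csv",
                                                package = "mogflow"),
                             units = "ml/min/kg") {
  df <- utils::read.csv(path)
  need <- c("subject", "ga_weeks", "weight_kg", "mpa", "dao", "da", "aao",
            "svc", "uv")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!nrow(df)) stop("no subjects in table")
  attr(df, "units") <- units
  df
}

#' Derive fetal shunt flows from measured vessel flows
#'
#' Shunt accounting for the parallel fetal circulation, in the same units as
#' the inputs:
#' \itemize{
#'   \item \code{cvo = (1 + coronary_fraction) * (mpa + aao)} — combined
#'     ventricular output, with 3\% of the summed outputs added for coronary
#'     flow;
#'   \item \code{pbf_indirect = mpa - da} — pulmonary blood flow from the
#'     difference between main pulmonary artery and ductal flow;
#'   \item \code{fo = cvo - mpa - pbf_indirect} — foramen ovale shunt, i.e.
#'     ascending aortic plus coronary flow minus pulmonary venous return;
#'   \item \code{pbf_direct = rpa + lpa} where both branch flows are present.
#' }
#' Negative derived values are physiologically possible (net retrograde
#' components) and are flagged with a warning, never clipped.
#'
#' @param records data.frame from [readSubjectTable()] (columns \code{mpa},
#'   \code{aao} required; \code{da} required for PBF/FO; \code{rpa},
#'   \code{lpa} optional).
#' @param coronary_fraction coronary flow as a fraction of \code{mpa + aao}
#'   (default 0.03, from fetal lamb data).
#' @return the input data.frame with columns \code{cvo},
#'   \code{pbf_indirect}, \code{pbf_direct}, \code{fo} appended (unrounded).
#' @examples
#' t1 <- readSubjectTable()
#' derived <- deriveFlows(t1)
#' round(derived[1, c("cvo", "pbf_indirect", "fo")])  # 446, 90, 78
#' @export
deriveFlows <- function(records, coronary_fraction = 0.03) {
  if (is.null(records$mpa) || is.null(records$aao) ||
      any(!is.finite(records$mpa)) || any(!is.finite(records$aao)))
    stop("MPA and AAo flows are required for every subject")
  if (is.null(records$da) || any(!is.finite(records$da)))
    stop("DA flow is required for PBF and FO derivation")
  out <- records
  out$cvo <- (1 + coronary_fraction) * (records$mpa + records$aao)
  out$pbf_indirect <- records$mpa - records$da
  out$fo <- out$cvo - records$mpa - out$pbf_indirect
  out$pbf_direct <- if (!is.null(records$rpa) && !is.null(records$lpa))
    records$rpa + records$lpa else NA_real_
  neg <- c("cvo", "pbf_indirect", "fo")
  if (any(out[neg] < 0, na.rm = TRUE))
    warning("negative derived flows (net retrograde component); not clipped")
  out
}

#' Flows as percentages of the combined ventricular output
#'
#' @param derived data.frame from [deriveFlows()] (needs \code{cvo > 0}).
#' @param vessels columns to express as \% of CVO.
#' @return data.frame of percentages (unrounded), one column per vessel,
#'   with the subject column retained.
#' @export
percentCVO <- function(derived,
                       vessels = c("mpa", "dao", "da", "aao", "svc", "uv",
                                   "rpa", "lpa", "pbf_indirect", "fo")) {
  if (any(derived$cvo <= 0)) stop("percent of CVO undefined for cvo <= 0")
  vessels <- intersect(vessels, names(derived))
  out <- derived[, intersect("subject", names(derived)), drop = FALSE]
  for (v in vessels) out[[v]] <- 100 * derived[[v]] / derived$cvo
  out
}

#' Cohort mean and SD per quantity
#'
#' Sample statistics (SD with n-1 denominator) over the subjects with each
#' quantity available; subjects lacking a measurement (e.g. the branch
#' pulmonary arteries) are excluded pairwise. Quantities with fewer than two
#' values get \code{NA} SD.
#'
#' @param records data.frame of per-subject quantities.
#' @param quantities columns to summarise (default: all numeric columns
#'   except subject metadata).
#' @return data.frame with columns \code{quantity}, \code{mean}, \code{sd},
#'   \code{n}.
#' @export
cohortSummary <- function(records, quantities = NULL) {
  if (is.null(quantities))
    quantities <- setdiff(names(records)[vapply(records, is.numeric,
                                                logical(1))],
                          c("subject", "ga_weeks"))
  rows <- lapply(quantities, function(q) {
    x <- records[[q]]
    x <- x[is.finite(x)]
    data.frame(quantity = q, mean = mean(x),
               sd = if (length(x) >= 2L) stats::sd(x) else NA_real_,
               n = length(x))
  })
  do.call(rbind, rows)
}

#' Inverse relationship between foramen ovale shunt and pulmonary flow
#'
#' Least-squares regression of directly measured pulmonary blood flow
#' (\code{rpa + lpa}, kept independent of the derived flows) on the foramen
#' ovale shunt, over the subjects with branch pulmonary measurements; with
#' the signed Pearson correlation and its two-sided p-value (t statistic,
#' n-2 df).
#'
#' @param records data.frame from [readSubjectTable()].
#' @param coronary_fraction passed to [deriveFlows()].
#' @return list with \code{slope}, \code{intercept}, \code{r}, \code{p_value},
#'   \code{n}, and the regression input columns \code{fo}, \code{pbf_direct}.
#' @examples
#' fit <- foPbfRelationship(readSubjectTable())
#' c(fit$slope, fit$intercept, fit$r)  # about -0.85, 170.4, -0.91
#' @export
foPbfRelationship <- function(records, coronary_fraction = 0.03) {
  d <- deriveFlows(records, coronary_fraction)
  ok <- is.finite(d$pbf_direct)
  if (sum(ok) < 3L) stop("need at least 3 subjects with branch PA flows")
  fo <- d$fo[ok]; pbf <- d$pbf_direct[ok]
  fit <- stats::lm(pbf ~ fo)
  ct <- stats::cor.test(fo, pbf)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok),
       fo = fo, pbf_direct = pbf)
}

#' Render the two-block cohort table
#'
#' Indexed flows and percentages of CVO, rounded half away from zero to
#' integers for display (internal values stay unrounded), mirroring how the
#' cohort is reported.
#'
#' @param records data.frame from [readSubjectTable()].
#' @param coronary_fraction passed to [deriveFlows()].
#' @return list with data.frames \code{indexed} and \code{percent}.
#' @export
cohortTable <- function(records, coronary_fraction = 0.03) {
  d <- deriveFlows(records, coronary_fraction)
  num <- c("mpa", "dao", "da", "aao", "svc", "uv", "rpa", "lpa",
           "pbf_indirect", "fo", "cvo")
  idx <- d[c("subject", "ga_weeks", "weight_kg",
             intersect(num, names(d)))]
  for (v in intersect(num, names(idx))) idx[[v]] <- roundHalfAway(idx[[v]])
  pct <- percentCVO(d)
  for (v in setdiff(names(pct), "subject"))
    pct[[v]] <- roundHalfAway(pct[[v]])
  list(indexed = idx, percent = pct)
}
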