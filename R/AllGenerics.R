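#' Extract the kilometre matrix from a DistanceMatrix
#' @param object a \linkS4class{DistanceMatrix}.
#' @return numeric matrix of kilometres (women x facilities).
#' @export
setGeneric("distances", function(object) standardGeneric("distances"))

#' Provenance of a DistanceMatrix
#' @param object a \linkS4class{DistanceMatrix}.
#' @return \code{"haversine"}, \code{"external"} or \code{"planar"}.
#' @export
setGeneric("distanceSource", function(object) standardGeneric("distanceSource"))

#' Chosen alternative per case
#' @param object a \linkS4class{ChoiceDesign}.
#' @return character vector of chosen facility ids, one per woman.
#' @export
setGeneric("chosenAlternative",
  function(object) standardGeneric("chosenAlternative"))

#' Interaction groups of the alternatives
#' @param object a \linkS4class{ChoiceDesign}.
#' @return factor over facilities; the first level is the reference group.
#' @export
setGeneric("alternativeGroups",
  function(object) standardGeneric("alternativeGroups"))

#' Inference table of a fitted choice model
#'
#' One row per free coefficient with estimate, standard error, Wald 95\%
#' confidence limits and two-sided normal p-value.
#'
#' @param object a \linkS4class{FitResult}.
#' @return data.frame with columns \code{term, estimate, se, ci_low,
#'   ci_high, p}.
#' @export
setGeneric("coefTable", function(object) standardGeneric("coefTable"))

## -- methods ----------------------------------------------------------------

#' @describeIn DistanceMatrix-class kilometre matrix accessor.
#' @param object a \code{DistanceMatrix}.
#' @export
setMethod("distances", "DistanceMatrix", function(object) object@km)

#' @describeIn DistanceMatrix-class provenance accessor.
#' @export
setMethod("distanceSource", "DistanceMatrix", function(object) object@source)

setMethod("show", "DistanceMatrix", function(object) {
  cat(sprintf("DistanceMatrix: %d women x %d facilities (source: %s)\n",
    nrow(object@km), ncol(object@km), object@source))
  cat(sprintf("  km range: %.3f - %.3f\n", min(object@km), max(object@km)))
})

#' @describeIn ChoiceDesign-class chosen facility id per woman.
#' @param object a \code{ChoiceDesign}.
#' @export
setMethod("chosenAlternative", "ChoiceDesign",
  function(object) as.character(rowData(object)$chosen))

#' @describeIn ChoiceDesign-class interaction-group factor over facilities.
#' @export
setMethod("alternativeGroups", "ChoiceDesign",
  function(object) colData(object)$group)

setMethod("show", "ChoiceDesign", function(object) {
  cat(sprintf(
    "ChoiceDesign: %d cases x %d alternatives, %d attribute(s)\n",
    nrow(object), ncol(object), length(assayNames(object))))
  cat("  attributes:", paste(assayNames(object), collapse = ", "), "\n")
  covs <- setdiff(colnames(rowData(object)), "chosen")
  if (length(covs))
    cat("  case covariates:", paste(covs, collapse = ", "), "\n")
  cat("  interaction groups:",
    paste(levels(alternativeGroups(object)), collapse = ", "),
    "(reference first)\n")
})

setMethod("show", "UtilityParams", function(object) {
  cat("UtilityParams\n  beta:\n")
  print(round(object@beta, 4))
  if (length(object@lambda)) {
    cat("  lambda (reference group fixed at 0):\n")
    print(round(object@lambda, 4))
  } else cat("  lambda: none\n")
})

#' @describeIn FitResult-class coefficient vector (beta then lambda terms).
#' @param object a \code{FitResult}.
#' @export
setMethod("coef", "FitResult", function(object) object@coefficients)

#' @describeIn FitResult-class observed-information covariance matrix.
#' @export
setMethod("vcov", "FitResult", function(object) object@vcov)

#' @describeIn FitResult-class maximised log-likelihood with df attribute.
#' @export
setMethod("logLik", "FitResult", function(object) {
  structure(object@loglik, df = length(object@coefficients),
    nobs = object@nCases, class = "logLik")
})

#' @describeIn FitResult-class number of cases used in the fit.
#' @export
setMethod("nobs", "FitResult", function(object) object@nCases)

#' @describeIn FitResult-class Wald confidence intervals.
#' @param parm coefficient names (default all).
#' @param level confidence level.
#' @export
setMethod("confint", "FitResult",
  function(object, parm, level = 0.95) {
    est <- object@coefficients
    if (missing(parm)) parm <- names(est)
    se <- sqrt(pmax(diag(object@vcov), 0))
    names(se) <- names(est)
    z <- stats::qnorm(1 - (1 - level) / 2)
    ci <- cbind(est[parm] - z * se[parm], est[parm] + z * se[parm])
    colnames(ci) <- sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
    ci
  })

#' @describeIn FitResult-class full inference table.
#' @export
setMethod("coefTable", "FitResult", function(object) {
  est <- object@coefficients
  se <- sqrt(pmax(diag(object@vcov), 0))
  z <- est / se
  data.frame(term = names(est), estimate = est, se = se,
    ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
    p = 2 * stats::pnorm(-abs(z)), row.names = NULL,
    stringsAsFactors = FALSE)
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf(
    "Conditional logit fit: %d cases, %d coefficients\n",
    object@nCases, length(object@coefficients)))
  cat(sprintf("  log-likelihood %.4f; converged: %s (%d iterations, |grad| %.2e)\n",
    object@loglik, object@converged, object@nIter, object@gradNorm))
  tab <- coefTable(object)
  tab$estimate <- sprintf("%.2f", tab$estimate)
  tab$se <- sprintf("%.3f", tab$se)
  tab$ci_low <- sprintf("%.2f", tab$ci_low)
  tab$ci_high <- sprintf("%.2f", tab$ci_high)
  tab$p <- formatPValue(tab$p)
  print(tab, row.names = FALSE)
})

setMethod("show", "WTTEstimate", function(object) {
  cat(sprintf(
    "Willingness to travel for '%s': %.1f km per unit (SE %.2f, 95%% CI %.1f to %.1f)\n",
    object@attribute, object@km, object@se, object@ciLow, object@ciHigh))
})

## p-values printed to 3 significant figures, "<0.0001" below that floor
formatPValue <- function(p) {
  ifelse(p < 1e-4, "<0.0001", signif(p, 3))
}
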