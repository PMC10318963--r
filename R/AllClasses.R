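#' @import methods
#' @importFrom stats4 coef vcov logLik confint nobs
NULL

#' Woman-to-facility distance matrix
#'
#' Holds the full woman x facility distance table, in kilometres, together
#' with its provenance: \code{"haversine"} when computed internally as
#' great-circle distances, \code{"external"} when supplied by the user (for
#' example road-network distances from a routing engine), or
#' \code{"planar"} when produced by the simulator from exact planar
#' coordinates.
#'
#' Row names are woman ids and column names facility ids; both must be
#' unique, and every entry must be a finite nonnegative number.
#'
#' @slot km numeric matrix of distances in kilometres, dimnames =
#'   (woman ids, facility ids).
#' @slot source character scalar, one of \code{"haversine"},
#'   \code{"external"}, \code{"planar"}.
#' @seealso [buildDistanceMatrix()], [nearestFlags()]
#' @export
setClass("DistanceMatrix",
  representation(km = "matrix", source = "character"))

setValidity("DistanceMatrix", function(object) {
  km <- object@km
  msg <- character()
  if (!is.numeric(km)) msg <- c(msg, "'km' must be a numeric matrix")
  if (is.null(rownames(km)) || is.null(colnames(km)))
    msg <- c(msg, "'km' must carry woman ids as rownames and facility ids as colnames")
  else {
    if (anyDuplicated(rownames(km))) msg <- c(msg, "duplicated woman ids")
    if (anyDuplicated(colnames(km))) msg <- c(msg, "duplicated facility ids")
  }
  if (is.numeric(km) && (any(!is.finite(km)) || any(km < 0)))
    msg <- c(msg, "all distances must be finite and >= 0")
  if (length(object@source) != 1L ||
      !object@source %in% c("haversine", "external", "planar"))
    msg <- c(msg, "'source' must be one of 'haversine', 'external', 'planar'")
  if (length(msg)) msg else TRUE
})

#' Conditional-logit utility parameters
#'
#' The coefficients of the utility a woman i derives from facility j:
#' \deqn{V_{ij} = \sum_m \beta_m x_{ijm} + \sum_p \lambda_{g(j)p} Z_{ip}}
#' where \eqn{x_{ijm}} are alternative-varying attributes (distance, nearest
#' flag, quality indicators), \eqn{Z_{ip}} case-specific covariates
#' (education, wealth), and \eqn{g(j)} maps each facility to an interaction
#' group; the reference group's \eqn{\lambda} row is fixed at zero and not
#' stored.
#'
#' @slot beta named numeric vector of attribute coefficients (one per
#'   alternative-varying attribute).
#' @slot lambda numeric matrix of interaction coefficients, one row per
#'   non-reference group, one column per case-covariate term; may have zero
#'   rows or columns when no interactions are modelled.
#' @seealso [utilityParams()], [choiceProbabilities()]
#' @export
setClass("UtilityParams",
  representation(beta = "numeric", lambda = "matrix"))

setValidity("UtilityParams", function(object) {
  msg <- character()
  if (length(object@beta) && is.null(names(object@beta)))
    msg <- c(msg, "'beta' must be named")
  if (any(!is.finite(object@beta))) msg <- c(msg, "'beta' must be finite")
  if (length(object@lambda) && any(!is.finite(object@lambda)))
    msg <- c(msg, "'lambda' must be finite")
  if (length(object@lambda) &&
      (is.null(rownames(object@lambda)) || is.null(colnames(object@lambda))))
    msg <- c(msg, "'lambda' must carry group rownames and covariate colnames")
  if (length(msg)) msg else TRUE
})

#' Woman-by-facility choice design
#'
#' A \linkS4class{SummarizedExperiment} subclass holding everything the
#' conditional logit needs: rows are women (cases), columns facilities
#' (alternatives, identical choice set for every case), and each assay is
#' one alternative-varying attribute \eqn{x_{ijm}} as a case x alternative
#' matrix. \code{rowData} carries the case-specific covariates plus a
#' \code{chosen} column naming the facility each woman actually used;
#' \code{colData} carries facility metadata including a \code{group} factor
#' defining the interaction groups for the \eqn{\lambda} coefficients (first
#' level = reference).
#'
#' @seealso [buildDesign()], [fitChoiceModel()]
#' @export
#' @import SummarizedExperiment
setClass("ChoiceDesign", contains = "SummarizedExperiment")

setValidity("ChoiceDesign", function(object) {
  msg <- character()
  if (length(assayNames(object)) == 0L)
    msg <- c(msg, "at least one attribute assay is required")
  if (anyDuplicated(assayNames(object)))
    msg <- c(msg, "attribute names must be unique")
  for (nm in assayNames(object)) {
    a <- assay(object, nm)
    if (!is.numeric(a) || any(!is.finite(a))) {
      msg <- c(msg, sprintf("attribute '%s' has missing or non-finite values", nm))
    }
  }
  rd <- rowData(object)
  if (!"chosen" %in% colnames(rd))
    msg <- c(msg, "rowData must contain a 'chosen' column")
  else if (!all(rd$chosen %in% colnames(object)))
    msg <- c(msg, "every chosen facility must be one of the design's alternatives")
  cd <- colData(object)
  if (!"group" %in% colnames(cd))
    msg <- c(msg, "colData must contain a 'group' factor")
  else if (!is.factor(cd$group))
    msg <- c(msg, "'group' must be a factor")
  if (length(msg)) msg else TRUE
})

#' Fitted conditional logit model
#'
#' Result of [fitChoiceModel()]: maximum-likelihood estimates with the
#' observed-information covariance matrix and convergence diagnostics.
#' Standard accessors [coef()], [vcov()], [logLik()], [confint()] and
#' [nobs()] apply; [coefTable()] formats the full inference table.
#'
#' @slot params \linkS4class{UtilityParams} estimates in structured form.
#' @slot coefficients named numeric vector, beta terms then lambda terms
#'   (lambda names are \code{"group:covariate"}).
#' @slot vcov symmetric covariance matrix over all free coefficients
#'   (inverse observed information at the optimum).
#' @slot loglik maximised log-likelihood (always <= 0).
#' @slot converged logical convergence flag.
#' @slot nIter Newton iterations used.
#' @slot gradNorm max-norm of the score at the reported estimate.
#' @slot nCases number of cases (women) entering the fit.
#' @slot nBeta number of alternative-varying attribute coefficients.
#' @export
setClass("FitResult",
  representation(params = "UtilityParams", coefficients = "numeric",
    vcov = "matrix", loglik = "numeric", converged = "logical",
    nIter = "integer", gradNorm = "numeric", nCases = "integer",
    nBeta = "integer"))

setValidity("FitResult", function(object) {
  msg <- character()
  k <- length(object@coefficients)
  if (!all(dim(object@vcov) == c(k, k)))
    msg <- c(msg, "vcov dimensions must match the coefficient vector")
  else if (max(abs(object@vcov - t(object@vcov))) > 1e-8)
    msg <- c(msg, "vcov must be symmetric")
  if (length(object@loglik) != 1L || object@loglik > 1e-8)
    msg <- c(msg, "loglik must be a scalar <= 0")
  if (length(msg)) msg else TRUE
})

#' Willingness-to-travel estimate
#'
#' The extra distance, in kilometres, a woman is willing to travel for one
#' additional unit of a quality attribute: the marginal rate of substitution
#' \eqn{\beta_a / |\beta_d|} between the attribute and distance, with a
#' delta-method standard error and Wald 95\% confidence interval.
#'
#' @slot attribute name of the quality attribute.
#' @slot km point estimate, kilometres per attribute unit.
#' @slot se delta-method standard error, kilometres.
#' @slot ciLow,ciHigh Wald 95\% confidence limits.
#' @seealso [willingnessToTravel()], [wttTable()]
#' @export
setClass("WTTEstimate",
  representation(attribute = "character", km = "numeric", se = "numeric",
    ciLow = "numeric", ciHigh = "numeric"))

setValidity("WTTEstimate", function(object) {
  msg <- character()
  if (!is.finite(object@km)) msg <- c(msg, "'km' must be finite")
  if (is.finite(object@ciLow) && is.finite(object@ciHigh) &&
      (object@km < object@ciLow || object@km > object@ciHigh))
    msg <- c(msg, "confidence interval must contain the estimate")
  if (length(msg)) msg else TRUE
})
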