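#' Willingness to travel for a quality attribute
#'
#' The extra distance a woman is willing to travel for one additional unit
#' of a quality attribute is the marginal rate of substitution between that
#' attribute and distance,
#' \deqn{WTT_a = \beta_a / |\beta_d|,}
#' defined against the absolute value of the distance coefficient so that
#' attractive attributes (positive \eqn{\beta_a}) give positive kilometres.
#' The distance coefficient must be strictly negative — distance must
#' deter — or the ratio is meaningless and the function refuses.
#'
#' Uncertainty is by the delta method on the 2x2 sub-covariance of
#' \eqn{(\beta_a, \beta_d)}, gradient \eqn{(1/|\beta_d|,\,
#' \beta_a/\beta_d^2)}, with a Wald 95\% interval. Ratio estimators
#' misbehave when the denominator is imprecise, so a warning is issued when
#' \eqn{|\beta_d|/se(\beta_d) < 3}.
#'
#' @param fit a \linkS4class{FitResult}.
#' @param attr name of the quality-attribute coefficient.
#' @param distAttr name of the distance coefficient (default
#'   \code{"distance"}).
#' @return a \linkS4class{WTTEstimate}.
#' @examples
#' \dontrun{
#' willingnessToTravel(fit, "n_other_services")
#' }
#' @export
willingnessToTravel <- function(fit, attr, distAttr = "distance") {
  est <- coef(fit)
  if (!attr %in% names(est))
    stop("no coefficient named '", attr, "' in the fit", call. = FALSE)
  if (!distAttr %in% names(est))
    stop("no coefficient named '", distAttr, "' in the fit", call. = FALSE)
  bA <- est[[attr]]
  bD <- est[[distAttr]]
  if (bD >= 0)
    stop("distance coefficient non-negative; WTT undefined", call. = FALSE)
  vc <- vcov(fit)[c(attr, distAttr), c(attr, distAttr)]
  seD <- sqrt(vc[2L, 2L])
  if (is.finite(seD) && seD > 0 && abs(bD) / seD < 3)
    warning("distance coefficient is imprecise (|coef|/SE < 3); the ",
      "delta-method interval for the ratio may be unreliable",
      call. = FALSE)
  km <- bA / abs(bD)
  grad <- c(1 / abs(bD), bA / bD^2)
  se <- sqrt(drop(t(grad) %*% vc %*% grad))
  new("WTTEstimate", attribute = attr, km = km, se = se,
    ciLow = km - 1.96 * se, ciHigh = km + 1.96 * se)
}

#' Willingness-to-travel table
#'
#' One willingness-to-travel estimate per quality attribute, in the order
#' given, as a data.frame ready to be written as the WTT report.
#'
#' @param fit a \linkS4class{FitResult}.
#' @param attrs character vector of attribute coefficient names.
#' @param distAttr name of the distance coefficient.
#' @return data.frame with columns \code{attribute, km, se, ci_low,
#'   ci_high}.
#' @export
wttTable <- function(fit, attrs, distAttr = "distance") {
  rows <- lapply(attrs, function(a) {
    w <- willingnessToTravel(fit, a, distAttr)
    data.frame(attribute = w@attribute, km = w@km, se = w@se,
      ci_low = w@ciLow, ci_high = w@ciHigh, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
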