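DEFAULT_ATTRIBUTES <- c("distance", "nearest", "n_fp_methods",
  "n_other_services", "hospital", "charges_fee", "open_weekends",
  "female_only_providers")

#' Construct utility parameters
#'
#' @param beta named numeric vector of attribute coefficients.
#' @param lambda optional matrix of interaction coefficients (rows =
#'   non-reference groups, columns = case-covariate terms); omit or give a
#'   0-row matrix when no interactions are modelled.
#' @return a \linkS4class{UtilityParams}.
#' @examples
#' utilityParams(c(distance = -0.17, nearest = 1.16))
#' @export
utilityParams <- function(beta, lambda = NULL) {
  if (is.null(lambda))
    lambda <- matrix(numeric(0), 0L, 0L,
      dimnames = list(character(0), character(0)))
  new("UtilityParams", beta = beta, lambda = lambda)
}

## Expand the rowData case covariates into numeric term columns:
## factors become treatment-coded dummies named <cov>_<level>.
caseCovariateColumns <- function(design) {
  rd <- rowData(design)
  covs <- setdiff(colnames(rd), "chosen")
  cols <- list()
  for (cv in covs) {
    x <- rd[[cv]]
    if (is.factor(x) || is.character(x)) {
      x <- factor(x)
      for (lv in levels(x)[-1L])
        cols[[paste0(cv, "_", lv)]] <- as.numeric(x == lv)
    } else {
      cols[[cv]] <- as.numeric(x)
    }
  }
  cols
}

## One n x J matrix per free coefficient: attribute assays first (beta
## block), then group-indicator x covariate products (lambda block).
designTermMatrices <- function(design) {
  mats <- lapply(assayNames(design), function(nm) unname(assay(design, nm)))
  names(mats) <- assayNames(design)
  nBeta <- length(mats)
  groups <- alternativeGroups(design)
  covCols <- caseCovariateColumns(design)
  lamGroups <- character(0); lamCovs <- character(0)
  if (length(covCols) && nlevels(groups) > 1L) {
    lamGroups <- levels(groups)[-1L]
    lamCovs <- names(covCols)
    for (g in lamGroups) {
      ind <- as.numeric(groups == g)
      for (p in lamCovs)
        mats[[paste0(g, ":", p)]] <- outer(covCols[[p]], ind)
    }
  }
  list(mats = mats, nBeta = nBeta, lamGroups = lamGroups, lamCovs = lamCovs)
}

paramsToVector <- function(params, tm) {
  beta <- params@beta[names(tm$mats)[seq_len(tm$nBeta)]]
  if (any(is.na(beta)))
    stop("params lack coefficients for attribute(s): ",
      paste(setdiff(names(tm$mats)[seq_len(tm$nBeta)], names(params@beta)),
        collapse = ", "), call. = FALSE)
  lam <- numeric(0)
  if (length(tm$lamGroups)) {
    lam <- as.numeric(t(params@lambda[tm$lamGroups, tm$lamCovs, drop = FALSE]))
  }
  theta <- c(beta, lam)
  names(theta) <- names(tm$mats)
  theta
}

vectorToParams <- function(theta, tm) {
  beta <- theta[seq_len(tm$nBeta)]
  lam <- matrix(numeric(0), 0L, 0L,
    dimnames = list(character(0), character(0)))
  if (length(tm$lamGroups)) {
    lam <- matrix(theta[-seq_len(tm$nBeta)], nrow = length(tm$lamGroups),
      ncol = length(tm$lamCovs), byrow = TRUE,
      dimnames = list(tm$lamGroups, tm$lamCovs))
  }
  new("UtilityParams", beta = beta, lambda = lam)
}

utilityMatrix <- function(tm, theta) {
  V <- theta[1L] * tm$mats[[1L]]
  for (k in seq_along(theta)[-1L]) if (theta[k] != 0)
    V <- V + theta[k] * tm$mats[[k]]
  V
}

rowMax <- function(V) V[cbind(seq_len(nrow(V)), max.col(V, "first"))]

softmaxRows <- function(V) {
  E <- exp(V - rowMax(V))         # per-case max subtraction: overflow-safe
  E / rowSums(E)
}

#' Build the woman-by-facility choice design
#'
#' Assembles the long-format design for the alternative-specific
#' conditional logit: every woman faces the same set of facilities, with
#' one attribute matrix per alternative-varying covariate and case-level
#' covariates reserved for interaction with facility groups. Default
#' attributes: distance (km), nearest-facility flag, number of family
#' planning methods (stock-validated when \code{stock} and
#' \code{surveyDate} are given), number of other services, hospital dummy,
#' fee flag, weekend opening, female-only providers.
#'
#' Women whose chosen facility is not in \code{facilities}, or with missing
#' case covariates, are dropped listwise with a message naming them.
#' Facilities never chosen by anyone stay in every choice set. The default
#' interaction grouping is hospital versus other (family planning/health
#' centers and dispensaries merged as the reference), since
#' facility-specific interactions are not estimable at these sample sizes.
#'
#' @param women data.frame of woman records; must include
#'   \code{woman_id} and \code{chosen_facility_id}.
#' @param facilities data.frame of facility records.
#' @param dm \linkS4class{DistanceMatrix} covering all pairs.
#' @param attributes character vector of attribute names to include.
#' @param caseCovs character vector of case-covariate columns of
#'   \code{women} to keep for interactions (e.g.
#'   \code{c("education", "wealth_quintile")}); \code{NULL} for none.
#' @param groups optional factor over facilities defining interaction
#'   groups (first level = reference); default hospital vs other.
#' @param stock,surveyDate optional stock table and survey day for the
#'   stock-validated method count.
#' @return a \linkS4class{ChoiceDesign}.
#' @export
buildDesign <- function(women, facilities, dm,
    attributes = DEFAULT_ATTRIBUTES, caseCovs = NULL, groups = NULL,
    stock = NULL, surveyDate = NULL) {
  fid <- as.character(facilities$facility_id)
  chosen <- as.character(women$chosen_facility_id)
  known <- chosen %in% fid
  if (any(!known)) {
    message("dropping ", sum(!known),
      " woman/women with unknown chosen facility: ",
      paste(women$woman_id[!known], collapse = ", "))
    women <- women[known, , drop = FALSE]
  }
  if (!is.null(caseCovs)) {
    miss <- setdiff(caseCovs, colnames(women))
    if (length(miss))
      stop("unknown case covariate(s): ", paste(miss, collapse = ", "),
        call. = FALSE)
    ok <- stats::complete.cases(women[, caseCovs, drop = FALSE])
    if (any(!ok)) {
      message("dropping ", sum(!ok),
        " woman/women with missing case covariates")
      women <- women[ok, , drop = FALSE]
    }
  }
  if (nrow(women) == 0L) stop("no usable cases left", call. = FALSE)
  wid <- as.character(women$woman_id)
  km <- distances(dm)
  if (!all(wid %in% rownames(km)) || !all(fid %in% colnames(km)))
    stop("distance matrix does not cover all women and facilities",
      call. = FALSE)
  km <- km[wid, fid, drop = FALSE]
  dmSub <- new("DistanceMatrix", km = km, source = distanceSource(dm))
  assays <- attributeMatrices(dmSub, facilities, attributes, stock, surveyDate)
  for (a in attributes) {
    if (all(assays[[a]] == assays[[a]][, 1L]))  # every row constant
      stop("attribute '", a, "' does not vary across alternatives; ",
        "it cannot be identified in a conditional logit", call. = FALSE)
  }
  if (is.null(groups)) {
    groups <- factor(ifelse(facilities$ftype == "hospital",
      "hospital", "other"), levels = c("other", "hospital"))
  } else {
    groups <- as.factor(groups)
    if (length(groups) != J)
      stop("'groups' must have one entry per facility", call. = FALSE)
  }
  rd <- S4Vectors::DataFrame(row.names = wid)
  for (cv in caseCovs) rd[[cv]] <- factorIfCategorical(women[[cv]], cv)
  rd$chosen <- as.character(women$chosen_facility_id)
  cd <- S4Vectors::DataFrame(group = groups, row.names = fid)
  if (!is.null(facilities$ftype)) cd$ftype <- as.character(facilities$ftype)
  new("ChoiceDesign", SummarizedExperiment(assays = assays,
    rowData = rd, colData = cd))
}

## Categorical case covariates use the package's canonical level orders so
## the reference level is substantively meaningful (no education, poorest).
factorIfCategorical <- function(x, name = "") {
  if (is.factor(x)) return(x)
  if (!is.character(x)) return(x)
  lev <- switch(name, education = EDUCATION_LEVELS,
    wealth_quintile = WEALTH_LEVELS, sort(unique(x)))
  factor(x, levels = intersect(lev, unique(x)))
}

## One case x alternative matrix per alternative-varying attribute; shared
## between the design builder and the choice simulator so simulated and
## fitted utilities use identical covariates.
attributeMatrices <- function(dm, facilities, attributes,
    stock = NULL, surveyDate = NULL) {
  km <- distances(dm)
  n <- nrow(km); J <- ncol(km)
  nMeth <- if (!is.null(stock) && !is.null(surveyDate))
    as.numeric(effectiveFpMethods(facilities, stock, surveyDate))
  else lengths(splitMethods(facilities$methods_provided))
  facRow <- function(x) matrix(as.numeric(x), n, J, byrow = TRUE)
  makers <- list(
    distance = function() km,
    nearest = function() nearestFlags(dm),
    n_fp_methods = function() facRow(nMeth),
    n_other_services = function() facRow(facilities$n_other_services),
    hospital = function() facRow(facilities$ftype == "hospital"),
    charges_fee = function() facRow(facilities$charges_fee),
    open_weekends = function() facRow(facilities$open_weekends),
    female_only_providers = function() facRow(facilities$female_only_providers))
  bad <- setdiff(attributes, names(makers))
  if (length(bad))
    stop("unknown attribute(s): ", paste(bad, collapse = ", "), call. = FALSE)
  assays <- lapply(attributes, function(a) {
    m <- makers[[a]]()
    dimnames(m) <- dimnames(km)
    m
  })
  names(assays) <- attributes
  assays
}

#' Conditional logit choice probabilities
#'
#' \deqn{P_{ij} = \exp(V_{ij}) / \sum_k \exp(V_{ik})}
#' with \eqn{V_{ij} = \sum_m \beta_m x_{ijm} + \sum_p \lambda_{g(j)p}
#' Z_{ip}}, evaluated with per-case max subtraction so large utilities do
#' not overflow. Rows sum to one.
#'
#' @param design a \linkS4class{ChoiceDesign}.
#' @param params a \linkS4class{UtilityParams}.
#' @return numeric matrix (cases x alternatives) of probabilities.
#' @export
choiceProbabilities <- function(design, params) {
  tm <- designTermMatrices(design)
  theta <- paramsToVector(params, tm)
  V <- utilityMatrix(tm, theta)
  if (any(!is.finite(V))) {
    bad <- rownames(design)[rowSums(!is.finite(V)) > 0][1L]
    stop("non-finite utility for case ", bad, call. = FALSE)
  }
  P <- softmaxRows(V)
  dimnames(P) <- dimnames(design)
  P
}

chosenIndex <- function(design) {
  match(chosenAlternative(design), colnames(design))
}

logLikFromTheta <- function(tm, theta, chIdx) {
  V <- utilityMatrix(tm, theta)
  m <- rowMax(V)
  sum(V[cbind(seq_along(chIdx), chIdx)] - m - log(rowSums(exp(V - m))))
}

scoreFromTheta <- function(tm, theta, chIdx) {
  P <- softmaxRows(utilityMatrix(tm, theta))
  n <- length(chIdx)
  ii <- cbind(seq_len(n), chIdx)
  vapply(tm$mats, function(X) sum(X[ii]) - sum(P * X), numeric(1))
}

## Observed information of the conditional logit (equals expected here):
## sum_i X_i' (diag(p_i) - p_i p_i') X_i, vectorised over cases.
informationFromTheta <- function(tm, theta) {
  P <- softmaxRows(utilityMatrix(tm, theta))
  K <- length(tm$mats)
  A <- vapply(tm$mats, function(X) rowSums(P * X), numeric(nrow(P)))
  H <- matrix(0, K, K, dimnames = list(names(tm$mats), names(tm$mats)))
  for (k in seq_len(K)) {
    PXk <- P * tm$mats[[k]]
    for (l in k:K)
      H[k, l] <- H[l, k] <- sum(PXk * tm$mats[[l]]) - sum(A[, k] * A[, l])
  }
  H
}

#' Log-likelihood of a conditional logit
#'
#' \eqn{\ell = \sum_i \log P_{i,chosen(i)}}.
#'
#' @inheritParams choiceProbabilities
#' @return scalar log-likelihood.
#' @export
choiceLogLik <- function(design, params) {
  tm <- designTermMatrices(design)
  logLikFromTheta(tm, paramsToVector(params, tm), chosenIndex(design))
}

#' Analytic score (gradient of the log-likelihood)
#'
#' \eqn{\sum_i (x_{i,chosen} - \sum_j P_{ij} x_{ij})}, stacked over the
#' beta block then the lambda block (the lambda block uses the
#' group-indicator times covariate products).
#'
#' @inheritParams choiceProbabilities
#' @return named numeric gradient vector.
#' @export
choiceScore <- function(design, params) {
  tm <- designTermMatrices(design)
  scoreFromTheta(tm, paramsToVector(params, tm), chosenIndex(design))
}

#' Fit the alternative-specific conditional logit by maximum likelihood
#'
#' Newton–Raphson on the (concave) conditional logit log-likelihood using
#' the analytic score and observed information, from a zero start by
#' default, with step-halving if a step fails to improve the
#' log-likelihood. Convergence is declared when the score max-norm falls
#' below \code{tol}. The covariance matrix is the inverse observed
#' information at the optimum; confidence intervals and p-values are Wald.
#'
#' @param design a \linkS4class{ChoiceDesign}.
#' @param start optional \linkS4class{UtilityParams} starting values.
#' @param tol convergence tolerance on the score max-norm.
#' @param maxIter maximum Newton iterations.
#' @return a \linkS4class{FitResult}.
#' @examples
#' \dontrun{
#' fit <- fitChoiceModel(design)
#' coefTable(fit)
#' }
#' @export
fitChoiceModel <- function(design, start = NULL, tol = 1e-8, maxIter = 200L) {
  if (nrow(design) < 1L) stop("design has no cases", call. = FALSE)
  tm <- designTermMatrices(design)
  chIdx <- chosenIndex(design)
  K <- length(tm$mats)
  theta <- if (is.null(start)) stats::setNames(numeric(K), names(tm$mats))
    else paramsToVector(start, tm)
  ll <- logLikFromTheta(tm, theta, chIdx)
  converged <- FALSE
  iter <- 0L
  g <- scoreFromTheta(tm, theta, chIdx)
  while (iter < maxIter) {
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    iter <- iter + 1L
    H <- informationFromTheta(tm, theta)
    step <- tryCatch(solve(H, g), error = function(e)
      stop("singular information matrix; check for collinear or ",
        "constant attributes", call. = FALSE))
    stepSize <- 1
    repeat {
      cand <- theta + stepSize * step
      llNew <- logLikFromTheta(tm, cand, chIdx)
      if (is.finite(llNew) && llNew >= ll - 1e-12) break
      stepSize <- stepSize / 2
      if (stepSize < 1e-10) break
    }
    theta <- theta + stepSize * step
    ll <- logLikFromTheta(tm, theta, chIdx)
    g <- scoreFromTheta(tm, theta, chIdx)
  }
  if (!converged && max(abs(g)) < tol) converged <- TRUE
  if (!converged)
    warning("maximum likelihood did not converge in ", maxIter,
      " iterations (|grad| = ", format(max(abs(g)), digits = 3), ")",
      call. = FALSE)
  if (any(abs(theta) > 50))
    warning("very large coefficient(s) (|coef| > 50): possible perfect ",
      "separation", call. = FALSE)
  H <- informationFromTheta(tm, theta)
  vc <- tryCatch(solve(H), error = function(e)
    stop("singular information matrix at the optimum; check for collinear ",
      "or constant attributes", call. = FALSE))
  vc <- (vc + t(vc)) / 2
  dimnames(vc) <- list(names(tm$mats), names(tm$mats))
  new("FitResult", params = vectorToParams(theta, tm),
    coefficients = theta, vcov = vc, loglik = ll, converged = converged,
    nIter = iter, gradNorm = max(abs(g)), nCases = nrow(design),
    nBeta = as.integer(tm$nBeta))
}
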