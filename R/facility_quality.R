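FTYPE_LEVELS <- c("hospital", "fp_health_center", "dispensary")
EDUCATION_LEVELS <- c("none", "primary", "secondary", "above_secondary")
WEALTH_LEVELS <- c("poorest", "poorer", "middle", "richer", "richest")

splitMethods <- function(x) {
  lapply(strsplit(ifelse(is.na(x) | x == "", "", x), ";", fixed = TRUE),
    function(m) unique(trimws(m[nzchar(trimws(m))])))
}

#' Stock-validated count of family planning methods
#'
#' A method counts as effectively available at a facility only when it is
#' both reported as provided and physically present in the facility's stock
#' with an unexpired lot on the survey day. "Within the expiry date" is
#' taken literally: a lot expiring on the survey day still counts.
#'
#' @param facilities data.frame with columns \code{facility_id} and
#'   \code{methods_provided} (\code{";"}-separated method names).
#' @param stock data.frame with columns \code{facility_id, method, expiry}
#'   (ISO-8601 dates).
#' @param surveyDate the survey day (coerced with [as.Date()]).
#' @return named integer vector, one count per facility, in the order of
#'   \code{facilities}.
#' @export
effectiveFpMethods <- function(facilities, stock, surveyDate) {
  surveyDate <- as.Date(surveyDate)
  if (is.na(surveyDate)) stop("unparseable survey date", call. = FALSE)
  expiry <- as.Date(as.character(stock$expiry), format = "%Y-%m-%d")
  if (any(is.na(expiry))) {
    bad <- stock$facility_id[is.na(expiry)]
    stop("unparseable expiry date for facility id(s): ",
      paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  valid <- stock[expiry >= surveyDate, , drop = FALSE]
  validByFac <- split(as.character(valid$method), as.character(valid$facility_id))
  provided <- splitMethods(facilities$methods_provided)
  out <- mapply(function(fid, prov) {
    length(intersect(prov, validByFac[[fid]]))
  }, as.character(facilities$facility_id), provided)
  stats::setNames(as.integer(out), as.character(facilities$facility_id))
}

#' Household wealth index by principal component analysis
#'
#' First principal component of the standardized asset/housing indicators
#' (PCA on the correlation matrix, the DHS convention), with the sign
#' oriented so the sum of loadings is positive — higher score means better
#' off. Scores are cut into quintiles at their 20/40/60/80 percent
#' quantiles; a score exactly on a cut falls in the lower quintile.
#'
#' @param assets numeric matrix or data.frame of indicator columns (binary
#'   or ordinal), one row per household/woman.
#' @return list with \code{score} (numeric), \code{quintile} (ordered
#'   factor poorest..richest), \code{loadings} (named numeric) and
#'   \code{dropped} (names of constant columns removed).
#' @export
wealthIndex <- function(assets) {
  x <- as.matrix(assets)
  storage.mode(x) <- "double"
  if (nrow(x) < 5L) stop("need at least 5 observations", call. = FALSE)
  if (any(is.na(x))) stop("missing values in asset indicators", call. = FALSE)
  sds <- apply(x, 2L, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant indicator column(s): ",
      paste(dropped, collapse = ", "), call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) < 2L)
    stop("need at least 2 indicators with nonzero variance", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  load <- pc$rotation[, 1L]
  if (sum(load) < 0) load <- -load
  score <- drop(scale(x) %*% load)
  cuts <- stats::quantile(score, probs = c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  q <- 1L + findInterval(score, cuts, left.open = TRUE)
  quintile <- factor(WEALTH_LEVELS[q], levels = WEALTH_LEVELS, ordered = TRUE)
  list(score = score, quintile = quintile, loadings = load, dropped = dropped)
}

fmtMeanSd <- function(m, s) sprintf("%.2f±%.2f", m, s)
fmtCount <- function(n, total, digits = 1) {
  sprintf("%d/%d (%s%%)", n, total, formatC(round(100 * n / total, digits),
    format = "f", digits = digits))
}

categoryBlock <- function(block, values, levels) {
  ok <- !is.na(values)
  total <- sum(ok)
  do.call(rbind, lapply(levels, function(lv) {
    n <- sum(values[ok] == lv)
    data.frame(block = block, level = lv, n = n, total = total,
      pct = round(100 * n / total, 1), mean = NA_real_, sd = NA_real_,
      formatted = fmtCount(n, total), stringsAsFactors = FALSE)
  }))
}

numericBlock <- function(block, level, x) {
  data.frame(block = block, level = level, n = sum(!is.na(x)),
    total = sum(!is.na(x)), pct = NA_real_,
    mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE),
    formatted = fmtMeanSd(mean(x, na.rm = TRUE), stats::sd(x, na.rm = TRUE)),
    stringsAsFactors = FALSE)
}

#' Descriptive summary of the women's survey
#'
#' Mean and SD for age and (when a distance matrix is supplied) for the
#' distance to the chosen and to the nearest facility; counts and
#' percentages (one decimal) for education, wealth quintile and the type of
#' facility visited. Denominators per block exclude missing values, so a
#' covariate observed for only part of the sample shows its own total.
#'
#' @param women data.frame of woman records (see [readWomenCsv()]).
#' @param facilities optional facility data.frame, to tabulate the type of
#'   facility each woman chose.
#' @param dm optional \linkS4class{DistanceMatrix} covering the women.
#' @return long data.frame with columns \code{block, level, n, total, pct,
#'   mean, sd, formatted}.
#' @export
summarizeWomen <- function(women, facilities = NULL, dm = NULL) {
  if (nrow(women) == 0L) stop("no women to summarize", call. = FALSE)
  out <- numericBlock("age_years", "mean", women$age)
  if (!is.null(women$education))
    out <- rbind(out, categoryBlock("education", as.character(women$education),
      EDUCATION_LEVELS))
  if (!is.null(women$wealth_quintile) && any(!is.na(women$wealth_quintile)))
    out <- rbind(out, categoryBlock("wealth_quintile",
      as.character(women$wealth_quintile), WEALTH_LEVELS))
  if (!is.null(facilities) && !is.null(women$chosen_facility_id)) {
    ft <- facilities$ftype[match(as.character(women$chosen_facility_id),
      as.character(facilities$facility_id))]
    out <- rbind(out, categoryBlock("facility_type_visited",
      as.character(ft), FTYPE_LEVELS))
  }
  if (!is.null(dm)) {
    km <- distances(dm)[as.character(women$woman_id), , drop = FALSE]
    nearest <- apply(km, 1L, min)
    out <- rbind(out, numericBlock("distance_nearest_km", "mean", nearest))
    if (!is.null(women$chosen_facility_id)) {
      chosen <- km[cbind(seq_len(nrow(km)),
        match(as.character(women$chosen_facility_id), colnames(km)))]
      out <- rbind(out, numericBlock("distance_chosen_km", "mean", chosen))
    }
  }
  out
}

#' Quality indicators stratified by facility type
#'
#' Mean and SD of the count indicators (family planning methods provided,
#' other services) and counts with percentages of the binary indicators
#' (fee charged, weekend opening, female-only providers), per facility
#' type plus a pooled column over all facilities. The pooled mean equals
#' the count-weighted aggregate of the stratum means. Empty strata are
#' omitted with a note.
#'
#' @param facilities facility data.frame (see [readFacilitiesCsv()]).
#' @param stock optional stock table; together with \code{surveyDate} adds
#'   the stock-validated effective method count as an indicator.
#' @param surveyDate survey day for stock validation.
#' @return long data.frame with columns \code{indicator, stratum, n_stratum,
#'   mean, sd, count, pct, formatted}.
#' @export
summarizeFacilities <- function(facilities, stock = NULL, surveyDate = NULL) {
  if (nrow(facilities) == 0L) stop("no facilities to summarize", call. = FALSE)
  ftype <- factor(as.character(facilities$ftype), levels = FTYPE_LEVELS)
  empty <- FTYPE_LEVELS[!FTYPE_LEVELS %in% ftype]
  if (length(empty))
    message("omitting empty facility stratum/strata: ",
      paste(empty, collapse = ", "))
  strata <- c(as.list(levels(droplevels(ftype))), list(NULL))  # NULL = pooled
  nMethods <- lengths(splitMethods(facilities$methods_provided))
  counts <- list(n_fp_methods = nMethods,
    n_other_services = as.numeric(facilities$n_other_services))
  if (!is.null(stock) && !is.null(surveyDate))
    counts$n_fp_methods_in_stock <-
      as.numeric(effectiveFpMethods(facilities, stock, surveyDate))
  binaries <- list(charges_fee = facilities$charges_fee,
    open_weekends = facilities$open_weekends,
    female_only_providers = facilities$female_only_providers)
  rows <- list()
  for (s in strata) {
    keep <- if (is.null(s)) rep(TRUE, nrow(facilities)) else ftype == s
    lab <- if (is.null(s)) "total" else s
    ns <- sum(keep)
    for (nm in names(counts)) {
      x <- counts[[nm]][keep]
      s_ <- if (ns > 1L) stats::sd(x) else 0
      rows[[length(rows) + 1L]] <- data.frame(indicator = nm, stratum = lab,
        n_stratum = ns, mean = mean(x), sd = s_, count = NA_integer_,
        pct = NA_real_, formatted = fmtMeanSd(mean(x), s_),
        stringsAsFactors = FALSE)
    }
    for (nm in names(binaries)) {
      k <- sum(binaries[[nm]][keep] == 1)
      rows[[length(rows) + 1L]] <- data.frame(indicator = nm, stratum = lab,
        n_stratum = ns, mean = NA_real_, sd = NA_real_, count = k,
        pct = round(100 * k / ns, 2),
        formatted = sprintf("%d (%.2f%%)", k, 100 * k / ns),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
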