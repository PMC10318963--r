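readCsvStrict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

requireColumns <- function(df, cols, path) {
  miss <- setdiff(cols, colnames(df))
  if (length(miss))
    stop("file ", path, " is missing column(s): ",
      paste(miss, collapse = ", "), call. = FALSE)
}

checkUniqueIds <- function(ids, what, path) {
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    rows <- which(ids %in% dup)
    stop("duplicate ", what, " in ", path, ": ",
      paste(unique(dup), collapse = ", "),
      " (rows ", paste(rows, collapse = ", "), ")", call. = FALSE)
  }
}

## case-insensitive mapping onto a fixed level set, with row numbers in
## the error message
foldLevels <- function(x, levels, what, path) {
  out <- levels[match(tolower(trimws(x)), levels)]
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    stop("invalid ", what, " in ", path, " at row(s) ",
      paste(bad, collapse = ", "), ": ",
      paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  out
}

#' Read the women's survey CSV
#'
#' Expected columns: \code{woman_id, lat, lon, age, education,
#' chosen_facility_id}, optionally \code{wealth_quintile} and any number of
#' asset columns prefixed \code{asset_}. Categorical fields are folded
#' case-insensitively onto the package's level sets; ids must be unique and
#' ages lie in the survey's 16-44 range. At least one of
#' \code{wealth_quintile} / asset columns must be present.
#'
#' @param path CSV path.
#' @return validated data.frame of woman records.
#' @export
readWomenCsv <- function(path) {
  df <- readCsvStrict(path)
  requireColumns(df, c("woman_id", "lat", "lon", "age", "education",
    "chosen_facility_id"), path)
  df$woman_id <- as.character(df$woman_id)
  checkUniqueIds(df$woman_id, "woman_id", path)
  checkCoordinates(df$lat, df$lon, "woman coordinate")
  badAge <- which(!is.na(df$age) & (df$age < 16 | df$age > 44))
  if (length(badAge))
    stop("age outside 16-44 in ", path, " at row(s) ",
      paste(badAge, collapse = ", "), call. = FALSE)
  df$education <- foldLevels(df$education, EDUCATION_LEVELS, "education",
    path)
  hasAssets <- any(grepl("^asset_", colnames(df)))
  if ("wealth_quintile" %in% colnames(df)) {
    df$wealth_quintile <- foldLevels(df$wealth_quintile, WEALTH_LEVELS,
      "wealth_quintile", path)
  } else if (!hasAssets) {
    stop("file ", path, " must contain 'wealth_quintile' or asset_* ",
      "columns", call. = FALSE)
  }
  df$chosen_facility_id <- as.character(df$chosen_facility_id)
  df
}

#' Read the facility survey CSV
#'
#' Expected columns: \code{facility_id, lat, lon, ftype, methods_provided}
#' (\code{";"}-separated), \code{n_other_services, charges_fee,
#' open_weekends, female_only_providers}.
#'
#' @param path CSV path.
#' @return validated data.frame of facility records.
#' @export
readFacilitiesCsv <- function(path) {
  df <- readCsvStrict(path)
  requireColumns(df, c("facility_id", "lat", "lon", "ftype",
    "methods_provided", "n_other_services", "charges_fee", "open_weekends",
    "female_only_providers"), path)
  df$facility_id <- as.character(df$facility_id)
  checkUniqueIds(df$facility_id, "facility_id", path)
  checkCoordinates(df$lat, df$lon, "facility coordinate")
  df$ftype <- foldLevels(df$ftype, FTYPE_LEVELS, "ftype", path)
  badN <- which(is.na(df$n_other_services) | df$n_other_services < 0 |
    df$n_other_services != round(df$n_other_services))
  if (length(badN))
    stop("n_other_services must be a nonnegative integer in ", path,
      " at row(s) ", paste(badN, collapse = ", "), call. = FALSE)
  for (b in c("charges_fee", "open_weekends", "female_only_providers")) {
    bad <- which(!df[[b]] %in% c(0, 1))
    if (length(bad))
      stop(b, " must be 0/1 in ", path, " at row(s) ",
        paste(bad, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read the facility stock CSV
#'
#' Expected columns: \code{facility_id, method, expiry} with ISO-8601
#' expiry dates.
#'
#' @param path CSV path.
#' @return validated data.frame of stock lots.
#' @export
readStockCsv <- function(path) {
  df <- readCsvStrict(path)
  requireColumns(df, c("facility_id", "method", "expiry"), path)
  bad <- which(is.na(as.Date(as.character(df$expiry),
    format = "%Y-%m-%d")))
  if (length(bad))
    stop("unparseable ISO-8601 expiry in ", path, " at row(s) ",
      paste(bad, collapse = ", "), call. = FALSE)
  df$facility_id <- as.character(df$facility_id)
  df$method <- as.character(df$method)
  df
}

#' Read an external distance matrix CSV
#'
#' First column \code{woman_id}; remaining headers are facility ids and
#' cells distances in kilometres.
#'
#' @param path CSV path.
#' @return a \linkS4class{DistanceMatrix} with source \code{"external"}.
#' @export
readDistanceCsv <- function(path) {
  df <- readCsvStrict(path)
  if (colnames(df)[1L] != "woman_id")
    stop("first column of ", path, " must be 'woman_id'", call. = FALSE)
  ids <- as.character(df$woman_id)
  checkUniqueIds(ids, "woman_id", path)
  km <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(km) <- "double"
  rownames(km) <- ids
  if (any(!is.finite(km)) || any(km < 0))
    stop("distances in ", path, " must be finite and >= 0", call. = FALSE)
  new("DistanceMatrix", km = km, source = "external")
}

#' Write the model fit report
#'
#' CSV with one row per coefficient (\code{term, estimate, se, ci_low,
#' ci_high, p}) plus a plain-text companion table with estimates and
#' confidence limits to two decimals.
#'
#' @param fit a \linkS4class{FitResult}.
#' @param path output CSV path; the text table goes to the same path with
#'   extension \code{.txt}.
#' @return invisibly, the inference data.frame.
#' @export
writeFitReport <- function(fit, path) {
  tab <- coefTable(fit)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  txt <- sprintf("%-28s %8.2f  [%6.2f, %6.2f]  p=%s", tab$term,
    tab$estimate, tab$ci_low, tab$ci_high, formatPValue(tab$p))
  writeLines(c(sprintf("%-28s %8s  %16s  %s", "term", "coef", "95% CI", "p"),
    txt), sub("\\.csv$", ".txt", path))
  invisible(tab)
}

#' Write the willingness-to-travel report
#'
#' CSV \code{attribute, km, se, ci_low, ci_high} plus a plain-text table
#' with kilometres to one decimal.
#'
#' @param wtt data.frame from [wttTable()].
#' @param path output CSV path.
#' @return invisibly, \code{wtt}.
#' @export
writeWttReport <- function(wtt, path) {
  utils::write.csv(wtt, path, row.names = FALSE, quote = FALSE)
  txt <- sprintf("%-28s %6.1f km  [%6.1f, %6.1f]", wtt$attribute, wtt$km,
    wtt$ci_low, wtt$ci_high)
  writeLines(c(sprintf("%-28s %9s  %s", "attribute", "km/unit", "95% CI"),
    txt), sub("\\.csv$", ".txt", path))
  invisible(wtt)
}

#' Run the full analysis pipeline
#'
#' Reads (or simulates) a study, then chains the stages: distance matrix,
#' descriptive summaries of women and facilities, conditional logit fit,
#' and willingness-to-travel table, writing all reports to \code{outDir}.
#' When \code{womenCsv} is \code{NULL}, a synthetic study is generated
#' under \code{outDir/data} first — a seed is then required.
#'
#' @param womenCsv,facilitiesCsv,stockCsv paths to the input tables;
#'   \code{NULL} to simulate instead.
#' @param distanceCsv optional external distance matrix CSV; when absent,
#'   straight-line haversine distances are computed from coordinates.
#' @param outDir output directory for reports.
#' @param caseCovs case covariates interacted with the facility grouping
#'   (default education and wealth quintile).
#' @param wttAttrs attributes to report willingness-to-travel for.
#' @param surveyDate survey day for stock validation.
#' @param seed integer seed, required when simulating.
#' @param cfg optional [simConfig()] overriding \code{seed} for simulation.
#' @return invisibly, a list with the tables, design, fit and reports.
#' @export
runPipeline <- function(womenCsv = NULL, facilitiesCsv = NULL,
    stockCsv = NULL, distanceCsv = NULL, outDir = ".",
    caseCovs = c("education", "wealth_quintile"),
    wttAttrs = c("n_fp_methods", "n_other_services",
      "female_only_providers"),
    surveyDate = as.Date("2018-03-01"), seed = NULL, cfg = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(womenCsv)) {
    if (is.null(cfg)) {
      if (is.null(seed))
        stop("a seed is required to simulate a study", call. = FALSE)
      cfg <- simConfig(seed = seed)
    }
    ds <- generateDataset(cfg, file.path(outDir, "data"))
    womenCsv <- ds$paths$women
    facilitiesCsv <- ds$paths$facilities
    stockCsv <- ds$paths$stock
    distanceCsv <- ds$paths$distances
    surveyDate <- cfg$surveyDate
  }
  women <- readWomenCsv(womenCsv)
  facilities <- readFacilitiesCsv(facilitiesCsv)
  stock <- if (!is.null(stockCsv)) readStockCsv(stockCsv) else NULL
  dm <- if (!is.null(distanceCsv))
    buildDistanceMatrix(women, facilities, readDistanceCsv(distanceCsv))
  else buildDistanceMatrix(women, facilities)
  message("pipeline: ", nrow(women), " women, ", nrow(facilities),
    " facilities, distance source '", distanceSource(dm), "'")
  womenSummary <- summarizeWomen(women, facilities, dm)
  facSummary <- summarizeFacilities(facilities, stock, surveyDate)
  utils::write.csv(womenSummary, file.path(outDir, "summary_women.csv"),
    row.names = FALSE)
  utils::write.csv(facSummary, file.path(outDir, "summary_facilities.csv"),
    row.names = FALSE)
  design <- buildDesign(women, facilities, dm, caseCovs = caseCovs,
    stock = stock, surveyDate = surveyDate)
  fit <- fitChoiceModel(design)
  writeFitReport(fit, file.path(outDir, "fit_report.csv"))
  wtt <- wttTable(fit, wttAttrs)
  writeWttReport(wtt, file.path(outDir, "wtt_report.csv"))
  invisible(list(women = women, facilities = facilities, stock = stock,
    dm = dm, design = design, fit = fit, wtt = wtt,
    womenSummary = womenSummary, facilitySummary = facSummary))
}
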