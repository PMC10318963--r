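FP_METHOD_NAMES <- c("pill", "condom", "injectable", "iud", "implant",
  "emergency_pill", "female_sterilization", "male_sterilization", "lam")

## km per degree of latitude on the package's reference sphere; used to
## convert the simulator's exact planar km coordinates to pseudo lat/lon
## near the equator, where haversine and planar distances agree closely.
KM_PER_DEGREE <- pi * EARTH_RADIUS_KM / 180

#' Configuration of a synthetic facility-choice study
#'
#' Defines the study conditions the simulator reproduces: a cross-sectional
#' survey of married women of reproductive age clustered in an urban
#' region, a set of surveyed facilities with quality indicators at the
#' observed margins, and choices generated by Gumbel-error utility
#' maximisation at the published coefficient values. Defaults emulate the
#' study this package was built around: 336 women in 110 clusters choosing
#' among 28 facilities (12 hospitals, 15 family planning/health centers,
#' 1 dispensary).
#'
#' @param seed integer seed; required — every simulation is reproducible.
#' @param nWomen,nFacilities,nClusters study sizes.
#' @param regionKm width and height of the rectangular study region, km.
#' @param clusterSdKm isotropic within-cluster scatter of homes, km.
#' @param typeShares facility-type probabilities (hospital,
#'   fp_health_center, dispensary).
#' @param fpMethodsMean mean number of stock-valid family planning methods
#'   per facility (truncated Poisson, 0-9).
#' @param otherServicesMean mean number of other services (truncated
#'   Poisson, 0-12).
#' @param feeProb,weekendProb,femaleOnlyProb Bernoulli probabilities of the
#'   binary quality indicators.
#' @param expiredExtraProb probability a facility also reports one extra
#'   method whose only stock lot has expired (exercises stock validation).
#' @param educationShares probabilities of the four education levels.
#' @param nAssets number of binary household asset indicators to draw for
#'   the wealth index.
#' @param surveyDate nominal survey day used for stock validation.
#' @param trueParams \linkS4class{UtilityParams} generating the choices;
#'   default: the published coefficient values with no case-covariate
#'   interactions.
#' @return a validated list of class \code{SimConfig}.
#' @export
simConfig <- function(seed,
    nWomen = 336L, nFacilities = 28L, nClusters = 110L,
    regionKm = c(20, 20), clusterSdKm = 0.3,
    typeShares = c(hospital = 12 / 28, fp_health_center = 15 / 28,
      dispensary = 1 / 28),
    fpMethodsMean = 4.29, otherServicesMean = 4.82,
    feeProb = 0.5714, weekendProb = 0.61, femaleOnlyProb = 0.43,
    expiredExtraProb = 0.25,
    educationShares = c(none = 0.354, primary = 0.158, secondary = 0.366,
      above_secondary = 0.122),
    nAssets = 8L,
    surveyDate = as.Date("2018-03-01"),
    trueParams = utilityParams(c(distance = -0.17, nearest = 1.16,
      n_fp_methods = 0.27, n_other_services = 0.23, hospital = 0.90,
      charges_fee = 0.21, open_weekends = 0.43,
      female_only_providers = 1.89))) {
  if (missing(seed))
    stop("a seed is required: simulations must be reproducible",
      call. = FALSE)
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1L, !is.na(seed))
  if (nWomen < 0 || nFacilities < 1 || nClusters < 1)
    stop("counts must be positive (nWomen may be 0 only to be rejected ",
      "downstream)", call. = FALSE)
  probs <- c(feeProb, weekendProb, femaleOnlyProb, expiredExtraProb)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(sum(typeShares) - 1) > 1e-8 ||
      abs(sum(educationShares) - 1) > 1e-8)
    stop("type and education shares must each sum to 1", call. = FALSE)
  structure(list(seed = seed, nWomen = as.integer(nWomen),
    nFacilities = as.integer(nFacilities), nClusters = as.integer(nClusters),
    regionKm = regionKm, clusterSdKm = clusterSdKm, typeShares = typeShares,
    fpMethodsMean = fpMethodsMean, otherServicesMean = otherServicesMean,
    feeProb = feeProb, weekendProb = weekendProb,
    femaleOnlyProb = femaleOnlyProb, expiredExtraProb = expiredExtraProb,
    educationShares = educationShares, nAssets = as.integer(nAssets),
    surveyDate = as.Date(surveyDate), trueParams = trueParams),
    class = "SimConfig")
}

rpoisTrunc <- function(n, mean, upper) {
  x <- stats::rpois(n, mean)
  while (any(x > upper)) x[x > upper] <- stats::rpois(sum(x > upper), mean)
  x
}

#' Simulate the facility survey
#'
#' Facilities are placed uniformly on the study region (planar km
#' coordinates, also expressed as pseudo WGS84 degrees near the equator),
#' typed multinomially, and given quality indicators at the configured
#' margins: truncated-Poisson counts of stock-valid family planning methods
#' and of other services, and Bernoulli fee/weekend/female-only flags.
#' Each stock-valid method gets a stock lot expiring after the survey day;
#' some facilities also report one extra method with only an expired lot,
#' so the stock-validation rule has something to do.
#'
#' @param cfg a [simConfig()].
#' @return list with \code{facilities} (data.frame) and \code{stock}
#'   (data.frame \code{facility_id, method, expiry}).
#' @export
simulateFacilities <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed + 1L)
  J <- cfg$nFacilities
  id <- sprintf("f%03d", seq_len(J))
  x <- stats::runif(J, 0, cfg$regionKm[1])
  y <- stats::runif(J, 0, cfg$regionKm[2])
  ftype <- sample(names(cfg$typeShares), J, replace = TRUE,
    prob = cfg$typeShares)
  kValid <- rpoisTrunc(J, cfg$fpMethodsMean, 9L)
  nServ <- rpoisTrunc(J, cfg$otherServicesMean, 12L)
  fee <- stats::rbinom(J, 1L, cfg$feeProb)
  weekend <- stats::rbinom(J, 1L, cfg$weekendProb)
  femOnly <- stats::rbinom(J, 1L, cfg$femaleOnlyProb)
  provided <- character(J)
  stockRows <- vector("list", J)
  for (j in seq_len(J)) {
    valid <- sample(FP_METHOD_NAMES, kValid[j])
    meths <- valid
    expiry <- cfg$surveyDate + sample(30:720, length(valid), replace = TRUE)
    if (kValid[j] < length(FP_METHOD_NAMES) &&
        stats::runif(1) < cfg$expiredExtraProb) {
      extra <- sample(setdiff(FP_METHOD_NAMES, valid), 1L)
      meths <- c(meths, extra)
      expiry <- c(expiry, cfg$surveyDate - sample(1:360, 1L))
    }
    provided[j] <- paste(meths, collapse = ";")
    stockRows[[j]] <- if (length(meths))
      data.frame(facility_id = id[j], method = meths,
        expiry = as.character(expiry), stringsAsFactors = FALSE)
  }
  facilities <- data.frame(facility_id = id,
    lat = y / KM_PER_DEGREE, lon = x / KM_PER_DEGREE,
    x_km = x, y_km = y, ftype = ftype, methods_provided = provided,
    n_other_services = nServ, charges_fee = fee, open_weekends = weekend,
    female_only_providers = femOnly, stringsAsFactors = FALSE)
  stock <- do.call(rbind, Filter(Negate(is.null), stockRows))
  if (is.null(stock))
    stock <- data.frame(facility_id = character(0), method = character(0),
      expiry = character(0), stringsAsFactors = FALSE)
  list(facilities = facilities, stock = stock)
}

#' Simulate the women's survey (choices unset)
#'
#' Emulates the multi-stage cluster sample: cluster centres uniform on the
#' region, women assigned to clusters multinomially, homes scattered around
#' the centre with isotropic Gaussian noise. Education is drawn at the
#' configured shares, age uniformly on 16-44 years, and binary household
#' assets from a latent socioeconomic gradient; the wealth quintile is the
#' package's own PCA index of those assets.
#'
#' @param cfg a [simConfig()].
#' @return data.frame of woman records with \code{chosen_facility_id} set
#'   to \code{NA} (see [simulateChoices()]).
#' @export
simulateWomen <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (cfg$nWomen == 0L) stop("empty study", call. = FALSE)
  set.seed(cfg$seed + 2L)
  n <- cfg$nWomen
  cx <- stats::runif(cfg$nClusters, 0, cfg$regionKm[1])
  cy <- stats::runif(cfg$nClusters, 0, cfg$regionKm[2])
  cl <- sample.int(cfg$nClusters, n, replace = TRUE)
  x <- cx[cl] + stats::rnorm(n, 0, cfg$clusterSdKm)
  y <- cy[cl] + stats::rnorm(n, 0, cfg$clusterSdKm)
  edu <- sample(names(cfg$educationShares), n, replace = TRUE,
    prob = cfg$educationShares)
  age <- sample(16:44, n, replace = TRUE)
  ses <- stats::rnorm(n)
  shift <- seq(-1.5, 1.5, length.out = cfg$nAssets)
  assets <- vapply(seq_len(cfg$nAssets), function(k)
    stats::rbinom(n, 1L, stats::plogis(1.2 * ses + shift[k])), integer(n))
  colnames(assets) <- sprintf("asset_%02d", seq_len(cfg$nAssets))
  wi <- wealthIndex(assets)
  women <- data.frame(woman_id = sprintf("w%04d", seq_len(n)),
    lat = y / KM_PER_DEGREE, lon = x / KM_PER_DEGREE,
    x_km = x, y_km = y, cluster = cl, age = age, education = edu,
    wealth_quintile = as.character(wi$quintile),
    chosen_facility_id = NA_character_, stringsAsFactors = FALSE)
  cbind(women, as.data.frame(assets))
}

#' Exact planar distance matrix from simulated km coordinates
#'
#' The simulator works in planar kilometres, so within a synthetic study
#' the distance geometry is exact rather than subject to the small
#' curvature error of converting through pseudo lat/lon.
#'
#' @param women,facilities simulated tables carrying \code{x_km, y_km}.
#' @return a \linkS4class{DistanceMatrix} with source \code{"planar"}.
#' @export
planarDistanceMatrix <- function(women, facilities) {
  stopifnot(!is.null(women$x_km), !is.null(facilities$x_km))
  km <- outer(seq_len(nrow(women)), seq_len(nrow(facilities)), function(i, j)
    sqrt((women$x_km[i] - facilities$x_km[j])^2 +
         (women$y_km[i] - facilities$y_km[j])^2))
  dimnames(km) <- list(as.character(women$woman_id),
    as.character(facilities$facility_id))
  new("DistanceMatrix", km = km, source = "planar")
}

## Dummy-expand the women's factor columns to match lambda column names
## of the form <column>_<level> (reference level omitted).
expandCaseColumns <- function(women, lamCovs) {
  cols <- list()
  for (cv in intersect(c("education", "wealth_quintile"), colnames(women))) {
    lev <- if (cv == "education") EDUCATION_LEVELS else WEALTH_LEVELS
    x <- factor(as.character(women[[cv]]), levels = lev)
    for (l in lev[-1L]) cols[[paste0(cv, "_", l)]] <- as.numeric(x == l)
  }
  miss <- setdiff(lamCovs, names(cols))
  if (length(miss))
    stop("cannot expand case covariate term(s): ",
      paste(miss, collapse = ", "), call. = FALSE)
  cols[lamCovs]
}

#' Simulate utility-maximising facility choices
#'
#' Each woman receives utility \eqn{u_{ij} = V_{ij} + \varepsilon_{ij}}
#' with independent standard Gumbel errors (the conditional logit's
#' implicit normalisation: error variance \eqn{\pi^2/6}) and chooses the
#' facility with the highest utility. The systematic part uses exactly the
#' attribute construction of [buildDesign()], so fitted and generating
#' utilities agree. Exact ties, impossible almost surely, would go to the
#' smallest facility id.
#'
#' @param women,facilities simulated (or read) survey tables.
#' @param dm \linkS4class{DistanceMatrix} covering all pairs.
#' @param params \linkS4class{UtilityParams} generating utilities.
#' @param seed integer seed; required.
#' @param stock,surveyDate optional, for the stock-validated method count
#'   (used by default in synthetic studies).
#' @param groups optional facility group factor for lambda interactions.
#' @return \code{women} with \code{chosen_facility_id} filled in.
#' @export
simulateChoices <- function(women, facilities, dm, params, seed,
    stock = NULL, surveyDate = NULL, groups = NULL) {
  if (missing(seed))
    stop("a seed is required: simulations must be reproducible",
      call. = FALSE)
  set.seed(as.integer(seed))
  wid <- as.character(women$woman_id)
  fid <- as.character(facilities$facility_id)
  km <- distances(dm)[wid, fid, drop = FALSE]
  dmSub <- new("DistanceMatrix", km = km, source = distanceSource(dm))
  mats <- attributeMatrices(dmSub, facilities, names(params@beta),
    stock, surveyDate)
  V <- matrix(0, nrow(km), ncol(km))
  for (a in names(params@beta))
    V <- V + params@beta[[a]] * mats[[a]]
  if (length(params@lambda) && any(params@lambda != 0)) {
    if (is.null(groups))
      groups <- factor(ifelse(facilities$ftype == "hospital",
        "hospital", "other"), levels = c("other", "hospital"))
    covs <- expandCaseColumns(women, colnames(params@lambda))
    for (g in intersect(rownames(params@lambda), levels(groups))) {
      ind <- as.numeric(groups == g)
      for (p in colnames(params@lambda))
        V <- V + params@lambda[g, p] * outer(covs[[p]], ind)
    }
  }
  eps <- -log(-log(stats::runif(length(V))))
  u <- V + eps
  ord <- order(fid)   # ties (a.s. impossible) to smallest facility id
  pick <- ord[apply(u[, ord, drop = FALSE], 1L, which.max)]
  women$chosen_facility_id <- fid[pick]
  women
}

#' Generate a complete synthetic study on disk
#'
#' Runs the whole generator — facilities, stock, clustered women, planar
#' distance matrix, utility-maximising choices — and writes the four CSV
#' files in the package's documented dialects plus a JSON manifest
#' recording the configuration and seed. The distance file preserves the
#' simulator's exact planar geometry and can be fed back as the external
#' distance matrix.
#'
#' @param cfg a [simConfig()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the in-memory tables, the
#'   \linkS4class{DistanceMatrix} and the file paths.
#' @export
generateDataset <- function(cfg, dir) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (cfg$nWomen == 0L) stop("empty study", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir,
    call. = FALSE)
  fac <- simulateFacilities(cfg)
  women <- simulateWomen(cfg)
  dm <- planarDistanceMatrix(women, fac$facilities)
  women <- simulateChoices(women, fac$facilities, dm, cfg$trueParams,
    seed = cfg$seed + 3L, stock = fac$stock, surveyDate = cfg$surveyDate)
  paths <- list(women = file.path(dir, "women.csv"),
    facilities = file.path(dir, "facilities.csv"),
    stock = file.path(dir, "stock.csv"),
    distances = file.path(dir, "distances.csv"),
    manifest = file.path(dir, "manifest.json"))
  womenOut <- women[, c("woman_id", "lat", "lon", "age", "education",
    "wealth_quintile", "chosen_facility_id",
    grep("^asset_", colnames(women), value = TRUE))]
  utils::write.csv(womenOut, paths$women, row.names = FALSE, quote = FALSE)
  facOut <- fac$facilities[, c("facility_id", "lat", "lon", "ftype",
    "methods_provided", "n_other_services", "charges_fee", "open_weekends",
    "female_only_providers")]
  utils::write.csv(facOut, paths$facilities, row.names = FALSE, quote = FALSE)
  utils::write.csv(fac$stock, paths$stock, row.names = FALSE, quote = FALSE)
  dOut <- data.frame(woman_id = rownames(distances(dm)),
    distances(dm), check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(dOut, paths$distances, row.names = FALSE, quote = FALSE)
  manifest <- list(seed = cfg$seed, nWomen = cfg$nWomen,
    nFacilities = cfg$nFacilities, nClusters = cfg$nClusters,
    regionKm = cfg$regionKm, clusterSdKm = cfg$clusterSdKm,
    surveyDate = as.character(cfg$surveyDate),
    trueBeta = as.list(cfg$trueParams@beta),
    files = lapply(paths, basename))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
    digits = NA), paths$manifest)
  invisible(list(women = women, facilities = fac$facilities,
    stock = fac$stock, dm = dm, paths = paths))
}
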