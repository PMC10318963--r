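test_that("the configuration validates its margins and requires a seed", {
  expect_error(simConfig(), "seed is required")
  expect_error(simConfig(seed = 1, feeProb = 1.2), "\\[0, 1\\]")
  expect_error(simConfig(seed = 1,
    typeShares = c(hospital = 0.5, fp_health_center = 0.4,
      dispensary = 0.3)), "sum to 1")
  cfg <- simConfig(seed = 1)
  expect_identical(cfg$nWomen, 336L)
  expect_identical(cfg$nFacilities, 28L)
  expect_identical(cfg$nClusters, 110L)
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- simConfig(seed = 77, nWomen = 40, nFacilities = 6)
  f1 <- simulateFacilities(cfg)
  f2 <- simulateFacilities(cfg)
  expect_identical(f1, f2)
  w1 <- simulateWomen(cfg)
  expect_identical(w1, simulateWomen(cfg))
  dm <- planarDistanceMatrix(w1, f1$facilities)
  c1 <- simulateChoices(w1, f1$facilities, dm, cfg$trueParams, seed = 5)
  c2 <- simulateChoices(w1, f1$facilities, dm, cfg$trueParams, seed = 5)
  expect_identical(c1, c2)
  expect_error(simulateChoices(w1, f1$facilities, dm, cfg$trueParams),
    "seed is required")
})

test_that("facility margins match the configured probabilities", {
  cfg <- simConfig(seed = 83, nFacilities = 10000)
  fac <- simulateFacilities(cfg)$facilities
  share <- mean(fac$charges_fee)
  expect_gt(share, 0.56)   # binomial CI around p = 0.5714 at n = 10,000
  expect_lt(share, 0.59)
  expect_true(all(fac$ftype %in% c("hospital", "fp_health_center",
    "dispensary")))
  nMeth <- lengths(strsplit(fac$methods_provided, ";"))
  expect_true(all(nMeth <= 9))
  # single facility still yields a valid record
  one <- simulateFacilities(simConfig(seed = 84, nFacilities = 1))
  expect_identical(nrow(one$facilities), 1L)
  expect_gte(nrow(one$stock), 0L)
})

test_that("the stock-validated method count keeps its configured mean", {
  cfg <- simConfig(seed = 85, nFacilities = 4000)
  fac <- simulateFacilities(cfg)
  eff <- effectiveFpMethods(fac$facilities, fac$stock, cfg$surveyDate)
  # oracle: closed-form mean of a Poisson(4.29) truncated to 0..9
  truncMean <- sum(0:9 * dpois(0:9, 4.29)) / ppois(9, 4.29)
  expect_lt(abs(mean(eff) - truncMean), 0.1)   # ~3 SE at n = 4000
  # the reported list is occasionally longer than the valid stock
  provided <- lengths(strsplit(fac$facilities$methods_provided, ";"))
  expect_gt(sum(provided > eff), 0)
})

test_that("women's sample emulates clustered geography and margins", {
  cfg <- simConfig(seed = 91, nWomen = 10000, nClusters = 110)
  w <- simulateWomen(cfg)
  noEdu <- mean(w$education == "none")
  expect_gt(noEdu, 0.34)   # binomial CI around 0.354 at n = 10,000
  expect_lt(noEdu, 0.37)
  expect_true(all(w$age >= 16 & w$age <= 44))
  # support: within the region padded by 5 within-cluster SDs
  pad <- 5 * cfg$clusterSdKm
  expect_true(all(w$x_km > -pad & w$x_km < cfg$regionKm[1] + pad))
  expect_true(all(w$y_km > -pad & w$y_km < cfg$regionKm[2] + pad))
  # a single cluster collapses all homes around one centre
  w1 <- simulateWomen(simConfig(seed = 92, nWomen = 200, nClusters = 1))
  expect_lt(max(dist(cbind(w1$x_km, w1$y_km))), 10 * cfg$clusterSdKm)
})

test_that("null-utility choices are uniform over facilities", {
  cfg <- simConfig(seed = 93, nWomen = 50000, nFacilities = 5,
    trueParams = utilityParams(c(distance = 0)))
  fac <- simulateFacilities(cfg)
  w <- simulateWomen(cfg)
  dm <- planarDistanceMatrix(w, fac$facilities)
  w <- simulateChoices(w, fac$facilities, dm, cfg$trueParams, seed = 94)
  tab <- table(w$chosen_facility_id)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("an overwhelming distance penalty forces the nearest facility", {
  cfg <- simConfig(seed = 95, nWomen = 300, nFacilities = 8,
    trueParams = utilityParams(c(distance = -100)))
  fac <- simulateFacilities(cfg)
  w <- simulateWomen(cfg)
  dm <- planarDistanceMatrix(w, fac$facilities)
  w <- simulateChoices(w, fac$facilities, dm, cfg$trueParams, seed = 96)
  nearestId <- colnames(distances(dm))[apply(distances(dm), 1, which.min)]
  expect_identical(w$chosen_facility_id, nearestId)
})

test_that("empirical choice frequencies match the analytic probabilities", {
  cfg <- simConfig(seed = 97, nWomen = 50000, nFacilities = 5,
    nClusters = 110)
  fac <- simulateFacilities(cfg)
  w <- simulateWomen(cfg)
  dm <- planarDistanceMatrix(w, fac$facilities)
  w <- simulateChoices(w, fac$facilities, dm, cfg$trueParams, seed = 98,
    stock = fac$stock, surveyDate = cfg$surveyDate)
  d <- buildDesign(w, fac$facilities, dm, stock = fac$stock,
    surveyDate = cfg$surveyDate)
  P <- choiceProbabilities(d, cfg$trueParams)
  expected <- colMeans(P)
  observed <- as.numeric(table(factor(w$chosen_facility_id,
    levels = colnames(d)))) / nrow(d)
  se <- sqrt(expected * (1 - expected) / nrow(d))
  expect_true(all(abs(observed - expected) <= 3 * se))
})

test_that("generateDataset writes a reproducible four-file study", {
  cfg <- simConfig(seed = 99, nWomen = 50, nFacilities = 6, nClusters = 15)
  d1 <- file.path(tempdir(), "study_a")
  d2 <- file.path(tempdir(), "study_b")
  out <- generateDataset(cfg, d1)
  generateDataset(cfg, d2)
  for (f in c("women.csv", "facilities.csv", "stock.csv", "distances.csv",
      "manifest.json"))
    expect_identical(readLines(file.path(d1, f)),
      readLines(file.path(d2, f)))
  expect_identical(length(readLines(out$paths$women)), 51L)
  expect_identical(length(readLines(out$paths$facilities)), 7L)
  manifest <- jsonlite::fromJSON(out$paths$manifest)
  expect_identical(manifest$seed, 99L)
  expect_error(generateDataset(simConfig(seed = 1, nWomen = 0), d1),
    "empty study")
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("bypassing emerges under the published coefficients", {
  cfg <- simConfig(seed = 103)     # full default study: 336 women, 28 fac
  fac <- simulateFacilities(cfg)
  w <- simulateWomen(cfg)
  dm <- planarDistanceMatrix(w, fac$facilities)
  w <- simulateChoices(w, fac$facilities, dm, cfg$trueParams, seed = 104,
    stock = fac$stock, surveyDate = cfg$surveyDate)
  km <- distances(dm)
  nearest <- apply(km, 1, min)
  chosen <- km[cbind(seq_len(nrow(km)),
    match(w$chosen_facility_id, colnames(km)))]
  expect_gt(mean(chosen), mean(nearest))
})
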