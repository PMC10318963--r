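test_that("buildDesign assembles the long-format choice set", {
  st <- tinyStudy(seed = 3, nWomen = 12, nFacilities = 5)
  d <- buildDesign(st$women, st$facilities, st$dm,
    caseCovs = c("education", "wealth_quintile"))
  expect_s4_class(d, "ChoiceDesign")
  expect_identical(dim(d), c(12L, 5L))
  expect_length(assayNames(d), 8L)
  expect_true(all(chosenAlternative(d) %in% colnames(d)))
  expect_identical(levels(alternativeGroups(d)), c("other", "hospital"))
  # a woman choosing an unknown facility is dropped with a message
  w2 <- st$women
  w2$chosen_facility_id[3] <- "f999"
  expect_message(d2 <- buildDesign(w2, st$facilities, st$dm),
    w2$woman_id[3])
  expect_identical(nrow(d2), 11L)
  # unknown attribute name is a configuration error
  expect_error(buildDesign(st$women, st$facilities, st$dm,
    attributes = c("distance", "wifi")), "wifi")
})

test_that("attributes constant across alternatives are rejected", {
  st <- tinyStudy(seed = 8, nWomen = 10, nFacilities = 3)
  fac <- st$facilities
  fac$charges_fee <- 1   # identical for every alternative
  expect_error(
    buildDesign(st$women, fac, st$dm,
      attributes = c("distance", "charges_fee")),
    "does not vary across alternatives")
})

test_that("choice probabilities have the closed conditional-logit form", {
  st <- tinyStudy(seed = 9, nWomen = 25, nFacilities = 5)
  d <- buildDesign(st$women, st$facilities, st$dm)
  # all utilities equal -> uniform over J
  p0 <- choiceProbabilities(d, utilityParams(
    setNames(numeric(8), assayNames(d))))
  expect_equal(unname(p0), matrix(0.2, 25, 5), tolerance = 1e-12)
  # rows always sum to 1 within 1e-12
  set.seed(10)
  for (r in 1:5) {
    pr <- utilityParams(setNames(rnorm(8), assayNames(d)))
    P <- choiceProbabilities(d, pr)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
    expect_true(all(P >= 0))
  }
})

test_that("two-alternative utilities reduce to the logistic closed form", {
  # one attribute taking values (1, 0): V = (beta, 0)
  women <- data.frame(woman_id = c("w1", "w2"), lat = 0, lon = 0,
    chosen_facility_id = "f1")
  fac <- data.frame(facility_id = c("f1", "f2"), lat = c(0, 0.01),
    lon = 0, ftype = c("hospital", "dispensary"),
    methods_provided = "pill", n_other_services = c(1, 0),
    charges_fee = c(1, 0), open_weekends = 0, female_only_providers = 0)
  dm <- buildDistanceMatrix(women, fac)
  d <- buildDesign(women, fac, dm, attributes = "charges_fee")
  P <- choiceProbabilities(d, utilityParams(c(charges_fee = 1)))
  expect_equal(unname(P[1, ]), c(exp(1) / (1 + exp(1)), 1 / (1 + exp(1))),
    tolerance = 1e-6)
  expect_equal(unname(P[1, 1]), 0.731059, tolerance = 1e-6)
})

test_that("probabilities are invariant to per-case utility shifts", {
  st <- tinyStudy(seed = 14, nWomen = 10, nFacilities = 3)
  d <- buildDesign(st$women, st$facilities, st$dm,
    attributes = c("distance", "nearest"))
  pr <- utilityParams(c(distance = -0.3, nearest = 1))
  P1 <- choiceProbabilities(d, pr)
  # adding a constant to every alternative's utility of a case changes
  # nothing: shift the distance attribute by a per-case constant (the
  # vector recycles down rows, so case i moves by -0.3 * shift[i] in every
  # alternative)
  set.seed(1)
  d2 <- d
  assay(d2, "distance") <- assay(d, "distance") + rnorm(10)
  P2 <- choiceProbabilities(d2, pr)
  expect_equal(P1, P2, tolerance = 1e-12)
})

test_that("log-likelihood matches the uniform model and is additive", {
  st <- tinyStudy(seed = 15, nWomen = 10, nFacilities = 5)
  d <- buildDesign(st$women, st$facilities, st$dm)
  zero <- utilityParams(setNames(numeric(8), assayNames(d)))
  expect_equal(choiceLogLik(d, zero), 10 * log(1 / 5), tolerance = 1e-12)
  expect_equal(choiceLogLik(d, zero), -16.0944, tolerance = 1e-4)
  # duplicating every case doubles the log-likelihood and score
  d2 <- rbind(d, d)
  pr <- utilityParams(setNames(rnorm(8, sd = 0.2), assayNames(d)))
  expect_equal(choiceLogLik(d2, pr), 2 * choiceLogLik(d, pr),
    tolerance = 1e-10)
  expect_equal(choiceScore(d2, pr), 2 * choiceScore(d, pr),
    tolerance = 1e-10)
})

test_that("vectorized likelihood equals an explicit per-case loop", {
  set.seed(16)
  for (r in 1:6) {
    st <- tinyStudy(seed = 100 + r, nWomen = 8, nFacilities = 5)
    d <- buildDesign(st$women, st$facilities, st$dm)
    beta <- setNames(rnorm(8, sd = 0.5), assayNames(d))
    expect_equal(choiceLogLik(d, utilityParams(beta)), loopLogLik(d, beta),
      tolerance = 1e-10)
  }
})

test_that("analytic score matches central finite differences", {
  set.seed(17)
  for (r in 1:20) {
    st <- tinyStudy(seed = 200 + r, nWomen = 9, nFacilities = 3)
    withCovs <- r %% 2 == 0
    d <- buildDesign(st$women, st$facilities, st$dm,
      attributes = c("distance", "nearest", "n_fp_methods"),
      caseCovs = if (withCovs) "education" else NULL)
    tmNames <- c("distance", "nearest", "n_fp_methods")
    beta <- setNames(rnorm(3, sd = 0.4), tmNames)
    lam <- matrix(numeric(0), 0, 0,
      dimnames = list(character(0), character(0)))
    if (withCovs && nlevels(alternativeGroups(d)) > 1) {
      # same level order as the design: canonical, reference first
      present <- intersect(c("none", "primary", "secondary",
        "above_secondary"), unique(st$women$education))
      covs <- paste0("education_", present[-1])
      lam <- matrix(rnorm(length(covs), sd = 0.3), 1,
        dimnames = list("hospital", covs))
    }
    pr <- utilityParams(beta, if (length(lam)) lam else NULL)
    analytic <- choiceScore(d, pr)
    numeric_ <- finiteDiffScore(d, pr)
    expect_equal(unname(analytic), numeric_,
      tolerance = 1e-6 * max(1, max(abs(numeric_))))
  }
})

test_that("the MLE matches a brute-force grid search in one dimension", {
  st <- tinyStudy(seed = 19, nWomen = 30, nFacilities = 3,
    params = utilityParams(c(distance = -0.4, nearest = 0,
      n_fp_methods = 0, n_other_services = 0, hospital = 0,
      charges_fee = 0, open_weekends = 0, female_only_providers = 0)))
  d <- buildDesign(st$women, st$facilities, st$dm, attributes = "distance")
  grid <- seq(-5, 5, by = 1e-3)
  ll <- vapply(grid, function(b)
    choiceLogLik(d, utilityParams(c(distance = b))), numeric(1))
  fit <- fitChoiceModel(d)
  expect_true(fit@converged)
  expect_lt(abs(coef(fit)[["distance"]] - grid[which.max(ll)]), 2e-3)
})

test_that("the fitted likelihood dominates the null and matches shares", {
  # six facility-level attributes live in R^J and lose one dimension to
  # per-case centering, so the full attribute set needs J >= 7
  st <- tinyStudy(seed = 23, nWomen = 150, nFacilities = 9)
  d <- buildDesign(st$women, st$facilities, st$dm)
  fit <- fitChoiceModel(d)
  zero <- utilityParams(setNames(numeric(8), assayNames(d)))
  expect_gte(fit@loglik, choiceLogLik(d, zero))
  # score-equation identity: with the hospital dummy in the model, the
  # fitted expected number of hospital choices equals the observed one
  P <- choiceProbabilities(d, fit@params)
  hosp <- assay(d, "hospital")
  observed <- sum(hosp[cbind(seq_len(nrow(d)),
    match(chosenAlternative(d), colnames(d)))])
  expect_equal(sum(P * hosp), observed, tolerance = 1e-6)
})

test_that("estimates are equivariant under affine attribute rescaling", {
  st <- tinyStudy(seed = 27, nWomen = 120, nFacilities = 5)
  d <- buildDesign(st$women, st$facilities, st$dm,
    attributes = c("distance", "nearest", "n_other_services"))
  fit1 <- fitChoiceModel(d)
  d2 <- d
  assay(d2, "distance") <- assay(d, "distance") * 10  # km -> hectometres
  fit2 <- fitChoiceModel(d2)
  expect_equal(coef(fit2)[["distance"]], coef(fit1)[["distance"]] / 10,
    tolerance = 1e-6)
  expect_equal(coef(fit2)[["nearest"]], coef(fit1)[["nearest"]],
    tolerance = 1e-6)
})

test_that("unidentified designs raise a singular-information error", {
  st <- tinyStudy(seed = 29, nWomen = 15, nFacilities = 3)
  d <- buildDesign(st$women, st$facilities, st$dm,
    attributes = c("distance", "nearest"))
  # duplicate attribute -> exactly collinear
  assay(d, "nearest") <- assay(d, "distance")
  expect_error(fitChoiceModel(d), "singular information")
})

test_that("simulated coefficients are recovered within three SEs", {
  cfg <- simConfig(seed = 301, nWomen = 2000, nFacilities = 10,
    nClusters = 110)
  fac <- simulateFacilities(cfg)
  women <- simulateWomen(cfg)
  dm <- planarDistanceMatrix(women, fac$facilities)
  women <- simulateChoices(women, fac$facilities, dm, cfg$trueParams,
    seed = 302, stock = fac$stock, surveyDate = cfg$surveyDate)
  d <- buildDesign(women, fac$facilities, dm, stock = fac$stock,
    surveyDate = cfg$surveyDate)
  fit <- fitChoiceModel(d)
  truth <- cfg$trueParams@beta[names(coef(fit))]
  se <- sqrt(diag(vcov(fit)))
  expect_true(all(abs(coef(fit) - truth) <= 3 * se))
})

test_that("interaction coefficients are estimable and recovered in sign", {
  lam <- matrix(c(1.0, -0.8), 1, 2,
    dimnames = list("hospital", c("education_secondary",
      "education_above_secondary")))
  truthBeta <- c(distance = -0.17, nearest = 1.16, n_fp_methods = 0.27,
    n_other_services = 0.23, hospital = 0.90, charges_fee = 0.21,
    open_weekends = 0.43, female_only_providers = 1.89)
  cfg <- simConfig(seed = 311, nWomen = 3000, nFacilities = 10,
    trueParams = utilityParams(truthBeta, lam))
  fac <- simulateFacilities(cfg)
  women <- simulateWomen(cfg)
  dm <- planarDistanceMatrix(women, fac$facilities)
  women <- simulateChoices(women, fac$facilities, dm, cfg$trueParams,
    seed = 312, stock = fac$stock, surveyDate = cfg$surveyDate)
  d <- buildDesign(women, fac$facilities, dm, caseCovs = "education",
    stock = fac$stock, surveyDate = cfg$surveyDate)
  fit <- fitChoiceModel(d)
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  expect_true(all(abs(est["hospital:education_secondary"] - 1.0) <=
    3 * se["hospital:education_secondary"]))
  expect_true(all(abs(est["hospital:education_above_secondary"] + 0.8) <=
    3 * se["hospital:education_above_secondary"]))
})
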