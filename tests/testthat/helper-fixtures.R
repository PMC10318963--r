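## Facilities reproducing the published quality-indicator margins exactly:
## 12 hospitals (methods sum 52 -> mean 4.33, services sum 71 -> 5.92),
## 15 FP/health centers (63 -> 4.20, 62 -> 4.13), 1 dispensary (5, 2);
## fee 8/7/1, weekend 8/8/1, female-only 5/7/0.
table2Facilities <- function() {
  methodCounts <- c(9, 8, 7, 6, 5, 4, 4, 3, 2, 2, 1, 1,        # hospitals
                    9, 8, 7, 6, 5, 5, 4, 4, 4, 3, 3, 2, 1, 1, 1, # centers
                    5)                                          # dispensary
  serviceCounts <- c(12, 10, 9, 8, 7, 6, 5, 4, 4, 3, 2, 1,
                     8, 7, 6, 6, 5, 5, 4, 4, 4, 3, 3, 3, 2, 1, 1,
                     2)
  ftype <- c(rep("hospital", 12), rep("fp_health_center", 15), "dispensary")
  flag <- function(kHosp, kCent, kDisp) {
    c(rep(1, kHosp), rep(0, 12 - kHosp),
      rep(1, kCent), rep(0, 15 - kCent),
      rep(1, kDisp), rep(0, 1 - kDisp))
  }
  allNames <- c("pill", "condom", "injectable", "iud", "implant",
    "emergency_pill", "female_sterilization", "male_sterilization", "lam")
  data.frame(
    facility_id = sprintf("f%03d", 1:28),
    lat = seq(0, 0.15, length.out = 28),
    lon = seq(0, 0.15, length.out = 28),
    ftype = ftype,
    methods_provided = vapply(methodCounts, function(k)
      paste(allNames[seq_len(k)], collapse = ";"), character(1)),
    n_other_services = serviceCounts,
    charges_fee = flag(8, 7, 1),
    open_weekends = flag(8, 8, 1),
    female_only_providers = flag(5, 7, 0),
    stringsAsFactors = FALSE)
}

## Women reproducing the published sociodemographic margins: education
## 119/53/123/41 of 336, facility types visited 221/111/4.
table1Women <- function() {
  fac <- table2Facilities()
  hospIds <- fac$facility_id[fac$ftype == "hospital"]
  centIds <- fac$facility_id[fac$ftype == "fp_health_center"]
  dispIds <- fac$facility_id[fac$ftype == "dispensary"]
  chosen <- c(rep(hospIds, length.out = 221), rep(centIds, length.out = 111),
    rep(dispIds, length.out = 4))
  data.frame(
    woman_id = sprintf("w%04d", 1:336),
    lat = rep(seq(0, 0.1, length.out = 56), 6),
    lon = rep(seq(0, 0.1, length.out = 6), each = 56),
    age = rep(16:44, length.out = 336),
    education = c(rep("none", 119), rep("primary", 53),
      rep("secondary", 123), rep("above_secondary", 41)),
    wealth_quintile = rep(c("poorest", "poorer", "middle", "richer",
      "richest"), length.out = 336),
    chosen_facility_id = chosen,
    stringsAsFactors = FALSE)
}

## Tiny facility sets can draw a binary indicator identically for every
## facility, which buildDesign rightly rejects as unidentifiable; nudge
## such attributes so every default attribute varies across alternatives.
ensureVariedFacilities <- function(fac, surveyDate) {
  f <- fac$facilities
  if (nrow(f) < 2) return(fac)
  f$ftype[1:2] <- c("hospital", "fp_health_center")
  # pin the binary attributes on the first five facilities to patterns
  # that are pairwise neither equal nor complementary (either relation
  # makes a pair unidentified: complements differ by a per-case constant,
  # which cancels in the logit); needs J >= 5 alongside the hospital dummy
  if (nrow(f) >= 5) {
    f$ftype[3:4] <- "fp_health_center"
    f$charges_fee[1:5] <- c(0, 1, 0, 1, 0)
    f$open_weekends[1:5] <- c(0, 0, 1, 1, 0)
    f$female_only_providers[1:5] <- c(0, 1, 1, 0, 1)
  } else {
    for (b in c("charges_fee", "open_weekends", "female_only_providers"))
      if (length(unique(f[[b]])) == 1) f[[b]][1] <- 1 - f[[b]][1]
  }
  if (length(unique(f$n_other_services)) == 1)
    f$n_other_services[1] <- f$n_other_services[1] + 1L
  eff <- effectiveFpMethods(f, fac$stock, surveyDate)
  if (length(unique(eff)) == 1) {
    meths <- strsplit(f$methods_provided[1], ";")[[1]]
    if (length(meths) > 0 && eff[1] > 0) {
      # stock-valid methods come first in the simulator's provided list
      f$methods_provided[1] <- paste(meths[-1], collapse = ";")
    } else {
      f$methods_provided[1] <- paste(c(meths, "pill"), collapse = ";")
      fac$stock <- rbind(fac$stock, data.frame(
        facility_id = f$facility_id[1], method = "pill",
        expiry = as.character(surveyDate + 365)))
    }
  }
  fac$facilities <- f
  fac
}

## A small complete synthetic study, optionally with choices.
tinyStudy <- function(seed = 7, nWomen = 60, nFacilities = 5,
    nClusters = 10, params = NULL, withChoices = TRUE) {
  cfg <- simConfig(seed = seed, nWomen = nWomen, nFacilities = nFacilities,
    nClusters = nClusters)
  fac <- ensureVariedFacilities(simulateFacilities(cfg), cfg$surveyDate)
  # tiny samples can draw constant asset columns; the PCA warning about
  # dropping them is expected here
  women <- suppressWarnings(simulateWomen(cfg))
  dm <- planarDistanceMatrix(women, fac$facilities)
  if (withChoices) {
    if (is.null(params)) params <- cfg$trueParams
    women <- simulateChoices(women, fac$facilities, dm, params,
      seed = cfg$seed + 3L, stock = fac$stock, surveyDate = cfg$surveyDate)
  }
  list(cfg = cfg, women = women, facilities = fac$facilities,
    stock = fac$stock, dm = dm)
}

## FitResult built directly from a coefficient vector and covariance,
## for exercising the WTT operations with known inputs.
makeFit <- function(coefs, vc = NULL, n = 336L) {
  if (is.null(vc)) vc <- diag(1e-4, length(coefs))
  dimnames(vc) <- list(names(coefs), names(coefs))
  new("FitResult", params = utilityParams(coefs), coefficients = coefs,
    vcov = vc, loglik = -1, converged = TRUE, nIter = 1L, gradNorm = 0,
    nCases = as.integer(n), nBeta = length(coefs))
}

## Independent per-case loop over the conditional logit likelihood,
## working directly from the assays (beta-only designs).
loopLogLik <- function(design, beta) {
  ch <- chosenAlternative(design)
  total <- 0
  for (i in seq_len(nrow(design))) {
    v <- numeric(ncol(design))
    for (a in names(beta)) v <- v + beta[[a]] * assay(design, a)[i, ]
    p <- exp(v) / sum(exp(v))
    total <- total + log(p[[match(ch[i], colnames(design))]])
  }
  total
}

## Central finite differences of the log-likelihood over all coefficients.
finiteDiffScore <- function(design, params, h = 1e-5) {
  beta <- params@beta
  lam <- params@lambda
  k <- length(beta) + length(lam)
  # group-major flattening, matching the package's coefficient order
  flat <- c(beta, as.numeric(t(lam)))
  perturb <- function(flat) {
    b <- flat[seq_along(beta)]
    names(b) <- names(beta)
    l <- lam
    if (length(lam)) {
      lt <- t(lam)
      lt[] <- flat[-seq_along(beta)]
      l <- t(lt)
    }
    new("UtilityParams", beta = b, lambda = l)
  }
  vapply(seq_len(k), function(j) {
    up <- flat; up[j] <- up[j] + h
    dn <- flat; dn[j] <- dn[j] - h
    (choiceLogLik(design, perturb(up)) -
     choiceLogLik(design, perturb(dn))) / (2 * h)
  }, numeric(1))
}
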