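test_that("ICD-10 matching handles codes, subcodes and ranges", {
  expect_true(icdMatches("J44.1", "J40-J44"))
  expect_true(icdMatches("J40", "J40-J44"))
  expect_false(icdMatches("J45", "J40-J44"))
  expect_true(icdMatches("J06.9", "J06"))
  expect_false(icdMatches("I63", "J00-J99"))
  expect_error(icdMatches("bad", "J40"), "unparseable")
  expect_error(icdRanges("J44-J40"), "ill-formed")
})

test_that("toy endpoint: 2 cases, 7 controls under the stated rules", {
  ev <- data.frame(id = c("t001", "t002"), code = "J44",
                   year = c(2010, 2011), fatal = FALSE)
  co <- makeToyCohort(10L, events = ev,
                      selfChd = c(rep(FALSE, 9), TRUE))
  defn <- endpointDefinition("copd", caseCodes = "J40-J44",
                            baselineSelfReportExclusions = "chd")
  labels <- buildEndpoint(co, defn)
  counts <- attr(labels, "counts")
  expect_identical(unname(counts), c(2L, 7L, 1L))
  expect_identical(sum(counts), 10L)
})

test_that("common-vascular controls exclude follow-up MVE and baseline CVD", {
  ev <- data.frame(id = c("t001", "t003"), code = c("I63", "I21"),
                   year = c(2010, 2012), fatal = FALSE)
  co <- makeToyCohort(8L, events = ev,
                      selfChd = c(rep(FALSE, 7), TRUE))
  defn <- endpointDefinition("stroke", caseCodes = "I60-I63",
                            controlExclusionCodes = c("I20-I25", "I60-I64"),
                            baselineSelfReportExclusions = c("chd",
                                                             "stroke_tia"),
                            controlSet = "common-vascular")
  labels <- buildEndpoint(co, defn)
  expect_identical(unname(labels["t001"]), 1L)   # case
  expect_true(is.na(labels["t003"]))             # MVE during follow-up
  expect_true(is.na(labels["t008"]))             # baseline self-report
  expect_identical(unname(attr(labels, "counts")), c(1L, 5L, 2L))
})

test_that("ascertainment exclusions remove participants from both groups", {
  ev <- data.frame(id = c("t001", "t002"), code = "J44",
                   year = c(2010, 2011), fatal = FALSE)
  co <- makeToyCohort(6L, events = ev,
                      ascertainment = c("cvd-panel", rep("population", 5)))
  defn <- endpointDefinition("copd", caseCodes = "J44",
                            ascertainmentExclusions = "cvd-panel")
  labels <- buildEndpoint(co, defn)
  expect_true(is.na(labels["t001"]))   # case genotyped for another panel
  expect_identical(unname(attr(labels, "counts")), c(1L, 4L, 1L))
  # population-subset restriction behaves the same way
  defn2 <- endpointDefinition("copd", caseCodes = "J44",
                             restrictToPopulationSubset = TRUE)
  expect_true(is.na(buildEndpoint(co, defn2)["t001"]))
  # an endpoint with no cases after filtering errors
  expect_error(buildEndpoint(co, endpointDefinition("none",
                                                    caseCodes = "A00")),
               "no cases")
})

test_that("saturated logistic fit equals the sample odds ratio", {
  labels <- c(rep(1L, 100), rep(0L, 100))
  exposed <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  names(labels) <- sprintf("p%d", 1:200)
  est <- logisticAssoc(labels, exposed, outcomeId = "fixture")
  expect_equal(est@beta, log((30 * 90) / (70 * 10)), tolerance = 1e-6)
  expect_equal(est@beta, 1.350, tolerance = 1e-3)
  expect_identical(est@nCases, 100L)
  expect_identical(est@nStrata, 1L)
})

test_that("null logistic z-scores are standard normal over replicates", {
  set.seed(601)
  z <- replicate(300, {
    n <- 400
    y <- rbinom(n, 1, 0.3)
    s <- rnorm(n)
    e <- logisticAssoc(y, s)
    e@beta / e@se
  })
  expect_gt(ks.test(z, "pnorm")$p.value, 0.01)
})

test_that("logistic recovery of a known odds ratio with strata", {
  set.seed(602)
  n <- 40000
  strata <- sample(1:4, n, replace = TRUE)
  s <- rnorm(n)
  y <- rbinom(n, 1, plogis(qlogis(0.08) + log(0.80) * s))
  est <- logisticAssoc(y, s, strata = strata)
  expect_lt(abs(est@beta - log(0.80)), 2 * est@se)
  expect_identical(est@nStrata, 4L)
})

test_that("sparse or separated strata are dropped with a warning", {
  set.seed(603)
  n <- 60
  strata <- rep(1:2, each = n / 2)
  s <- rnorm(n)
  y <- c(rbinom(n / 2, 1, 0.4), rep(0L, n / 2 - 2), 1L, 1L)
  # stratum 2 has 2 cases < minCases=5
  expect_warning(est <- logisticAssoc(y, s, strata = strata),
                 "excluded")
  expect_identical(est@nStrata, 1L)
  # total separation in a single stratum is an error after the drop
  ysep <- as.integer(s > 0)
  expect_warning(expect_error(logisticAssoc(ysep, s), "no usable stratum"),
                 "separation")
})

test_that("logistic estimates are invariant to affine covariate recoding", {
  set.seed(604)
  n <- 2000
  s <- rnorm(n)
  x <- rnorm(n, 50, 10)
  y <- rbinom(n, 1, plogis(-2 + 0.3 * s + 0.01 * x))
  e1 <- logisticAssoc(y, s, covariates = data.frame(x = x))
  e2 <- logisticAssoc(y, s, covariates = data.frame(x = (x - 50) / 10))
  expect_equal(e1@beta, e2@beta, tolerance = 1e-6)
  expect_equal(e1@se, e2@se, tolerance = 1e-6)
})

test_that("linear association recovers a negative biomarker loading", {
  set.seed(605)
  n <- 30000
  strata <- sample(1:5, n, replace = TRUE)
  s <- rnorm(n, 0, 0.12)          # locus-score-like scale
  apoB <- -0.95 * s + rnorm(n)
  est <- linearAssoc(apoB, s, strata = strata, outcomeId = "apob")
  expect_lt(abs(est@beta - (-0.95)), 2 * est@se)
  # trait equal to the score: slope 1, p -> 0
  est2 <- linearAssoc(s + 1e-8 * rnorm(n), s)
  expect_equal(est2@beta, 1, tolerance = 1e-4)
  expect_lt(est2@p, 1e-200)
  # null trait
  est3 <- linearAssoc(rnorm(n), s, strata = strata)
  expect_lt(abs(est3@beta), 2 * est3@se)
})

test_that("pooling strata equals ivw and matches joint adjustment", {
  e1 <- new("EffectEstimate", outcomeId = "x", beta = 0.2, se = 0.1,
            p = waldP(0.2, 0.1), unit = "per-unit-score",
            orientation = "ldl-raising", nStrata = 1L)
  e2 <- new("EffectEstimate", outcomeId = "x", beta = 0.4, se = 0.1,
            p = waldP(0.4, 0.1), unit = "per-unit-score",
            orientation = "ldl-raising", nStrata = 1L)
  pooled <- poolStrata(list(e1, e2))
  expect_equal(pooled@beta, 0.3)           # equal SEs: simple average
  expect_identical(pooled@nStrata, 2L)
  expect_equal(poolStrata(list(e1))@beta, e1@beta)   # identity
  e3 <- e2; e3@unit <- "per-allele"
  expect_error(poolStrata(list(e1, e3)), "mixed units")

  # stratified-pooled vs single regression with stratum indicators
  set.seed(606)
  n <- 20000
  strata <- sample(1:6, n, replace = TRUE)
  s <- rnorm(n)
  y <- 0.15 * s + 0.3 * strata + rnorm(n)
  est <- linearAssoc(y, s, strata = strata)
  joint <- summary(lm(y ~ s + factor(strata)))
  expect_lt(abs(est@beta - coef(joint)[2L, 1L]), 0.1 * est@se)
})

test_that("orientation flip is an involution that only changes sign", {
  est <- new("EffectEstimate", outcomeId = "x", beta = log(1.25), se = 0.1,
             p = waldP(log(1.25), 0.1), unit = "per-unit-score",
             orientation = "ldl-raising", nStrata = 1L)
  flipped <- orientPerSdLowerLdl(est)
  expect_equal(flipped@beta, log(0.8))
  expect_identical(flipped@unit, "per-SD-lower-LDL")
  expect_equal(flipped@se, est@se)
  expect_equal(flipped@p, est@p)
  back <- orientPerSdLowerLdl(flipped)
  expect_equal(back@beta, est@beta)
  expect_identical(back@unit, est@unit)
  bad <- est; bad@unit <- "per-allele"
  expect_error(orientPerSdLowerLdl(bad), "cannot reorient")
})

test_that("phewas scan applies the combined Bonferroni threshold", {
  set.seed(607)
  n <- 4000
  ids <- sprintf("t%03d", 1:n)
  score <- rnorm(n)
  # one endpoint driven by the score, one null, one with no cases
  pCase <- plogis(qlogis(0.05) + 1.2 * score)
  ev <- rbind(
    data.frame(id = ids[runif(n) < pCase], code = "J44", year = 2010,
               fatal = FALSE),
    data.frame(id = sample(ids, 150), code = "K80", year = 2011,
               fatal = FALSE))
  co <- makeToyCohort(n, events = ev)
  eps <- list(endpointDefinition("resp", caseCodes = "J40-J47"),
              endpointDefinition("gall", caseCodes = "K80"),
              endpointDefinition("empty", caseCodes = "A00"))
  out <- phewasScan(co, eps, score, nPrior = 7L)
  expect_equal(attr(out, "threshold"), 0.05 / (3 + 7))
  expect_true(out$significant[out$outcome_id == "resp"])
  expect_false(out$significant[out$outcome_id == "gall"])
  expect_match(attr(out, "failures"), "empty")
  # spec-sized scan: 41 groups + 7 priors -> 0.0010
  expect_equal(round(0.05 / (length(defaultPhewasGroups()) + 7), 4), 0.0010)
})

test_that("phewas group ranges are disjoint and cover A00-N99", {
  gps <- defaultPhewasGroups()
  expect_length(gps, 41L)
  rngs <- t(sapply(gps, function(g) scoreMR:::icdRanges(g$caseCodes)[1, ]))
  expect_identical(rngs[1L, 1L], scoreMR:::icdOrd("A00"))
  expect_identical(rngs[41L, 2L], scoreMR:::icdOrd("N99"))
  expect_true(all(rngs[-1L, 1L] == rngs[-41L, 2L] + 1L))
})
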