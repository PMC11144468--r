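test_that("locus carrier fraction matches Hardy-Weinberg expectation", {
  cfg <- simulationConfig(nParticipants = 70914L, grsNSnps = 0L, seed = 201L)
  g <- simulateGenotypes(cfg)
  expected <- 1 - (1 - 0.013)^2           # 0.0258
  carriers <- mean(g[, "rs151193009"] >= 1)
  se3 <- 3 * sqrt(expected * (1 - expected) / nrow(g))
  expect_lt(abs(carriers - expected), se3)
})

test_that("zero-frequency alleles never appear and empirical MAFs track config", {
  cfg <- simulationConfig(nParticipants = 50000L,
                          locusMaf = c(0, 0.2, 0.4), grsNSnps = 4L,
                          grsMafs = c(0.1, 0.2, 0.3, 0.4),
                          grsBetas = rep(0, 4L), seed = 202L)
  g <- simulateGenotypes(cfg)
  expect_true(all(g[, 1L] == 0))
  mafs <- colMeans(g[, -1L]) / 2
  want <- c(0.2, 0.4, 0.1, 0.2, 0.3, 0.4)
  se3 <- 3 * sqrt(want * (1 - want) / (2 * nrow(g)))
  expect_true(all(abs(mafs - want) < se3))
})

test_that("independent LD leaves locus dosages uncorrelated", {
  cfg <- simulationConfig(nParticipants = 100000L,
                          locusMaf = c(0.5, 0.5, 0.5), grsNSnps = 0L,
                          seed = 203L)
  g <- simulateGenotypes(cfg)
  cc <- cor(g)
  diag(cc) <- 0
  expect_lt(max(abs(cc)), 0.02)
})

test_that("haplotype-frequency tables induce the requested LD", {
  # SNPs 1 and 2 in perfect coupling, SNP 3 independent at 0.5
  hap <- c("000" = 0.35, "001" = 0.35, "110" = 0.15, "111" = 0.15,
           "010" = 0, "011" = 0, "100" = 0, "101" = 0)
  cfg <- simulationConfig(nParticipants = 20000L,
                          locusMaf = c(0.3, 0.3, 0.5), locusLd = hap,
                          grsNSnps = 0L, seed = 204L)
  g <- simulateGenotypes(cfg)
  expect_gt(cor(g[, 1L], g[, 2L]), 0.99)   # coupled
  expect_lt(abs(cor(g[, 1L], g[, 3L])), 0.03)
})

test_that("invalid haplotype tables are refused", {
  expect_error(simulationConfig(nParticipants = 10L,
                                locusLd = rep(0.2, 8L)),
               "sum to 1")
  expect_error(simulationConfig(nParticipants = 10L,
                                locusLd = c(1.2, -0.2, rep(0, 6L))),
               "non-negative")
})

test_that("seeded simulation is reproducible and seeds differ", {
  cfg <- simulationConfig(nParticipants = 500L, seed = 205L)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(dosages(a), dosages(b))
  expect_identical(participantData(a), participantData(b))
  expect_identical(eventData(a), eventData(b))
  c2 <- simulateCohort(simulationConfig(nParticipants = 500L, seed = 206L))
  expect_false(identical(dosages(a), dosages(c2)))
})

test_that("null LDL model reproduces the marginal mean and SD", {
  cfg <- simulationConfig(nParticipants = 50000L,
                          locusBetas = c(0, 0, 0), grsNSnps = 0L,
                          covariateEffects = c(age = 0), seed = 207L)
  g <- simulateGenotypes(cfg)
  cov <- simulateCovariates(cfg)
  ldl <- simulateLdl(cfg, g, cov)
  expect_lt(abs(mean(ldl$latent) - 2.36), 0.02)
  expect_lt(abs(sd(ldl$latent) - 0.69), 0.02)
  expect_lt(abs(mean(is.na(ldl$ldl)) - 0.75), 0.02)
})

test_that("locus variance explained matches the analytic decomposition", {
  maf <- c(0.013, 0.3, 0.1)
  beta <- c(0.65, 0.10, 0.16)
  cfg <- simulationConfig(nParticipants = 200000L, locusMaf = maf,
                          locusBetas = beta, grsNSnps = 0L,
                          covariateEffects = c(age = 0),
                          ldlMeasuredFraction = 1, seed = 208L)
  g <- simulateGenotypes(cfg)
  cov <- simulateCovariates(cfg)
  ldl <- simulateLdl(cfg, g, cov)
  analytic <- sum(2 * maf * (1 - maf) * beta^2)
  fit <- summary(lm(ldl$latent ~ g))
  expect_lt(abs(fit$r.squared - analytic / (analytic + (1 - analytic))),
            0.004)
  # per-allele contrast for the lead SNP recovers beta * sd in mmol/L
  expect_lt(abs(coef(fit)[2L, 1L] - 0.65 * 0.69), 3 * coef(fit)[2L, 2L])
})

test_that("mismatched rows are refused", {
  cfg <- simulationConfig(nParticipants = 100L, seed = 209L)
  g <- simulateGenotypes(cfg)
  cov <- simulateCovariates(cfg)
  expect_error(simulateLdl(cfg, g[1:50, ], cov), "different numbers of rows")
})

test_that("null outcome model hits its baseline risk", {
  om <- list(outcomeModel("null1", baselineRisk = 0.1, code = "K80"))
  cfg <- simulationConfig(nParticipants = 50000L, outcomeModels = om,
                          grsNSnps = 0L, seed = 210L)
  g <- simulateGenotypes(cfg)
  cov <- simulateCovariates(cfg)
  ldl <- simulateLdl(cfg, g, cov)
  score <- as.numeric(g[, 1:3] %*% cfg@locusBetas)
  ev <- simulateOutcomes(cfg, g, ldl$latent, score)
  frac <- length(unique(ev$id)) / nrow(g)
  expect_lt(abs(frac - 0.10), 3 * sqrt(0.1 * 0.9 / nrow(g)))
  expect_true(all(ev$year >= cfg@baselineYear &
                  ev$year <= cfg@baselineYear + cfg@followupYears))
})

test_that("fatal flags follow the configured fraction", {
  om <- list(outcomeModel("f", baselineRisk = 0.2, fatalFraction = 0.3,
                          code = "I21"))
  cfg <- simulationConfig(nParticipants = 20000L, outcomeModels = om,
                          grsNSnps = 0L, seed = 211L)
  g <- simulateGenotypes(cfg)
  cov <- simulateCovariates(cfg)
  ldl <- simulateLdl(cfg, g, cov)
  ev <- simulateOutcomes(cfg, g, ldl$latent, rep(0, nrow(g)))
  expect_lt(abs(mean(ev$fatal) - 0.3), 3 * sqrt(0.3 * 0.7 / nrow(ev)))
})

test_that("spirometry respects the LLN calibration and liability shift", {
  cfg <- simulationConfig(nParticipants = 60000L,
                          copdLiabilityFraction = 0, grsNSnps = 0L,
                          spiroUnusableRegions = integer(), seed = 212L)
  cov <- simulateCovariates(cfg)
  sp <- simulateSpirometry(cfg, cov)
  z <- lmsZscore(sp$fev1 / sp$fvc, cov$age, cov$sex, cov$height,
                 defaultLmsReference())
  frac <- mean(prevalentCopd(z))
  expect_lt(abs(frac - 0.05), 0.01)   # centile definition

  cfg2 <- simulationConfig(nParticipants = 60000L,
                           copdLiabilityFraction = 0.10,
                           copdLiabilityShift = -1.5, grsNSnps = 0L,
                           spiroUnusableRegions = integer(), seed = 213L)
  cov2 <- simulateCovariates(cfg2)
  sp2 <- simulateSpirometry(cfg2, cov2)
  z2 <- lmsZscore(sp2$fev1 / sp2$fvc, cov2$age, cov2$sex, cov2$height,
                  defaultLmsReference())
  want <- 0.05 * 0.9 + pnorm(-1.6449 + 1.5) * 0.1   # Gaussian tail arithmetic
  expect_lt(abs(mean(prevalentCopd(z2)) - want), 0.012)
})

test_that("spirometry is missing in unusable regions and fvc >= fev1 > 0", {
  cfg <- simulationConfig(nParticipants = 5000L, seed = 214L)
  co <- simulateCohort(cfg)
  pd <- participantData(co)
  bad <- pd$region %in% cfg@spiroUnusableRegions
  expect_true(all(is.na(pd$fev1[bad])))
  expect_true(all(pd$fvc[!bad] >= pd$fev1[!bad]))
  expect_true(all(pd$fev1[!bad] > 0))
})

test_that("assembled cohort passes validity and keeps dosages in range", {
  co <- simulateCohort(simulationConfig(nParticipants = 300L, seed = 215L))
  expect_true(validObject(co))
  expect_true(all(dosages(co) >= 0 & dosages(co) <= 2))
  expect_identical(ncol(co), 300L)
})
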