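test_that("joint betas equal marginal betas for independent SNPs", {
  # exact fixture: orthogonal dosage columns, no covariates
  g <- cbind(s1 = c(0, 0, 1, 1, 2, 2, 0, 2),
             s2 = c(1, 0, 1, 0, 1, 0, 2, 2))
  # orthogonalise s2 against s1 so joint == marginal exactly
  g[, 2] <- g[, 2] - mean(g[, 2])
  g[, 1] <- g[, 1] - mean(g[, 1])
  g[, 2] <- g[, 2] - sum(g[, 1] * g[, 2]) / sum(g[, 1]^2) * g[, 1]
  g <- g + 1  # keep dosages positive-ish; affine shift is absorbed by intercept
  y <- c(0.2, -0.1, 0.5, 0.1, 0.9, 0.6, 0.3, 1.1)
  joint <- fitLocusWeights(g, y)
  m1 <- fitLocusWeights(g[, 1, drop = FALSE], y)
  m2 <- fitLocusWeights(g[, 2, drop = FALSE], y)
  expect_equal(unname(weightBetas(joint)[1L]), unname(weightBetas(m1)),
               tolerance = 1e-6)
  expect_equal(unname(weightBetas(joint)[2L]), unname(weightBetas(m2)),
               tolerance = 1e-6)
})

test_that("weight recovery on a simulated cohort and null SNP behaviour", {
  cfg <- simulationConfig(nParticipants = 60000L,
                          locusBetas = c(0.65, 0.10, 0), grsNSnps = 0L,
                          ldlMeasuredFraction = 1, seed = 501L)
  g <- simulateGenotypes(cfg)
  cov <- simulateCovariates(cfg)
  ldl <- simulateLdl(cfg, g, cov)
  cvm <- covariateColumns(cov, c("age", "age2", "sex"))
  rl <- stratifiedTransform(ldl$ldl, cvm, cov$region)
  w <- fitLocusWeights(g[, 1:3], rl, cvm, cov$region)
  expect_lt(abs(weightBetas(w)[1L] - 0.65), 2 * weightSes(w)[1L])
  expect_lt(abs(weightBetas(w)[2L] - 0.10), 2 * weightSes(w)[2L])
  expect_lt(abs(weightBetas(w)[3L] - 0), 2 * weightSes(w)[3L])
})

test_that("monomorphic and collinear dosages are refused by name", {
  g <- cbind(a = c(0, 1, 2, 1, 0, 1), b = rep(0, 6))
  expect_error(fitLocusWeights(g, rnorm(6)), "monomorphic.*b")
  g2 <- cbind(a = c(0, 1, 2, 1, 0, 1), b = c(0, 1, 2, 1, 0, 1))
  expect_error(fitLocusWeights(g2, rnorm(6)), "collinear")
})

test_that("jackknife blocks partition near-equally and reproducibly", {
  m <- assignJackknifeBlocks(sprintf("p%d", 1:100), B = 100L, seed = 1L)
  expect_true(all(table(m) == 1L))
  m2 <- assignJackknifeBlocks(sprintf("p%d", 1:101), B = 100L, seed = 1L)
  expect_equal(sort(unname(table(m2)), decreasing = TRUE)[1L], 2L)
  expect_true(all(table(m2) %in% 1:2))
  expect_identical(assignJackknifeBlocks(letters, 5L, seed = 9L),
                   assignJackknifeBlocks(letters, 5L, seed = 9L))
  expect_error(assignJackknifeBlocks(letters[1:3], B = 10L), "cannot form")
})

test_that("leave-one-block-out downdating matches brute-force refits", {
  set.seed(502)
  n <- 60
  g <- cbind(s1 = rbinom(n, 2, 0.4), s2 = rbinom(n, 2, 0.25))
  rownames(g) <- sprintf("p%02d", 1:n)
  cv <- data.frame(age = rnorm(n))
  y <- 0.3 * g[, 1] - 0.1 * g[, 2] + 0.2 * cv$age + rnorm(n)
  blocks <- assignJackknifeBlocks(rownames(g), B = 4L, seed = 503L)
  w <- jackknifeWeights(g, y, cv, NULL, blocks)
  oracle <- jackknifeOracle(g, y, cv, blocks)
  expect_equal(unname(perBlockBetas(w)), unname(oracle), tolerance = 1e-10)
})

test_that("zero-noise data give identical weights in every block", {
  set.seed(504)
  n <- 40
  g <- cbind(s1 = rbinom(n, 2, 0.5), s2 = rbinom(n, 2, 0.3))
  rownames(g) <- sprintf("p%02d", 1:n)
  y <- 0.5 * g[, 1] + 0.2 * g[, 2]
  blocks <- assignJackknifeBlocks(rownames(g), B = 2L, seed = 1L)
  w <- jackknifeWeights(g, y, NULL, NULL, blocks)
  expect_equal(perBlockBetas(w)[1L, ], perBlockBetas(w)[2L, ],
               tolerance = 1e-9)
  expect_equal(unname(perBlockBetas(w)[1L, ]), c(0.5, 0.2),
               tolerance = 1e-9)
  expect_equal(unname(weightBetas(w)), c(0.5, 0.2), tolerance = 1e-9)
})

test_that("jackknife block means stay near the full-sample weights", {
  cfg <- simulationConfig(nParticipants = 8000L, grsNSnps = 0L,
                          ldlMeasuredFraction = 1, seed = 505L)
  g <- simulateGenotypes(cfg)
  cov <- simulateCovariates(cfg)
  ldl <- simulateLdl(cfg, g, cov)
  rl <- stratifiedTransform(ldl$ldl, NULL, cov$region)
  blocks <- assignJackknifeBlocks(cov$id, B = 50L, seed = 506L)
  w <- jackknifeWeights(g[, 1:3], rl, NULL, cov$region, blocks)
  jkSe <- apply(perBlockBetas(w), 2L, sd) * sqrt(nrow(perBlockBetas(w)) - 1)
  expect_true(all(abs(colMeans(perBlockBetas(w)) - weightBetas(w)) <=
                  3 * pmax(jkSe, 1e-8)))
})

test_that("a failing leave-out subsample names its block", {
  g <- cbind(s1 = c(rep(0, 8), 1, 1))   # both carriers in one block
  rownames(g) <- sprintf("p%02d", 1:10)
  blocks <- setNames(rep(c(1L, 2L), each = 5L), rownames(g))
  expect_error(jackknifeWeights(g, rnorm(10), NULL, NULL, blocks),
               "block 2")
})

test_that("buildScore is a weighted dosage sum with block lookup", {
  w <- ScoreWeights(c("a", "b", "c"), c(0.65, 0.10, 0.16),
                    c(0.05, 0.01, 0.03))
  x <- matrix(c(1, 0, 2), 1, dimnames = list("p1", c("a", "b", "c")))
  expect_equal(unname(buildScore(x, w)), 0.97)
  expect_equal(unname(buildScore(x, ScoreWeights(c("a", "b", "c"),
                                                 c(0, 0, 0), c(1, 1, 1)))), 0)
  # linearity: doubling betas doubles the score
  w2 <- ScoreWeights(c("a", "b", "c"), 2 * c(0.65, 0.10, 0.16),
                     c(0.05, 0.01, 0.03))
  expect_equal(buildScore(x, w2), 2 * buildScore(x, w))
  # per-block weights override the full-sample ones for mapped participants
  pb <- rbind(c(1, 1, 1), c(2, 2, 2))
  wj <- ScoreWeights(c("a", "b", "c"), c(0.65, 0.10, 0.16),
                     c(0.05, 0.01, 0.03),
                     blockMap = c(p1 = 2L), perBlockBetas = pb)
  expect_equal(unname(buildScore(x, wj)), sum(x * 2))
  # permutation equivariance
  set.seed(507)
  xx <- matrix(rbinom(30, 2, 0.4), 10,
               dimnames = list(sprintf("q%d", 1:10), c("a", "b", "c")))
  perm <- sample(10)
  expect_equal(buildScore(xx, w)[perm], buildScore(xx[perm, ], w))
  # missing dosages and missing SNPs are refused
  xx[1, 1] <- NA
  expect_error(buildScore(xx, w), "no imputation")
  expect_error(buildScore(xx[, 1:2], w), "lacks SNP")
})

test_that("instrument strength matches its closed form and edge cases", {
  set.seed(508)
  n <- 500
  s <- rnorm(n)
  y <- 0.2 * s + rnorm(n)
  d <- instrumentStrength(s, y)
  r2 <- cor(s, y)^2
  expect_equal(d$rSquared, r2, tolerance = 1e-10)
  expect_equal(d$fStatistic, r2 / (1 - r2) * (n - 2), tolerance = 1e-10)
  # exact fit: infinite F flag
  expect_true(is.infinite(instrumentStrength(y, y)$fStatistic))
  expect_error(instrumentStrength(rnorm(5), rnorm(5)), "at least 10")
  # independent score: F has mean about 1 under the null
  f <- replicate(300, {
    instrumentStrength(rnorm(60), rnorm(60))$fStatistic
  })
  expect_lt(abs(mean(f) - 1), 0.25)
})

test_that("score calibration: score-LDL slope near 1 with consistent weights", {
  cfg <- simulationConfig(nParticipants = 50000L, grsNSnps = 0L,
                          ldlMeasuredFraction = 1, seed = 509L)
  g <- simulateGenotypes(cfg)
  cov <- simulateCovariates(cfg)
  ldl <- simulateLdl(cfg, g, cov)
  rl <- stratifiedTransform(ldl$ldl, NULL, cov$region)
  w <- fitLocusWeights(g[, 1:3], rl, NULL, cov$region)
  sc <- buildScore(g, w)
  fit <- summary(lm(rl ~ sc))
  expect_lt(abs(coef(fit)[2L, 1L] - 1), 2 * coef(fit)[2L, 2L])
})

test_that("jackknifed weights remove the spurious self-calibration of naive weights", {
  # Under an all-null locus, the naive internally weighted score regresses
  # on LDL with slope identically 1 (overfitting artefact); the jackknifed
  # score does not.
  set.seed(510)
  slopeNaive <- slopeJack <- numeric(40)
  for (r in 1:40) {
    n <- 3000
    g <- cbind(a = rbinom(n, 2, 0.013), b = rbinom(n, 2, 0.35),
               c = rbinom(n, 2, 0.032))
    rownames(g) <- sprintf("i%d", 1:n)
    y <- rnorm(n)
    blocks <- assignJackknifeBlocks(rownames(g), 100L, seed = 510L + r)
    jw <- jackknifeWeights(g, y, NULL, NULL, blocks)
    nv <- fitLocusWeights(g, y)
    slopeNaive[r] <- coef(lm(y ~ buildScore(g, nv)))[2L]
    slopeJack[r] <- coef(lm(y ~ buildScore(g, jw)))[2L]
  }
  expect_true(all(abs(slopeNaive - 1) < 1e-8))
  expect_lt(median(slopeJack), 0.5)
})

test_that("polygenic filter keeps 64 of 76 on an engineered panel", {
  set.seed(511)
  n <- 400
  mafs <- runif(76, 0.1, 0.5)
  g <- sapply(mafs, function(p) rbinom(n, 2, p))
  colnames(g) <- sprintf("v%02d", 1:76)
  g[, 75] <- 0          # two monomorphic candidates
  g[, 76] <- 2
  ext <- rep(0.05, 76)
  extSe <- rep(0.004, 76)
  int <- ext
  intSe <- rep(0.004, 76)
  # ten opposite-sign SNPs with heterogeneity far beyond the 0.05/74 bound
  int[1:10] <- -ext[1:10]   # |z_het| = 0.1/sqrt(2*0.004^2) = 17.7
  out <- buildPolygenicScore(g, ext, extSe, int, intSe)
  expect_identical(out$mTested, 74L)
  expect_identical(length(out$kept), 64L)
  expect_false(any(sprintf("v%02d", c(1:10, 75, 76)) %in% out$kept))
  expect_equal(unname(out$score),
               as.numeric(g[, out$kept] %*% ext[match(out$kept,
                                                      colnames(g))]))
})

test_that("polygenic filter keeps consistent or homogeneous SNPs", {
  g <- matrix(rbinom(300, 2, 0.3), 100, dimnames = list(NULL, c("a", "b", "c")))
  # identical internal and external: all kept
  out <- buildPolygenicScore(g, c(0.1, -0.2, 0.05), rep(0.01, 3),
                             c(0.1, -0.2, 0.05), rep(0.01, 3))
  expect_identical(out$kept, c("a", "b", "c"))
  # one opposite-sign, strongly heterogeneous SNP is dropped
  out2 <- buildPolygenicScore(g, c(0.1, -0.2, 0.05), rep(0.01, 3),
                              c(-0.1, -0.2, 0.05), rep(0.01, 3))
  expect_identical(out2$kept, c("b", "c"))
  # opposite sign but homogeneous (wide SEs) survives
  out3 <- buildPolygenicScore(g, c(0.01, -0.2, 0.05), rep(0.2, 3),
                              c(-0.01, -0.2, 0.05), rep(0.2, 3))
  expect_identical(out3$kept, c("a", "b", "c"))
  # allele mismatch is an error naming the SNP
  expect_error(
    buildPolygenicScore(g, c(0.1, -0.2, 0.05), rep(0.01, 3),
                        c(0.1, -0.2, 0.05), rep(0.01, 3),
                        externalAlleles = c("A", "C", "G"),
                        internalAlleles = c("A", "G", "G")),
    "mismatch.*b")
})
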