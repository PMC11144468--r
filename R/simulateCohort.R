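locusSnpIds <- c("rs151193009", "rs2495477", "rs11206517")

#' Simulate allele dosages
#'
#' Draws the 3 locus SNPs from two haplotypes per individual under the
#' configured haplotype-frequency table (Hardy-Weinberg at the haplotype
#' level; \code{"independent"} means the table is the product of allele
#' frequencies) and the polygenic panel as independent binomial(2, maf)
#' dosages.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @return Integer matrix, participants in rows, SNPs in columns (locus SNPs
#'   first, then \code{grs_01}, ...).
#' @export
simulateGenotypes <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(subSeed(config@seed, "genotypes"))
  n <- config@nParticipants
  hf <- haplotypeFrequencies(config)
  bits <- sapply(0:2, function(j) bitwAnd(bitwShiftR(0:7, j), 1L))  # 8 x 3
  h1 <- sample.int(8L, n, replace = TRUE, prob = hf)
  h2 <- sample.int(8L, n, replace = TRUE, prob = hf)
  locus <- bits[h1, , drop = FALSE] + bits[h2, , drop = FALSE]
  colnames(locus) <- locusSnpIds
  if (config@grsNSnps > 0L) {
    grs <- vapply(config@grsMafs, function(p) rbinom(n, 2L, p), integer(n))
    colnames(grs) <- sprintf("grs_%02d", seq_len(config@grsNSnps))
    g <- cbind(locus, grs)
  } else g <- locus
  rownames(g) <- sprintf("p%06d", seq_len(n))
  g
}

## Haplotype frequencies over the 3 locus SNPs; bit j of the haplotype index
## (0..7) is the allele at SNP j+1. A named table ("000".."111", character k
## = allele at SNP k) is reordered to index order.
haplotypeFrequencies <- function(config) {
  if (is.numeric(config@locusLd)) {
    hf <- config@locusLd
    if (!is.null(names(hf))) {
      key <- vapply(0:7, function(h)
        paste(bitwAnd(bitwShiftR(h, 0:2), 1L), collapse = ""), "")
      if (!all(key %in% names(hf)))
        stop("haplotype table names must be the binary strings 000..111")
      hf <- hf[key]
    }
    return(unname(hf))
  }
  p <- config@locusMaf
  vapply(0:7, function(h) {
    a <- bitwAnd(bitwShiftR(h, 0:2), 1L)
    prod(ifelse(a == 1L, p, 1 - p))
  }, numeric(1))
}

#' Simulate participant covariates
#'
#' Generates region assignment (near-equal sizes), age (truncated normal,
#' mean 52.1, SD 10.7, range 30-79), sex (59.7\% female, coded 1), fasting
#' time since last meal, height with a sex difference, genetic principal
#' components, ascertainment category (70\% population-representative, the
#' rest split between vascular and respiratory case panels) and baseline
#' self-report disease flags.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @return A \code{data.frame}, one row per participant.
#' @export
simulateCovariates <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(subSeed(config@seed, "covariates"))
  n <- config@nParticipants
  region <- sample(rep_len(seq_len(config@nRegions), n))
  age <- rnorm(n, 52.1, 10.7)
  bad <- which(age < 30 | age > 79)
  while (length(bad)) {
    age[bad] <- rnorm(length(bad), 52.1, 10.7)
    bad <- bad[age[bad] < 30 | age[bad] > 79]
  }
  sex <- rbinom(n, 1L, 0.597)                    # 1 = female
  fasting_time <- pmin(rexp(n, 1 / 4) + 0.5, 16)
  height <- rnorm(n, ifelse(sex == 1L, 155.5, 163.8), 6.0)
  pcs <- matrix(rnorm(n * config@nPcs), n,
                dimnames = list(NULL, sprintf("pc%d", seq_len(config@nPcs))))
  ascertainment <- sample(c("population", "cvd-panel", "respiratory-panel"),
                          n, replace = TRUE, prob = c(0.70, 0.15, 0.15))
  out <- data.frame(
    id = sprintf("p%06d", seq_len(n)), region = region, age = age,
    sex = sex, fasting_time = fasting_time, height = height,
    self_chd = rbinom(n, 1L, 0.036) == 1L,
    self_stroke_tia = rbinom(n, 1L, 0.017) == 1L,
    self_diabetes = rbinom(n, 1L, 0.061) == 1L,
    self_asthma = rbinom(n, 1L, 0.006) == 1L,
    self_copd = rbinom(n, 1L, 0.020) == 1L,
    ascertainment_category = ascertainment,
    stringsAsFactors = FALSE)
  cbind(out, pcs)
}

#' Simulate LDL-C concentrations
#'
#' LDL-C (mmol/L) is the sum of a seeded region intercept, centred covariate
#' effects, the genetic contribution
#' \code{ldlSdMmol * (dosages \%*\% per-allele betas)} of locus and
#' polygenic SNPs, and Gaussian noise scaled so the marginal SD is
#' approximately \code{ldlSdMmol}. A random subset of size
#' \code{ldlMeasuredFraction} is "assayed"; the rest are missing completely
#' at random, mirroring an assay-driven measurement subset.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @param genotypes Dosage matrix from \code{\link{simulateGenotypes}}.
#' @param covariates Data frame from \code{\link{simulateCovariates}}.
#' @return List with \code{ldl} (observed, NA outside the measured subset),
#'   \code{latent} (complete values, used as the liability for outcome
#'   generation) and \code{measured} (logical).
#' @export
simulateLdl <- function(config, genotypes, covariates) {
  stopifnot(is(config, "SimulationConfig"))
  if (nrow(genotypes) != nrow(covariates))
    stop("genotypes and covariates have different numbers of rows")
  set.seed(subSeed(config@seed, "ldl"))
  n <- nrow(genotypes)
  betas <- c(config@locusBetas, config@grsBetas)
  gval <- as.numeric(genotypes[, seq_along(betas), drop = FALSE] %*% betas)
  mafs <- c(config@locusMaf, config@grsMafs)
  gvar <- sum(2 * mafs * (1 - mafs) * betas^2)     # variance in SD^2 units
  noiseSd <- config@ldlSdMmol * sqrt(max(1 - gvar, 0.05))
  regionShift <- rnorm(config@nRegions, 0, 0.10 * config@ldlSdMmol)
  ce <- config@covariateEffects
  covPart <- rep(0, n)
  for (nm in names(ce)) {
    x <- covariates[[nm]]
    covPart <- covPart + ce[[nm]] * (x - mean(x))
  }
  latent <- config@ldlMeanMmol + regionShift[covariates$region] + covPart +
    config@ldlSdMmol * (gval - mean(gval)) + rnorm(n, 0, noiseSd)
  measured <- runif(n) < config@ldlMeasuredFraction
  list(ldl = ifelse(measured, latent, NA_real_), latent = latent,
       measured = measured)
}

#' Simulate binary outcomes and follow-up events
#'
#' For each configured \linkS4class{OutcomeModel}, draws a Bernoulli event
#' per participant with
#' \code{logit = logit(baselineRisk) + logOrPerSdLdl * z(LDL) +
#' logOrPerSdScoreDirect * centred score}, where \code{z(LDL)} standardises
#' the latent (complete) LDL-C. Events receive a uniform year within
#' follow-up and a fatal flag with the configured probability.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @param genotypes Dosage matrix (rownames are participant ids).
#' @param ldlLatent Complete latent LDL-C vector (mmol/L).
#' @param score True locus score in SD-of-LDL units (higher = higher LDL).
#' @return \code{data.frame(id, code, year, fatal)}; also an
#'   \code{"outcomeFlags"} attribute with the per-outcome case indicator
#'   matrix.
#' @export
simulateOutcomes <- function(config, genotypes, ldlLatent, score) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(subSeed(config@seed, "outcomes"))
  n <- nrow(genotypes)
  ids <- rownames(genotypes)
  zLdl <- as.numeric(scale(ldlLatent))
  sc <- score - mean(score)
  evs <- list()
  flags <- matrix(FALSE, n, length(config@outcomeModels),
                  dimnames = list(ids, vapply(config@outcomeModels,
                                              function(m) m@outcomeId, "")))
  for (m in config@outcomeModels) {
    eta <- qlogis(m@baselineRisk) + m@logOrPerSdLdl * zLdl +
      m@logOrPerSdScoreDirect * sc
    case <- runif(n) < plogis(eta)
    flags[, m@outcomeId] <- case
    k <- sum(case)
    if (k > 0L)
      evs[[m@outcomeId]] <- data.frame(
        id = ids[case], code = m@code,
        year = config@baselineYear + runif(k, 0, config@followupYears),
        fatal = runif(k) < m@fatalFraction, stringsAsFactors = FALSE)
  }
  out <- if (length(evs)) do.call(rbind, c(evs, make.row.names = FALSE))
         else data.frame(id = character(), code = character(),
                         year = numeric(), fatal = logical())
  attr(out, "outcomeFlags") <- flags
  out
}

#' Simulate spirometry
#'
#' FVC follows a log-linear height/age/sex mean model with lognormal noise;
#' the FEV1/FVC ratio is drawn from the package's synthetic LMS reference
#' distribution, with the ratio z-score shifted down by
#' \code{copdLiabilityShift} for the high-liability subgroup. Regions listed
#' in \code{spiroUnusableRegions} get missing spirometry, mimicking regions
#' whose collection showed systematic errors.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @param covariates Data frame from \code{\link{simulateCovariates}}.
#' @param copdLiability Logical (or 0/1) vector marking the high-liability
#'   subgroup; \code{NULL} draws it from
#'   \code{copdLiabilityFraction}.
#' @return List with \code{fev1}, \code{fvc} (litres, NA in unusable
#'   regions), \code{liability} and \code{usable}.
#' @export
simulateSpirometry <- function(config, covariates, copdLiability = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(subSeed(config@seed, "spirometry"))
  n <- nrow(covariates)
  if (is.null(copdLiability))
    copdLiability <- runif(n) < config@copdLiabilityFraction
  liab <- as.logical(copdLiability)
  fvc <- exp(-9.3 + 2.05 * log(covariates$height) -
             0.006 * (covariates$age - 50) +
             0.12 * (covariates$sex == 0) + rnorm(n, 0, 0.10))
  ref <- defaultLmsReference()
  z <- rnorm(n) + ifelse(liab, config@copdLiabilityShift, 0)
  ratio <- pmin(pmax(lmsRatioFromZ(z, covariates$age, covariates$sex,
                                   covariates$height, ref), 0.2), 1)
  usable <- !(covariates$region %in% config@spiroUnusableRegions)
  list(fev1 = ifelse(usable, fvc * ratio, NA_real_),
       fvc = ifelse(usable, fvc, NA_real_),
       liability = liab, usable = usable)
}

#' Simulate a full synthetic cohort
#'
#' Runs the genotype, covariate, LDL-C, spirometry and outcome generators
#' under one master seed and assembles a \linkS4class{GeneticCohort}. The
#' true (noise-free) locus score used as the pleiotropy liability is stored
#' in \code{metadata()$trueScore}; the latent complete LDL-C in
#' \code{metadata()$latentLdl}; the generating config in
#' \code{metadata()$config}.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @return A \linkS4class{GeneticCohort}.
#' @examples
#' cohort <- simulateCohort(simulationConfig(nParticipants = 500, seed = 3))
#' cohort
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  g <- simulateGenotypes(config)
  cov <- simulateCovariates(config)
  ldl <- simulateLdl(config, g, cov)
  trueScore <- as.numeric(g[, seq_len(3L), drop = FALSE] %*% config@locusBetas)
  spiro <- simulateSpirometry(config, cov)
  events <- simulateOutcomes(config, g, ldl$latent, trueScore)
  cd <- cov
  cd$ldl_mmol <- ldl$ldl
  cd$fev1 <- spiro$fev1
  cd$fvc <- spiro$fvc
  cd$spiro_usable <- spiro$usable
  rowdat <- S4Vectors::DataFrame(
    snp_id = colnames(g),
    effect_allele = rep("ALT", ncol(g)),
    maf = c(config@locusMaf, config@grsMafs),
    class = rep(c("locus", "grs"), c(3L, config@grsNSnps)),
    true_beta = c(config@locusBetas, config@grsBetas))
  se <- SummarizedExperiment(
    assays = list(dosage = t(g)),
    rowData = rowdat,
    colData = S4Vectors::DataFrame(cd, row.names = cd$id))
  obj <- new("GeneticCohort", se)
  metadata(obj) <- list(events = events, config = config,
                        trueScore = setNames(trueScore, cd$id),
                        latentLdl = setNames(ldl$latent, cd$id),
                        outcomeFlags = attr(events, "outcomeFlags"),
                        copdLiability = spiro$liability)
  validObject(obj)
  obj
}
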