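#' @importFrom stats qnorm qlogis rbinom rnorm runif rexp setNames pnorm
#'   plogis qchisq pchisq complete.cases var sd cor coef vcov
NULL

#' Construct an outcome-generating model
#'
#' @param outcomeId Label for the endpoint.
#' @param baselineRisk Cumulative event probability at zero liability.
#' @param logOrPerSdLdl Log-odds per SD of *higher* latent LDL-C (the
#'   LDL-mediated path).
#' @param logOrPerSdScoreDirect Log-odds per unit of the *higher-LDL* true
#'   locus score, acting directly (pleiotropic path that bypasses LDL-C).
#' @param fatalFraction Probability an event is fatal.
#' @param code ICD-10-style code written to the event table.
#' @return An \linkS4class{OutcomeModel}.
#' @examples
#' outcomeModel("urti", baselineRisk = 0.01,
#'              logOrPerSdScoreDirect = -log(2.18), code = "J06")
#' @export
outcomeModel <- function(outcomeId, baselineRisk, logOrPerSdLdl = 0,
                         logOrPerSdScoreDirect = 0, fatalFraction = 0,
                         code = "R99") {
  new("OutcomeModel", outcomeId = outcomeId, baselineRisk = baselineRisk,
      logOrPerSdLdl = logOrPerSdLdl,
      logOrPerSdScoreDirect = logOrPerSdScoreDirect,
      fatalFraction = fatalFraction, code = code)
}

#' Default outcome panel of the synthetic cohort
#'
#' Five endpoints spanning the association patterns the pipeline must
#' resolve: an occlusive vascular endpoint mediated by LDL-C (protective per
#' SD lower), respiratory endpoints driven directly by the locus score
#' (pleiotropic, so a genome-wide LDL-C score shows nothing), and a null
#' endpoint. Direct-path magnitudes follow the respiratory odds ratios the
#' score analysis is designed to detect (2.18 for upper respiratory tract
#' infection, 1.38 for COPD hospitalisation, 2.28 for asthma, all per 1-SD
#' lower LDL-C).
#'
#' @return List of \linkS4class{OutcomeModel}.
#' @export
defaultOutcomeModels <- function() {
  list(
    outcomeModel("move", baselineRisk = 0.05, logOrPerSdLdl = -log(0.80),
                 fatalFraction = 0.30, code = "I63"),
    outcomeModel("copd", baselineRisk = 0.03,
                 logOrPerSdScoreDirect = -log(1.38),
                 fatalFraction = 0.24, code = "J44"),
    outcomeModel("urti", baselineRisk = 0.012,
                 logOrPerSdScoreDirect = -log(2.18),
                 fatalFraction = 0, code = "J06"),
    outcomeModel("asthma", baselineRisk = 0.006,
                 logOrPerSdScoreDirect = -log(2.28),
                 fatalFraction = 0, code = "J45"),
    outcomeModel("gallstones", baselineRisk = 0.02, code = "K80")
  )
}

#' Configure the synthetic biobank cohort
#'
#' Defaults emulate a 10-region Chinese biobank genotyping subset: LDL-C
#' 2.36 (SD 0.69) mmol/L measured in a random quarter of participants; a
#' 3-SNP locus whose lead loss-of-function variant has effect-allele
#' frequency 0.013 and per-allele effect 0.65 SD on standardised LDL-C, with
#' secondary signals of 0.10 and 0.16 SD; and an independent 64-SNP
#' polygenic LDL-C panel. The two secondary locus frequencies are not
#' directly reported for the emulated study; the defaults 0.35 and 0.032 are
#' back-derived from the printed standard errors of the per-allele effects
#' (0.01 and 0.03 SD) via \code{se = 1/sqrt(2p(1-p) n)} at n = 17,687, the
#' same reasoning that reproduces the lead variant's carrier-count frequency
#' 0.013 from its SE of 0.05.
#'
#' @param nParticipants Cohort size.
#' @param nRegions Number of recruitment regions (default 10).
#' @param locusMaf Effect-allele frequencies of the 3 locus SNPs.
#' @param locusLd \code{"independent"} or 8 haplotype frequencies (names
#'   \code{"000"}..\code{"111"}, bit j = allele at SNP j) summing to 1.
#' @param locusBetas Per-allele locus effects on standardised LDL-C.
#' @param grsNSnps,grsMafs,grsBetas Independent polygenic panel (defaults:
#'   64 SNPs, frequencies spread over 0.10--0.45, per-allele effects
#'   alternating 0.04/0.06 SD).
#' @param covariateEffects Named vector of LDL-C effects in mmol/L per unit
#'   of \code{age} (years), \code{sex} (female = 1) and
#'   \code{fasting_time} (hours).
#' @param ldlMeanMmol,ldlSdMmol Marginal LDL-C mean and SD (mmol/L).
#' @param ldlMeasuredFraction Fraction with an LDL-C assay (default 0.25).
#' @param outcomeModels List of \linkS4class{OutcomeModel}.
#' @param followupYears,baselineYear Follow-up length (default 10 years) and
#'   calendar baseline (default 2006).
#' @param spiroUnusableRegions Regions flagged spirometry-unusable (default
#'   the last two, emulating systematic collection errors).
#' @param copdLiabilityShift,copdLiabilityFraction Ratio z-score shift (SD)
#'   and prevalence of the high-COPD-liability subgroup.
#' @param nPcs Simulated genetic principal components per participant.
#' @param seed Integer master seed; every generator substream derives from
#'   it.
#' @return A validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nParticipants = 1000, seed = 7)
#' cohort <- simulateCohort(cfg)
#' @export
simulationConfig <- function(nParticipants,
                             nRegions = 10L,
                             locusMaf = c(0.013, 0.35, 0.032),
                             locusLd = "independent",
                             locusBetas = c(0.65, 0.10, 0.16),
                             grsNSnps = 64L,
                             grsMafs = seq(0.10, 0.45,
                                           length.out = grsNSnps),
                             grsBetas = rep(c(0.04, 0.06),
                                            length.out = grsNSnps),
                             covariateEffects = c(age = 0.008, sex = 0.05,
                                                  fasting_time = -0.01),
                             ldlMeanMmol = 2.36,
                             ldlSdMmol = 0.69,
                             ldlMeasuredFraction = 0.25,
                             outcomeModels = defaultOutcomeModels(),
                             followupYears = 10,
                             baselineYear = 2006,
                             spiroUnusableRegions = NULL,
                             copdLiabilityShift = -1.5,
                             copdLiabilityFraction = 0.10,
                             nPcs = 5L,
                             seed = 1L) {
  if (is.null(spiroUnusableRegions))
    spiroUnusableRegions <- if (nRegions >= 3L)
      as.integer(c(nRegions - 1L, nRegions)) else integer()
  new("SimulationConfig",
      nParticipants = as.integer(nParticipants),
      nRegions = as.integer(nRegions),
      locusMaf = locusMaf, locusLd = locusLd, locusBetas = locusBetas,
      grsNSnps = as.integer(grsNSnps),
      grsMafs = as.numeric(grsMafs), grsBetas = as.numeric(grsBetas),
      covariateEffects = covariateEffects,
      ldlMeanMmol = ldlMeanMmol, ldlSdMmol = ldlSdMmol,
      ldlMeasuredFraction = ldlMeasuredFraction,
      outcomeModels = outcomeModels,
      followupYears = followupYears, baselineYear = baselineYear,
      spiroUnusableRegions = as.integer(spiroUnusableRegions),
      copdLiabilityShift = copdLiabilityShift,
      copdLiabilityFraction = copdLiabilityFraction,
      nPcs = as.integer(nPcs), seed = as.integer(seed))
}

## Deterministic substream seed derived from the master seed and a stream
## name, kept below 2^31.
subSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483587)
}
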