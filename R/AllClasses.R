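#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

## ---------------------------------------------------------------------------
## OutcomeModel
## ---------------------------------------------------------------------------

#' Binary-outcome generating model for the synthetic cohort
#'
#' Describes one simulated disease endpoint. Disease liability acts on the
#' log-odds scale through two channels: an LDL-C-mediated path (log-odds per
#' SD of the participant's latent standardised LDL-C) and a direct,
#' pleiotropic path (log-odds per unit of the true locus score, bypassing
#' LDL-C). The direct path exists so that heterogeneity between a locus score
#' and a genome-wide LDL-C score has simulated power.
#'
#' @slot outcomeId Character label.
#' @slot baselineRisk Cumulative event probability at zero liability.
#' @slot logOrPerSdLdl Log-odds per SD of latent LDL-C (mediated path).
#' @slot logOrPerSdScoreDirect Log-odds per SD-of-LDL unit of the true locus
#'   score (pleiotropic path).
#' @slot fatalFraction Probability that an event carries a fatal flag.
#' @slot code ICD-10-style code attached to generated events.
#' @export
setClass("OutcomeModel",
  representation(
    outcomeId = "character",
    baselineRisk = "numeric",
    logOrPerSdLdl = "numeric",
    logOrPerSdScoreDirect = "numeric",
    fatalFraction = "numeric",
    code = "character"
  )
)

setValidity("OutcomeModel", function(object) {
  msg <- character()
  if (length(object@outcomeId) != 1L || !nzchar(object@outcomeId))
    msg <- c(msg, "'outcomeId' must be a non-empty string")
  for (s in c("baselineRisk", "fatalFraction")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("'%s' must be a probability in [0, 1]", s))
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## SimulationConfig
## ---------------------------------------------------------------------------

#' Configuration of the synthetic biobank cohort
#'
#' Holds every parameter of the generator: cohort size and regional
#' structure, the 3-SNP locus (allele frequencies, optional haplotype-level
#' linkage disequilibrium, per-allele effects on standardised LDL-C), an
#' independent polygenic SNP panel, covariate effects on LDL-C in mmol/L,
#' the LDL-C marginal distribution and measured subset, outcome models,
#' spirometry parameters and follow-up. Construct with
#' \code{\link{simulationConfig}}, which supplies defaults.
#'
#' @slot nParticipants,nRegions Cohort size and number of recruitment regions.
#' @slot locusMaf Effect-allele frequencies of the 3 locus SNPs.
#' @slot locusLd Either the string \code{"independent"} or a numeric vector of
#'   8 haplotype frequencies (names: binary strings \code{"000"} ...
#'   \code{"111"}) summing to 1.
#' @slot locusBetas Per-allele effects of the locus SNPs on standardised
#'   LDL-C (SD units).
#' @slot grsNSnps,grsMafs,grsBetas The independent polygenic panel.
#' @slot covariateEffects Named effects (mmol/L per unit) of \code{age},
#'   \code{sex}, \code{fasting_time} on LDL-C.
#' @slot ldlMeanMmol,ldlSdMmol Marginal mean and SD of LDL-C in mmol/L.
#' @slot ldlMeasuredFraction Fraction of the cohort with an LDL-C assay
#'   (missing completely at random elsewhere).
#' @slot outcomeModels List of \linkS4class{OutcomeModel}.
#' @slot followupYears,baselineYear Follow-up length and calendar baseline.
#' @slot spiroUnusableRegions Integer region codes whose spirometry is
#'   flagged unusable (emulating systematic collection errors).
#' @slot copdLiabilityShift,copdLiabilityFraction Downward shift (in ratio
#'   z-score SDs) and prevalence of the high-COPD-liability subgroup.
#' @slot nPcs Number of simulated genetic principal components.
#' @slot seed Integer seed; all generator randomness flows from it.
#' @export
setClass("SimulationConfig",
  representation(
    nParticipants = "integer",
    nRegions = "integer",
    locusMaf = "numeric",
    locusLd = "ANY",
    locusBetas = "numeric",
    grsNSnps = "integer",
    grsMafs = "numeric",
    grsBetas = "numeric",
    covariateEffects = "numeric",
    ldlMeanMmol = "numeric",
    ldlSdMmol = "numeric",
    ldlMeasuredFraction = "numeric",
    outcomeModels = "list",
    followupYears = "numeric",
    baselineYear = "numeric",
    spiroUnusableRegions = "integer",
    copdLiabilityShift = "numeric",
    copdLiabilityFraction = "numeric",
    nPcs = "integer",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nParticipants < 1L) msg <- c(msg, "'nParticipants' must be positive")
  if (object@nRegions < 1L) msg <- c(msg, "'nRegions' must be positive")
  if (length(object@locusMaf) != 3L || any(object@locusMaf < 0) ||
      any(object@locusMaf >= 1))
    msg <- c(msg, "'locusMaf' must be 3 frequencies in [0, 1)")
  if (length(object@locusBetas) != 3L)
    msg <- c(msg, "'locusBetas' must have length 3")
  ld <- object@locusLd
  if (is.character(ld)) {
    if (!identical(ld, "independent"))
      msg <- c(msg, "character 'locusLd' must be \"independent\"")
  } else if (is.numeric(ld)) {
    if (length(ld) != 8L)
      msg <- c(msg, "'locusLd' haplotype table must have 8 frequencies")
    if (any(ld < 0))
      msg <- c(msg, "haplotype frequencies must be non-negative")
    if (abs(sum(ld) - 1) > 1e-12)
      msg <- c(msg, "haplotype frequencies must sum to 1 (tolerance 1e-12)")
  } else msg <- c(msg, "'locusLd' must be \"independent\" or 8 haplotype frequencies")
  if (length(object@grsMafs) != object@grsNSnps ||
      length(object@grsBetas) != object@grsNSnps)
    msg <- c(msg, "'grsMafs'/'grsBetas' must match 'grsNSnps'")
  if (object@grsNSnps > 0L && (any(object@grsMafs <= 0) || any(object@grsMafs >= 1)))
    msg <- c(msg, "'grsMafs' must lie in (0, 1)")
  if (object@ldlSdMmol <= 0) msg <- c(msg, "'ldlSdMmol' must be > 0")
  if (object@ldlMeasuredFraction < 0 || object@ldlMeasuredFraction > 1)
    msg <- c(msg, "'ldlMeasuredFraction' must be in [0, 1]")
  if (!all(vapply(object@outcomeModels, is, TRUE, "OutcomeModel")))
    msg <- c(msg, "'outcomeModels' must be a list of OutcomeModel")
  if (object@followupYears <= 0) msg <- c(msg, "'followupYears' must be positive")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## GeneticCohort
## ---------------------------------------------------------------------------

#' Synthetic (or imported) genotyped cohort
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} with SNPs in rows and
#' participants in columns. The single assay \code{"dosage"} holds effect
#' allele dosages in \[0, 2\]; \code{rowData} annotates SNPs (see
#' \code{\link{snpInfo}}); \code{colData} carries participant covariates and
#' phenotypes (see \code{\link{participantData}}); the follow-up event table
#' lives in \code{metadata(x)$events} (see \code{\link{eventData}}).
#'
#' @seealso \code{\link{simulateCohort}}
#' @export
setClass("GeneticCohort", contains = "SummarizedExperiment")

setValidity("GeneticCohort", function(object) {
  msg <- character()
  if (!"dosage" %in% assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- assay(object, "dosage")
    if (any(d < 0 | d > 2, na.rm = TRUE))
      msg <- c(msg, "dosages must lie in [0, 2]")
  }
  ev <- metadata(object)$events
  if (!is.null(ev) && !all(c("id", "code", "year", "fatal") %in% names(ev)))
    msg <- c(msg, "metadata()$events needs columns id, code, year, fatal")
  cd <- colData(object)
  if (all(c("fev1", "fvc") %in% names(cd))) {
    ok <- is.na(cd$fev1) | is.na(cd$fvc) |
      (cd$fvc >= cd$fev1 & cd$fev1 > 0)
    if (!all(ok)) msg <- c(msg, "need fvc >= fev1 > 0 wherever spirometry present")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname dosages
#' @export
setMethod("dosages", "GeneticCohort", function(x) assay(x, "dosage"))

#' @rdname snpInfo
#' @export
setMethod("snpInfo", "GeneticCohort", function(x) rowData(x))

#' @rdname participantData
#' @export
setMethod("participantData", "GeneticCohort",
  function(x) as.data.frame(colData(x)))

#' @rdname eventData
#' @export
setMethod("eventData", "GeneticCohort", function(x) {
  ev <- metadata(x)$events
  if (is.null(ev))
    ev <- data.frame(id = character(), code = character(),
                     year = numeric(), fatal = logical())
  ev
})

setMethod("show", "GeneticCohort", function(object) {
  callNextMethod()
  ev <- metadata(object)$events
  cat(sprintf("events: %d records, %d participants with >=1 event\n",
              if (is.null(ev)) 0L else nrow(ev),
              if (is.null(ev)) 0L else length(unique(ev$id))))
})

## ---------------------------------------------------------------------------
## ScoreWeights
## ---------------------------------------------------------------------------

#' Per-allele score weights with optional jackknife structure
#'
#' Weights calibrate a dosage-weighted score to predicted SD units of
#' rank-normalised LDL-C. When a block jackknife has been run,
#' \code{perBlockBetas} holds, per block, the weights estimated with that
#' block held out, and \code{blockMap} assigns each weight-estimation
#' participant to a block (participants outside the estimation sample get
#' \code{NA} and are scored with the full-sample weights).
#'
#' @slot snpIds SNP identifiers (counted-allele orientation of the dosage
#'   file; no strand flipping is attempted).
#' @slot effectAlleles Counted allele labels, recorded for the manifest.
#' @slot betas,ses Full-sample per-allele effects and standard errors.
#' @slot blockMap Named integer vector (participant id to block; NA = full).
#' @slot perBlockBetas Blocks-by-SNP matrix of leave-one-block-out weights.
#' @export
setClass("ScoreWeights",
  representation(
    snpIds = "character",
    effectAlleles = "character",
    betas = "numeric",
    ses = "numeric",
    blockMap = "integer",
    perBlockBetas = "matrix"
  )
)

setValidity("ScoreWeights", function(object) {
  msg <- character()
  p <- length(object@snpIds)
  if (length(object@betas) != p || length(object@ses) != p)
    msg <- c(msg, "'betas' and 'ses' must match 'snpIds' in length")
  if (length(object@ses) && any(object@ses < 0, na.rm = TRUE))
    msg <- c(msg, "'ses' must be non-negative")
  if (nrow(object@perBlockBetas) > 0L && ncol(object@perBlockBetas) != p)
    msg <- c(msg, "'perBlockBetas' must have one column per SNP")
  if (nrow(object@perBlockBetas) > 0L && length(object@blockMap)) {
    bm <- object@blockMap[!is.na(object@blockMap)]
    if (length(bm) && (min(bm) < 1L || max(bm) > nrow(object@perBlockBetas)))
      msg <- c(msg, "'blockMap' indexes outside 'perBlockBetas' rows")
  }
  if (length(msg)) msg else TRUE
})

#' Construct ScoreWeights
#'
#' @param snpIds,betas,ses SNP identifiers, per-allele effects (SD of
#'   rank-normalised LDL-C) and standard errors.
#' @param effectAlleles Counted allele labels (defaults to \code{"A"}).
#' @param blockMap Named integer block assignment (optional).
#' @param perBlockBetas Blocks-by-SNP leave-one-block-out weights (optional).
#' @return A \linkS4class{ScoreWeights}.
#' @export
ScoreWeights <- function(snpIds, betas, ses,
                         effectAlleles = rep("A", length(snpIds)),
                         blockMap = integer(),
                         perBlockBetas = matrix(numeric(), 0L, length(snpIds))) {
  new("ScoreWeights", snpIds = as.character(snpIds), betas = as.numeric(betas),
      ses = as.numeric(ses), effectAlleles = as.character(effectAlleles),
      blockMap = blockMap, perBlockBetas = perBlockBetas)
}

#' @rdname weightBetas
#' @export
setMethod("weightBetas", "ScoreWeights",
  function(x) stats::setNames(x@betas, x@snpIds))

#' @rdname weightSes
#' @export
setMethod("weightSes", "ScoreWeights",
  function(x) stats::setNames(x@ses, x@snpIds))

#' @rdname blockMap
#' @export
setMethod("blockMap", "ScoreWeights", function(x) x@blockMap)

#' @rdname perBlockBetas
#' @export
setMethod("perBlockBetas", "ScoreWeights", function(x) x@perBlockBetas)

setMethod("show", "ScoreWeights", function(object) {
  cat(sprintf("ScoreWeights: %d SNPs%s\n", length(object@snpIds),
              if (nrow(object@perBlockBetas))
                sprintf(", %d jackknife blocks", nrow(object@perBlockBetas))
              else ""))
  print(data.frame(snp = object@snpIds, allele = object@effectAlleles,
                   beta = object@betas, se = object@ses))
})

## ---------------------------------------------------------------------------
## EffectEstimate
## ---------------------------------------------------------------------------

#' One association estimate with its unit and orientation
#'
#' @slot outcomeId Endpoint or trait label.
#' @slot beta Log-odds (binary) or SD units (continuous).
#' @slot se,p Standard error and two-sided Wald p-value.
#' @slot nCases,nControls Counts for binary endpoints (NA for continuous).
#' @slot n Analysis sample size.
#' @slot unit One of \code{"per-unit-score"}, \code{"per-SD-lower-LDL"},
#'   \code{"per-allele"}.
#' @slot orientation \code{"ldl-raising"} or \code{"ldl-lowering"}.
#' @slot nStrata Number of strata pooled.
#' @export
setClass("EffectEstimate",
  representation(
    outcomeId = "character", beta = "numeric", se = "numeric", p = "numeric",
    nCases = "integer", nControls = "integer", n = "integer",
    unit = "character", orientation = "character", nStrata = "integer"
  ),
  prototype(nCases = NA_integer_, nControls = NA_integer_, n = NA_integer_,
            unit = "per-unit-score", orientation = "ldl-raising",
            nStrata = 1L)
)

setValidity("EffectEstimate", function(object) {
  msg <- character()
  if (!is.na(object@se) && object@se <= 0)
    msg <- c(msg, "'se' must be positive")
  if (!is.na(object@p) && (object@p < 0 || object@p > 1))
    msg <- c(msg, "'p' must lie in [0, 1]")   # 0 only by numeric underflow
  if (!object@unit %in% c("per-unit-score", "per-SD-lower-LDL", "per-allele"))
    msg <- c(msg, "unknown 'unit'")
  if (!object@orientation %in% c("ldl-raising", "ldl-lowering"))
    msg <- c(msg, "unknown 'orientation'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EffectEstimate", function(object) {
  cat(sprintf("EffectEstimate '%s' (%s, %s)\n", object@outcomeId,
              object@unit, object@orientation))
  cat(sprintf("  beta = %.4f (se %.4f), p = %.3g", object@beta, object@se,
              object@p))
  if (!is.na(object@nCases))
    cat(sprintf(", cases/controls = %d/%d", object@nCases, object@nControls))
  cat(sprintf(", strata pooled = %d\n", object@nStrata))
})

#' Flatten EffectEstimate(s) to a data.frame
#'
#' @param x An \linkS4class{EffectEstimate} or list of them.
#' @return A \code{data.frame} with odds ratios and 95\% CI added for
#'   log-odds estimates.
#' @export
effectTable <- function(x) {
  if (is(x, "EffectEstimate")) x <- list(x)
  do.call(rbind, lapply(x, function(e) {
    z <- stats::qnorm(0.975)
    data.frame(outcome_id = e@outcomeId, beta = e@beta, se = e@se,
               or = exp(e@beta), ci_low = exp(e@beta - z * e@se),
               ci_high = exp(e@beta + z * e@se), p = e@p,
               n_cases = e@nCases, n_controls = e@nControls, n = e@n,
               unit = e@unit, orientation = e@orientation,
               strata_pooled = e@nStrata, row.names = NULL)
  }))
}

## ---------------------------------------------------------------------------
## MetaResult
## ---------------------------------------------------------------------------

#' Fixed-effect meta-analysis result with heterogeneity
#'
#' @slot beta,se,p Inverse-variance-weighted pooled estimate, its standard
#'   error and two-sided Wald p-value.
#' @slot q Cochran's Q statistic.
#' @slot df Degrees of freedom (k - 1).
#' @slot pHet Upper-tail chi-square p-value for Q (NA when k = 1).
#' @slot k Number of estimates pooled.
#' @export
setClass("MetaResult",
  representation(beta = "numeric", se = "numeric", p = "numeric",
                 q = "numeric", df = "integer", pHet = "numeric",
                 k = "integer"))

setValidity("MetaResult", function(object) {
  msg <- character()
  if (object@se <= 0) msg <- c(msg, "'se' must be positive")
  if (!is.na(object@q) && object@q < -1e-8) msg <- c(msg, "'q' must be >= 0")
  if (object@df != object@k - 1L) msg <- c(msg, "'df' must equal k - 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MetaResult", function(object) {
  cat(sprintf("MetaResult (k = %d)\n", object@k))
  cat(sprintf("  pooled beta = %.4f (se %.4f), OR = %.3f, p = %.3g\n",
              object@beta, object@se, exp(object@beta), object@p))
  if (object@df > 0L)
    cat(sprintf("  Cochran Q = %.3f on %d df, P-het = %.3g\n",
                object@q, object@df, object@pHet))
})

## ---------------------------------------------------------------------------
## LmsReference
## ---------------------------------------------------------------------------

#' LMS reference for the FEV1/FVC ratio
#'
#' Lambda-mu-sigma (skewness/median/scatter) reference equations for the
#' FEV1/FVC ratio, per sex, as polynomial coefficient tables: for each sex,
#' \code{l} and \code{s} are polynomials in age (coefficients in increasing
#' order) and \code{m} is \code{m[1] + m[2]*age + m[3]*height_cm}. The lower
#' limit of normal is the \code{centile} quantile (default 5th) of the
#' reference distribution. The published spirometry lookup tables are
#' external artifacts; this class carries pluggable coefficients and the
#' package ships a self-consistent synthetic default
#' (\code{\link{defaultLmsReference}}) matched to the cohort generator.
#'
#' @slot male,female Lists with elements \code{l}, \code{m}, \code{s}.
#' @slot centile Quantile defining the lower limit of normal.
#' @slot ageRange Supported age range in years.
#' @export
setClass("LmsReference",
  representation(male = "list", female = "list", centile = "numeric",
                 ageRange = "numeric"))

setValidity("LmsReference", function(object) {
  msg <- character()
  for (sx in c("male", "female")) {
    cf <- slot(object, sx)
    if (!all(c("l", "m", "s") %in% names(cf)))
      msg <- c(msg, sprintf("'%s' needs elements l, m, s", sx))
  }
  if (object@centile <= 0 || object@centile >= 1)
    msg <- c(msg, "'centile' must lie in (0, 1)")
  if (length(object@ageRange) != 2L || diff(object@ageRange) <= 0)
    msg <- c(msg, "'ageRange' must be an increasing pair")
  if (length(msg)) msg else TRUE
})
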