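#' @import methods
NULL

#' Extract the dosage matrix
#'
#' Returns the SNP-by-participant allele dosage matrix (values in \[0, 2\])
#' stored in a \linkS4class{GeneticCohort}.
#'
#' @param x A \linkS4class{GeneticCohort}.
#' @return A numeric matrix, SNPs in rows, participants in columns.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' SNP annotation accessor
#'
#' @param x A \linkS4class{GeneticCohort}.
#' @return A \code{DataFrame} with one row per SNP: identifier, effect allele,
#'   configured minor-allele frequency, SNP class (\code{"locus"} or
#'   \code{"grs"}) and, for simulated cohorts, the true per-allele effect.
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' Participant-level data accessor
#'
#' @param x A \linkS4class{GeneticCohort}.
#' @return A \code{data.frame} of per-participant covariates and phenotypes
#'   (region, age, sex, fasting time, height, principal components, LDL-C,
#'   spirometry, baseline self-report flags, ascertainment category).
#' @export
setGeneric("participantData", function(x) standardGeneric("participantData"))

#' Event-history accessor
#'
#' @param x A \linkS4class{GeneticCohort}.
#' @return A \code{data.frame} of follow-up events with columns \code{id},
#'   \code{code} (ICD-10-style), \code{year} and \code{fatal}.
#' @export
setGeneric("eventData", function(x) standardGeneric("eventData"))

#' Per-allele weight accessor
#'
#' @param x A \linkS4class{ScoreWeights}.
#' @return Named numeric vector of full-sample per-allele effects (SD units of
#'   rank-normalised LDL-C).
#' @export
setGeneric("weightBetas", function(x) standardGeneric("weightBetas"))

#' Weight standard-error accessor
#'
#' @param x A \linkS4class{ScoreWeights}.
#' @return Named numeric vector of standard errors of the full-sample weights.
#' @export
setGeneric("weightSes", function(x) standardGeneric("weightSes"))

#' Jackknife block assignment accessor
#'
#' @param x A \linkS4class{ScoreWeights}.
#' @return Integer vector, named by participant id, giving each participant's
#'   jackknife block; \code{NA} marks participants that receive full-sample
#'   weights.
#' @export
setGeneric("blockMap", function(x) standardGeneric("blockMap"))

#' Leave-one-block-out weight matrix accessor
#'
#' @param x A \linkS4class{ScoreWeights}.
#' @return Numeric matrix (blocks by SNPs); row \code{b} holds the weights
#'   estimated with block \code{b} held out. Zero rows when no jackknife has
#'   been run.
#' @export
setGeneric("perBlockBetas", function(x) standardGeneric("perBlockBetas"))

#' Build a calibrated genetic score
#'
#' Computes, for every participant, the dosage-weighted sum of per-allele
#' effects. When the weights carry a jackknife block assignment, each
#' participant in a block is scored with the weights estimated with their own
#' block excluded, removing the correlation between weight error and own
#' phenotype that biases internally weighted scores; participants without a
#' block receive the full-sample weights.
#'
#' @param x A \linkS4class{GeneticCohort} or a participant-by-SNP dosage
#'   matrix.
#' @param weights A \linkS4class{ScoreWeights} whose SNPs are all present in
#'   \code{x}.
#' @param ... Unused.
#' @return Named numeric score vector in predicted SD-of-LDL-C units; higher
#'   score predicts higher LDL-C.
#' @examples
#' w <- ScoreWeights(snpIds = c("a", "b", "c"), betas = c(0.65, 0.10, 0.16),
#'                   ses = c(0.05, 0.01, 0.03))
#' buildScore(matrix(c(1, 0, 2), 1, dimnames = list("p1", c("a", "b", "c"))), w)
#' @export
setGeneric("buildScore", function(x, weights, ...) standardGeneric("buildScore"))
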