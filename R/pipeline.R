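#' Run the full score-association pipeline
#'
#' Orchestrates the analysis end to end on a \linkS4class{GeneticCohort}:
#' stratum-specific residualisation and rank-normalisation of LDL-C;
#' mutually adjusted locus weights with 100-fold block-jackknifed internal
#' weights; score construction in predicted-SD-of-LDL-C units; instrument
#' diagnostics; an externally weighted, heterogeneity-filtered polygenic
#' LDL-C score; region-stratified logistic associations for every endpoint,
#' pooled by inverse-variance-weighted fixed-effect meta-analysis and
#' reoriented to per 1-SD-lower LDL-C; per-endpoint heterogeneity between
#' the locus and polygenic instruments; and Benjamini-Hochberg plus
#' Bonferroni significance flags.
#'
#' @param cohort A \linkS4class{GeneticCohort}.
#' @param endpoints List of \code{\link{endpointDefinition}}s; \code{NULL}
#'   derives one simple endpoint per simulated outcome model.
#' @param B Number of jackknife blocks (default 100).
#' @param seed Seed for the block assignment.
#' @param spec A \code{\link{transformSpec}} for the LDL-C transform.
#' @param assocCovariates Covariate column names for the association models
#'   (default age, age squared, sex and all principal components).
#' @param externalGrs Optional \code{data.frame(snp, beta, se)} of external
#'   polygenic weights; \code{NULL} uses the simulation's generating betas
#'   (with a nominal SE) as the external source.
#' @param alphaNonVascular Family-wise level for the Bonferroni threshold
#'   over non-vascular endpoints.
#' @param outDir Optional directory; when given, results, weights and a
#'   machine-readable JSON run log are written as text files.
#' @return List with elements \code{weights} (\linkS4class{ScoreWeights}),
#'   \code{score}, \code{diagnostics}, \code{grs}, \code{results} (one row
#'   per endpoint and instrument, per 1-SD-lower-LDL scale),
#'   \code{heterogeneity}, and \code{log}.
#' @export
runPipeline <- function(cohort, endpoints = NULL, B = 100L, seed = 1L,
                        spec = transformSpec(),
                        assocCovariates = NULL, externalGrs = NULL,
                        alphaNonVascular = 0.05, outDir = NULL) {
  stopifnot(is(cohort, "GeneticCohort"))
  pd <- participantData(cohort)
  info <- snpInfo(cohort)
  dmat <- t(dosages(cohort))
  pcCols <- grep("^pc[0-9]+$", names(pd), value = TRUE)
  log <- list(seed = as.integer(seed), n = nrow(pd))

  ## 1. phenotype transform (stratum-specific residualise + RINT)
  covTrans <- cbind(covariateColumns(pd, spec$covariates),
                    pd[, pcCols, drop = FALSE])
  strata <- if (identical(spec$strata, "none")) NULL else pd[[spec$strata]]
  rintLdl <- suppressWarnings(
    stratifiedTransform(pd$ldl_mmol, covTrans, strata,
                        minStratumSize = spec$minStratumSize,
                        offset = spec$rintOffset))
  log$n_ldl_measured <- sum(!is.na(pd$ldl_mmol))
  log$n_ldl_transformed <- attr(rintLdl, "nUsed")

  ## 2. jackknifed locus weights
  locusSnps <- info$snp_id[info$class == "locus"]
  if (!length(locusSnps)) locusSnps <- colnames(dmat)[seq_len(3L)]
  estIds <- pd$id[!is.na(rintLdl)]
  blocks <- assignJackknifeBlocks(estIds, B = B, seed = seed)
  wts <- jackknifeWeights(dmat[, locusSnps, drop = FALSE], rintLdl,
                          covTrans, strata, blocks)
  score <- buildScore(dmat, wts)

  ## 3. instrument diagnostics on the measured subset
  diag <- instrumentStrength(score, rintLdl, covTrans)

  ## 4. polygenic score with heterogeneity filter
  grs <- NULL
  grsSnps <- info$snp_id[info$class == "grs"]
  if (length(grsSnps)) {
    if (is.null(externalGrs)) {
      externalGrs <- data.frame(snp = grsSnps,
                                beta = info$true_beta[info$class == "grs"],
                                se = 0.01)
    }
    internal <- fitMarginalWeights(dmat[, grsSnps, drop = FALSE], rintLdl,
                                   covTrans, strata)
    grs <- buildPolygenicScore(
      dmat[, grsSnps, drop = FALSE],
      externalBetas = setNames(externalGrs$beta, externalGrs$snp)[grsSnps],
      externalSes = setNames(externalGrs$se, externalGrs$snp)[grsSnps],
      internalBetas = setNames(internal$beta, internal$snp)[grsSnps],
      internalSes = setNames(internal$se, internal$snp)[grsSnps])
    log$grs_snps_kept <- length(grs$kept)
  }

  ## 5. endpoint associations, both instruments
  if (is.null(endpoints)) {
    cfg <- metadata(cohort)$config
    if (is.null(cfg)) stop("supply 'endpoints' for a non-simulated cohort")
    endpoints <- lapply(cfg@outcomeModels, function(m)
      endpointDefinition(m@outcomeId, caseCodes = m@code))
  }
  if (is.null(assocCovariates))
    assocCov <- cbind(covariateColumns(pd, c("age", "age2", "sex")),
                      pd[, pcCols, drop = FALSE])
  else
    assocCov <- covariateColumns(pd, assocCovariates)
  rows <- list()
  hets <- list()
  warnings <- character()
  for (defn in endpoints) {
    res <- tryCatch({
      labels <- buildEndpoint(cohort, defn)
      est <- withCallingHandlers(
        logisticAssoc(labels, score, assocCov, strata,
                      outcomeId = defn$outcomeId),
        warning = function(w) {
          warnings <<- c(warnings, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      locusRow <- effectTable(orientPerSdLowerLdl(est))
      locusRow$instrument <- "locus"
      locusRow$excluded <- attr(labels, "counts")[["excluded"]]
      out <- locusRow
      if (!is.null(grs)) {
        estG <- withCallingHandlers(
          logisticAssoc(labels, grs$score, assocCov, strata,
                        outcomeId = defn$outcomeId),
          warning = function(w) {
            warnings <<- c(warnings, conditionMessage(w))
            invokeRestart("muffleWarning")
          })
        grsRow <- effectTable(orientPerSdLowerLdl(estG))
        grsRow$instrument <- "ldl_grs"
        grsRow$excluded <- attr(labels, "counts")[["excluded"]]
        out <- rbind(locusRow, grsRow)
        hets[[defn$outcomeId]] <- data.frame(
          outcome_id = defn$outcomeId,
          q = cochranQ(c(locusRow$beta, grsRow$beta),
                       c(locusRow$se, grsRow$se))$q,
          p_het = cochranQ(c(locusRow$beta, grsRow$beta),
                           c(locusRow$se, grsRow$se))$pHet)
      }
      out
    }, error = function(e) {
      warnings <<- c(warnings, sprintf("%s: %s", defn$outcomeId,
                                       conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[defn$outcomeId]] <- res
  }
  if (!length(rows)) stop("no endpoint could be analysed")
  results <- do.call(rbind, c(rows, make.row.names = FALSE))

  ## 6. multiplicity
  isLocus <- results$instrument == "locus"
  results$fdr_significant <- NA
  results$fdr_significant[isLocus] <- bhFdr(results$p[isLocus])
  thr <- bonferroniThreshold(alphaNonVascular, sum(isLocus), digits = NULL)
  results$bonferroni_significant <- results$p < thr & isLocus
  log$bonferroni_threshold <- thr
  log$strata_warnings <- warnings
  log$instrument_f <- diag$fStatistic
  log$instrument_r2 <- diag$rSquared

  het <- if (length(hets)) do.call(rbind, c(hets, make.row.names = FALSE))
         else NULL
  out <- list(weights = wts, score = score, diagnostics = diag, grs = grs,
              results = results, heterogeneity = het, log = log)
  if (!is.null(outDir)) writePipelineResults(out, outDir)
  out
}

writePipelineResults <- function(out, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(out$results, file.path(dir, "results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  w <- out$weights
  utils::write.table(
    data.frame(snp_id = w@snpIds, effect_allele = w@effectAlleles,
               beta = w@betas, se = w@ses, source = "internal-jackknife"),
    file.path(dir, "weights.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (nrow(perBlockBetas(w)) > 0L)
    utils::write.table(
      cbind(data.frame(block = seq_len(nrow(perBlockBetas(w)))),
            as.data.frame(perBlockBetas(w))),
      file.path(dir, "per_block_betas.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  if (!is.null(out$heterogeneity))
    utils::write.table(out$heterogeneity,
                       file.path(dir, "heterogeneity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  jsonlite::write_json(out$log, file.path(dir, "runlog.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
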