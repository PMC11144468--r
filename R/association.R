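## ---------------------------------------------------------------------------
## ICD-10 code ranges
## ---------------------------------------------------------------------------

## Ordinal of a 3-character ICD-10 category: letter * 100 + number.
icdOrd <- function(code) {
  code <- toupper(trimws(code))
  bad <- !grepl("^[A-Z][0-9]{2}", code)
  if (any(bad)) stop("unparseable ICD-10 code(s): ",
                     paste(code[bad], collapse = ", "))
  (match(substr(code, 1L, 1L), LETTERS) - 1L) * 100L +
    as.integer(substr(code, 2L, 3L))
}

## Parse code specs like "J44", "J40-J44" into an ordinal interval matrix.
icdRanges <- function(specs) {
  t(vapply(specs, function(s) {
    parts <- strsplit(s, "-", fixed = TRUE)[[1L]]
    if (length(parts) == 1L) rep(icdOrd(parts), 2L)
    else if (length(parts) == 2L) {
      r <- c(icdOrd(parts[1L]), icdOrd(parts[2L]))
      if (r[1L] > r[2L]) stop("ill-formed ICD-10 range: ", s)
      r
    } else stop("ill-formed ICD-10 range: ", s)
  }, integer(2)))
}

#' Match event codes against ICD-10 codes/ranges
#'
#' A code matches when its 3-character category (subcodes such as
#' \code{"J44.1"} truncate to \code{"J44"}) falls inside any listed code or
#' inclusive range (\code{"J40-J44"}).
#'
#' @param codes Character vector of event codes.
#' @param specs Character vector of codes and/or ranges.
#' @return Logical vector aligned with \code{codes}.
#' @export
icdMatches <- function(codes, specs) {
  if (!length(specs) || !length(codes)) return(rep(FALSE, length(codes)))
  rng <- icdRanges(specs)
  ord <- icdOrd(codes)
  out <- rep(FALSE, length(codes))
  for (i in seq_len(nrow(rng)))
    out <- out | (ord >= rng[i, 1L] & ord <= rng[i, 2L])
  out
}

## ---------------------------------------------------------------------------
## Endpoint definitions
## ---------------------------------------------------------------------------

#' Define a disease endpoint
#'
#' Describes how cases and controls are constructed from the event history
#' and baseline questionnaire: ICD-10 case codes/ranges, event codes that
#' exclude controls, baseline self-report flags that exclude controls, the
#' control-set style, ascertainment-category exclusions (participants
#' genotyped for a different disease panel), an optional restriction to the
#' population-representative subset, and an optional minimum calendar year
#' for cases (used for endpoints with reporting artefacts).
#'
#' @param outcomeId Endpoint label.
#' @param caseCodes Character codes/ranges (e.g. \code{"J40-J44"}).
#' @param controlExclusionCodes Codes/ranges whose follow-up events exclude
#'   a participant from the control group.
#' @param baselineSelfReportExclusions Names of baseline flags (without the
#'   \code{self_} prefix, e.g. \code{"chd"}) excluding controls.
#' @param controlSet \code{"disease-specific"} or \code{"common-vascular"}
#'   (bookkeeping label; the exclusion lists carry the logic).
#' @param ascertainmentExclusions Ascertainment categories removed from both
#'   cases and controls.
#' @param restrictToPopulationSubset Keep only
#'   \code{ascertainment_category == "population"}.
#' @param minYear Discard case events before this calendar year.
#' @return A classed list (\code{"EndpointDefinition"}).
#' @export
endpointDefinition <- function(outcomeId, caseCodes,
                               controlExclusionCodes = character(),
                               baselineSelfReportExclusions = character(),
                               controlSet = c("disease-specific",
                                              "common-vascular"),
                               ascertainmentExclusions = character(),
                               restrictToPopulationSubset = FALSE,
                               minYear = NULL) {
  controlSet <- match.arg(controlSet)
  invisible(icdRanges(caseCodes))  # validate early
  if (length(controlExclusionCodes)) invisible(icdRanges(controlExclusionCodes))
  structure(list(outcomeId = outcomeId, caseCodes = caseCodes,
                 controlExclusionCodes = controlExclusionCodes,
                 baselineSelfReportExclusions = baselineSelfReportExclusions,
                 controlSet = controlSet,
                 ascertainmentExclusions = ascertainmentExclusions,
                 restrictToPopulationSubset = restrictToPopulationSubset,
                 minYear = minYear),
            class = "EndpointDefinition")
}

#' Build case/control labels for an endpoint
#'
#' Cases are participants with any follow-up event matching the case codes
#' (respecting \code{minYear}). Controls are all remaining participants
#' minus those excluded by baseline self-report flags or control-exclusion
#' events. Participants removed by ascertainment rules (or, when requested,
#' outside the population-representative subset) are excluded from both
#' groups. Counts always reconcile: cases + controls + excluded = cohort
#' size.
#'
#' @param cohort A \linkS4class{GeneticCohort}.
#' @param defn An \code{\link{endpointDefinition}}.
#' @return Named integer vector (1 case, 0 control, NA excluded) with a
#'   \code{"counts"} attribute.
#' @export
buildEndpoint <- function(cohort, defn) {
  stopifnot(is(cohort, "GeneticCohort"), inherits(defn, "EndpointDefinition"))
  pd <- participantData(cohort)
  ev <- eventData(cohort)
  ids <- pd$id
  excluded <- rep(FALSE, length(ids))
  if (defn$restrictToPopulationSubset)
    excluded <- excluded | pd$ascertainment_category != "population"
  if (length(defn$ascertainmentExclusions))
    excluded <- excluded |
      pd$ascertainment_category %in% defn$ascertainmentExclusions
  caseEv <- ev[icdMatches(ev$code, defn$caseCodes), , drop = FALSE]
  if (!is.null(defn$minYear))
    caseEv <- caseEv[caseEv$year >= defn$minYear, , drop = FALSE]
  isCase <- ids %in% caseEv$id & !excluded
  if (!any(isCase)) stop("endpoint '", defn$outcomeId,
                         "' has no cases after filtering")
  ctrlExcl <- rep(FALSE, length(ids))
  for (flag in defn$baselineSelfReportExclusions) {
    col <- paste0("self_", flag)
    if (!col %in% names(pd)) stop("missing baseline flag column: ", col)
    ctrlExcl <- ctrlExcl | pd[[col]]
  }
  if (length(defn$controlExclusionCodes)) {
    exclEv <- ev[icdMatches(ev$code, defn$controlExclusionCodes), ,
                 drop = FALSE]
    ctrlExcl <- ctrlExcl | ids %in% exclEv$id
  }
  labels <- rep(NA_integer_, length(ids))
  labels[isCase] <- 1L
  labels[!isCase & !excluded & !ctrlExcl] <- 0L
  names(labels) <- ids
  counts <- c(cases = sum(labels == 1L, na.rm = TRUE),
              controls = sum(labels == 0L, na.rm = TRUE),
              excluded = sum(is.na(labels)))
  attr(labels, "counts") <- counts
  labels
}

## ---------------------------------------------------------------------------
## Stratified association
## ---------------------------------------------------------------------------

newEffect <- function(outcomeId, mr, nCases = NA_integer_,
                      nControls = NA_integer_, n = NA_integer_,
                      unit = "per-unit-score") {
  new("EffectEstimate", outcomeId = outcomeId, beta = mr@beta, se = mr@se,
      p = mr@p, nCases = as.integer(nCases), nControls = as.integer(nControls),
      n = as.integer(n), unit = unit, orientation = "ldl-raising",
      nStrata = mr@k)
}

#' Region-stratified logistic association
#'
#' Fits a maximum-likelihood logistic regression of the case/control label
#' on the score plus covariates within each stratum (convergence when the
#' deviance change is below 1e-10 or 100 iterations), then pools the
#' per-stratum Wald estimates for the score term with
#' \code{\link{ivwMeta}}. Strata with fewer than \code{minCases} cases or
#' controls, or showing separation (non-convergence or an exploding Wald
#' SE), are dropped with a warning rather than penalised.
#'
#' @param labels Named 1/0/NA vector from \code{\link{buildEndpoint}} (NA
#'   rows are excluded).
#' @param score Genetic score aligned with \code{labels}.
#' @param covariates Optional covariate matrix/data frame.
#' @param strata Optional stratum labels.
#' @param minCases Minimum cases and controls per usable stratum (default 5).
#' @param outcomeId Label carried into the result.
#' @return An \linkS4class{EffectEstimate} in per-unit-score units,
#'   LDL-raising orientation.
#' @export
logisticAssoc <- function(labels, score, covariates = NULL, strata = NULL,
                          minCases = 5L, outcomeId = "outcome") {
  n <- length(labels)
  if (length(score) != n) stop("'score' and 'labels' lengths differ")
  cv <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  if (is.null(strata)) strata <- rep(1L, n)
  ok <- !is.na(labels) & !is.na(score) & !is.na(strata)
  if (!is.null(cv)) ok <- ok & stats::complete.cases(cv)
  betas <- ses <- numeric(0)
  nc <- nco <- 0L
  skipped <- character()
  for (s in unique(strata[ok])) {
    idx <- which(ok & strata == s)
    y <- labels[idx]
    if (sum(y == 1L) < minCases || sum(y == 0L) < minCases) {
      skipped <- c(skipped, sprintf("%s (cases=%d)", s, sum(y == 1L)))
      next
    }
    X <- cbind(score = score[idx],
               if (is.null(cv)) NULL else as.matrix(cv[idx, , drop = FALSE]))
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(cbind(1, X), y,
        family = stats::binomial(),
        control = stats::glm.control(epsilon = 1e-10, maxit = 100L))),
      error = function(e) NULL)
    est <- glmWald(fit, term = 2L)
    if (is.null(est)) {
      skipped <- c(skipped, sprintf("%s (separation/non-convergence)", s))
      next
    }
    betas <- c(betas, est$beta)
    ses <- c(ses, est$se)
    nc <- nc + sum(y == 1L)
    nco <- nco + sum(y == 0L)
  }
  if (length(skipped))
    warning("strata excluded from pooling: ", paste(skipped, collapse = "; "))
  if (!length(betas)) stop("no usable stratum for outcome '", outcomeId, "'")
  newEffect(outcomeId, ivwMeta(betas, ses), nCases = nc, nControls = nco,
            n = nc + nco)
}

## Wald beta/se for one glm.fit coefficient; NULL flags separation or
## non-convergence.
glmWald <- function(fit, term) {
  if (is.null(fit) || !fit$converged) return(NULL)
  cf <- fit$coefficients
  if (anyNA(cf)) return(NULL)
  R <- fit$qr$qr[seq_along(cf), seq_along(cf), drop = FALSE]
  R[lower.tri(R)] <- 0
  cov <- tryCatch(chol2inv(R), error = function(e) NULL)
  if (is.null(cov)) return(NULL)
  se <- sqrt(diag(cov))[term]
  if (!is.finite(se) || se > 20 || abs(cf[term]) > 15) return(NULL)
  list(beta = unname(cf[term]), se = unname(se))
}

#' Region-stratified linear association
#'
#' Least-squares estimate of the score term for a continuous trait within
#' each stratum, pooled with \code{\link{ivwMeta}}. The trait is expected to
#' be in stratum-RINT SD units (see \code{\link{stratifiedTransform}}).
#'
#' @param trait Continuous outcome vector.
#' @inheritParams logisticAssoc
#' @return An \linkS4class{EffectEstimate} (beta in trait SD units per unit
#'   score).
#' @export
linearAssoc <- function(trait, score, covariates = NULL, strata = NULL,
                        outcomeId = "trait") {
  n <- length(trait)
  if (length(score) != n) stop("'score' and 'trait' lengths differ")
  cv <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  if (is.null(strata)) strata <- rep(1L, n)
  ok <- !is.na(trait) & !is.na(score) & !is.na(strata)
  if (!is.null(cv)) ok <- ok & stats::complete.cases(cv)
  betas <- ses <- numeric(0)
  used <- 0L
  for (s in unique(strata[ok])) {
    idx <- which(ok & strata == s)
    X <- cbind(1, score = score[idx],
               if (is.null(cv)) NULL else as.matrix(cv[idx, , drop = FALSE]))
    f <- lsFit(X, trait[idx])
    if (is.null(f)) next
    betas <- c(betas, f$coef[2L])
    ses <- c(ses, f$se[2L])
    used <- used + length(idx)
  }
  if (!length(betas)) stop("no usable stratum for trait '", outcomeId, "'")
  newEffect(outcomeId, ivwMeta(betas, ses), n = used)
}

#' Pool per-stratum estimates
#'
#' Inverse-variance-weighted fixed-effect pooling of a list of
#' \linkS4class{EffectEstimate}s for the same outcome (identity for a
#' single stratum); the number of strata pooled is recorded.
#'
#' @param estimates List of \linkS4class{EffectEstimate} on the same unit.
#' @return A pooled \linkS4class{EffectEstimate}.
#' @export
poolStrata <- function(estimates) {
  if (!length(estimates)) stop("no estimates to pool")
  units <- unique(vapply(estimates, function(e) e@unit, ""))
  if (length(units) != 1L) stop("cannot pool estimates on mixed units")
  mr <- ivwMeta(vapply(estimates, function(e) e@beta, 0),
                vapply(estimates, function(e) e@se, 0))
  nc <- vapply(estimates, function(e) e@nCases, 0L)
  nco <- vapply(estimates, function(e) e@nControls, 0L)
  out <- newEffect(estimates[[1L]]@outcomeId, mr,
                   nCases = if (all(is.na(nc))) NA_integer_ else
                     sum(nc, na.rm = TRUE),
                   nControls = if (all(is.na(nco))) NA_integer_ else
                     sum(nco, na.rm = TRUE),
                   n = sum(vapply(estimates, function(e) e@n, 0L),
                           na.rm = TRUE),
                   unit = units)
  out@orientation <- estimates[[1L]]@orientation
  out
}

#' Reorient an estimate to per 1-SD-lower LDL-C
#'
#' Negates the log-scale effect of a per-unit-score estimate (score unit =
#' one predicted SD of LDL-C, LDL-raising) so that it reads per 1-SD
#' \emph{lower} LDL-C, the scale on which drug-target estimates are
#' reported. SE and p are unchanged. Applying the function twice returns
#' the original estimate.
#'
#' @param est An \linkS4class{EffectEstimate} in per-unit-score or
#'   per-SD-lower-LDL units.
#' @return The reoriented \linkS4class{EffectEstimate}.
#' @export
orientPerSdLowerLdl <- function(est) {
  stopifnot(is(est, "EffectEstimate"))
  if (est@unit == "per-unit-score" && est@orientation == "ldl-raising") {
    est@beta <- -est@beta
    est@unit <- "per-SD-lower-LDL"
    est@orientation <- "ldl-lowering"
  } else if (est@unit == "per-SD-lower-LDL" &&
             est@orientation == "ldl-lowering") {
    est@beta <- -est@beta
    est@unit <- "per-unit-score"
    est@orientation <- "ldl-raising"
  } else stop("cannot reorient an estimate in unit '", est@unit, "'")
  est
}

## ---------------------------------------------------------------------------
## Phenome-wide scan
## ---------------------------------------------------------------------------

#' Disjoint ICD-10 groupings for a phenome-wide scan
#'
#' Partitions the category range A00-N99 into \code{nGroups} contiguous,
#' disjoint code ranges, each an endpoint with no exclusions for prevalent
#' disease. The grouping is illustrative plumbing for the scan machinery;
#' real analyses supply curated groupings.
#'
#' @param nGroups Number of groups (default 41).
#' @return List of \code{\link{endpointDefinition}}s.
#' @export
defaultPhewasGroups <- function(nGroups = 41L) {
  lo <- icdOrd("A00")
  hi <- icdOrd("N99")
  cuts <- floor(seq(lo, hi + 1L, length.out = nGroups + 1L))
  lapply(seq_len(nGroups), function(i) {
    a <- cuts[i]; b <- cuts[i + 1L] - 1L
    codeOf <- function(o) sprintf("%s%02d", LETTERS[o %/% 100L + 1L],
                                  o %% 100L)
    endpointDefinition(sprintf("phewas_%s_%s", codeOf(a), codeOf(b)),
                       caseCodes = sprintf("%s-%s", codeOf(a), codeOf(b)))
  })
}

#' Phenome-wide association scan
#'
#' Runs \code{\link{buildEndpoint}} + \code{\link{logisticAssoc}} (which
#' pools strata) for every endpoint grouping, with no exclusions for
#' prevalent disease, and flags endpoints significant at the Bonferroni
#' threshold \code{alpha / (n_endpoints + nPrior)}. Per-endpoint failures
#' (e.g. no cases) are recorded and the scan continues.
#'
#' @param cohort A \linkS4class{GeneticCohort}.
#' @param endpoints List of \code{\link{endpointDefinition}}s (disjoint
#'   groupings).
#' @param score,covariates,strata Passed to \code{\link{logisticAssoc}}.
#' @param nPrior Number of prior hypotheses added to the multiplicity
#'   correction (default 7).
#' @param alpha Family-wise level (default 0.05).
#' @param minCases Minimum cases/controls per stratum.
#' @return \code{data.frame} of estimates with \code{significant} flags;
#'   attributes \code{"threshold"} and \code{"failures"}.
#' @export
phewasScan <- function(cohort, endpoints, score, covariates = NULL,
                       strata = NULL, nPrior = 7L, alpha = 0.05,
                       minCases = 5L) {
  threshold <- alpha / (length(endpoints) + nPrior)
  rows <- list()
  failures <- character()
  for (defn in endpoints) {
    est <- tryCatch({
      labels <- buildEndpoint(cohort, defn)
      suppressWarnings(
        logisticAssoc(labels, score, covariates, strata,
                      minCases = minCases, outcomeId = defn$outcomeId))
    }, error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", defn$outcomeId,
                                       conditionMessage(e)))
      NULL
    })
    if (!is.null(est)) rows[[defn$outcomeId]] <- effectTable(est)
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
         else stop("every endpoint failed")
  out$significant <- out$p < threshold
  attr(out, "threshold") <- threshold
  attr(out, "failures") <- failures
  out
}
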