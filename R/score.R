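## Least-squares fit returning coefficients and Wald SEs; NULL when the
## normal equations are singular.
lsFit <- function(X, y) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) return(NULL)
  cf <- qr.coef(qrX, y)
  res <- y - X %*% cf
  df <- length(y) - ncol(X)
  if (df < 1L) return(NULL)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  list(coef = as.numeric(cf), se = sqrt(sigma2 * diag(XtXinv)))
}

## Assemble the weight-model design per stratum: intercept | dosages |
## covariates. Returns per-stratum row indices plus the SNP coefficient
## positions.
weightDesign <- function(dosages, rintLdl, covariates, strata) {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages)
  if (length(rintLdl) != n) stop("dosage and phenotype rows do not align")
  if (is.null(colnames(dosages)))
    colnames(dosages) <- sprintf("snp%d", seq_len(ncol(dosages)))
  cv <- if (is.null(covariates)) NULL else as.matrix(as.data.frame(covariates))
  if (!is.null(cv) && nrow(cv) != n) stop("covariate rows do not align")
  if (is.null(strata)) strata <- rep(1L, n)
  ok <- !is.na(rintLdl) & !is.na(strata) & stats::complete.cases(dosages)
  if (!is.null(cv)) ok <- ok & stats::complete.cases(cv)
  mono <- colSums(dosages[ok, , drop = FALSE] > 0) < 2L |
    apply(dosages[ok, , drop = FALSE], 2L, function(x) var(x) == 0)
  if (any(mono))
    stop("monomorphic (or near-monomorphic) SNP in estimation sample: ",
         paste(colnames(dosages)[mono], collapse = ", "))
  if (ncol(dosages) > 1L) {
    cc <- cor(dosages[ok, , drop = FALSE])
    diag(cc) <- 0
    if (any(abs(cc) > 0.999)) {
      idx <- which(abs(cc) > 0.999, arr.ind = TRUE)[1L, ]
      stop("collinear dosages (|r| > 0.999): ",
           paste(colnames(dosages)[idx], collapse = " and "))
    }
  }
  X <- cbind("(Intercept)" = 1, dosages, cv)
  list(X = X, y = rintLdl, strata = strata, ok = ok,
       snpCols = 1L + seq_len(ncol(dosages)), snpIds = colnames(dosages),
       ids = if (!is.null(rownames(dosages))) rownames(dosages)
             else sprintf("row%d", seq_len(n)))
}

## IVW-pool per-stratum SNP coefficients into one beta/se per SNP; a single
## stratum passes through unchanged (noise-free fits then carry se = 0).
poolSnpCoefs <- function(fits, snpIds) {
  p <- length(snpIds)
  if (length(fits) == 1L)
    return(list(betas = setNames(fits[[1L]]$coef, snpIds),
                ses = setNames(fits[[1L]]$se, snpIds)))
  betas <- ses <- numeric(p)
  for (j in seq_len(p)) {
    b <- vapply(fits, function(f) f$coef[j], 0)
    s <- vapply(fits, function(f) f$se[j], 0)
    mr <- ivwMeta(b, s)
    betas[j] <- mr@beta
    ses[j] <- mr@se
  }
  list(betas = setNames(betas, snpIds), ses = setNames(ses, snpIds))
}

#' Fit mutually adjusted per-allele locus weights
#'
#' Jointly regresses rank-normalised LDL-C on all locus SNP dosages plus
#' covariates within each stratum (recruitment region), then pools each
#' SNP's per-stratum coefficients by inverse-variance-weighted fixed-effect
#' meta-analysis — the same pooling operator used for disease associations.
#' Mutual adjustment makes the weights valid under linkage disequilibrium
#' between the SNPs.
#'
#' @param dosages Participant-by-SNP dosage matrix (named columns).
#' @param rintLdl Rank-normalised LDL-C, aligned with rows; \code{NA} rows
#'   are excluded from estimation.
#' @param covariates Optional covariate matrix/data frame.
#' @param strata Optional stratum labels (default: one stratum).
#' @return A \linkS4class{ScoreWeights} with full-sample betas and SEs.
#' @export
fitLocusWeights <- function(dosages, rintLdl, covariates = NULL,
                            strata = NULL) {
  d <- weightDesign(dosages, rintLdl, covariates, strata)
  fits <- list()
  dropped <- character()
  for (s in unique(d$strata[d$ok])) {
    idx <- which(d$ok & d$strata == s)
    f <- lsFit(d$X[idx, , drop = FALSE], d$y[idx])
    if (is.null(f)) dropped <- c(dropped, as.character(s))
    else fits[[as.character(s)]] <-
        list(coef = f$coef[d$snpCols], se = f$se[d$snpCols])
  }
  if (!length(fits)) stop("no stratum yielded a full-rank weight fit")
  if (length(dropped))
    warning("strata dropped from weight estimation (rank deficient): ",
            paste(dropped, collapse = ", "))
  pooled <- poolSnpCoefs(fits, d$snpIds)
  ScoreWeights(snpIds = d$snpIds, betas = pooled$betas, ses = pooled$ses)
}

#' Assign jackknife blocks
#'
#' Random partition of participants into \code{B} blocks whose sizes differ
#' by at most one, for leave-one-block-out internal weights.
#'
#' @param ids Participant identifiers.
#' @param B Number of blocks (default 100, i.e. random 1\% subsets).
#' @param seed Integer seed.
#' @return Named integer vector mapping each id to a block in \code{1..B}.
#' @export
assignJackknifeBlocks <- function(ids, B = 100L, seed = 1L) {
  n <- length(ids)
  if (B > n) stop("cannot form ", B, " blocks from ", n, " participants")
  if (B < 1L) stop("'B' must be positive")
  set.seed(as.integer(seed))
  setNames(sample(rep_len(seq_len(as.integer(B)), n)), ids)
}

#' Block-jackknifed internal weights
#'
#' For each block \code{b}, refits the mutually adjusted weight model on the
#' estimation sample excluding block \code{b}, so that participants are
#' never scored with weights their own phenotype helped estimate. The
#' leave-one-block-out fits are computed exactly by downdating the
#' per-stratum normal equations (\code{X'X - Xb'Xb}), which reproduces a
#' brute-force refit to machine precision at a fraction of the cost.
#' Participants outside the estimation sample keep the full-sample weights
#' (block \code{NA}).
#'
#' @param dosages Participant-by-SNP dosage matrix with row names.
#' @param rintLdl Rank-normalised LDL-C aligned with rows (NA outside the
#'   estimation sample).
#' @param covariates,strata As in \code{\link{fitLocusWeights}}.
#' @param jackknifeMap Named block assignment from
#'   \code{\link{assignJackknifeBlocks}} covering every estimation row.
#' @return A \linkS4class{ScoreWeights} with \code{perBlockBetas} and
#'   \code{blockMap} filled.
#' @export
jackknifeWeights <- function(dosages, rintLdl, covariates = NULL,
                             strata = NULL, jackknifeMap) {
  d <- weightDesign(dosages, rintLdl, covariates, strata)
  estIds <- d$ids[d$ok]
  if (!all(estIds %in% names(jackknifeMap)))
    stop("'jackknifeMap' must cover every estimation-sample participant")
  blocks <- jackknifeMap[estIds]
  B <- max(blocks)
  p <- ncol(d$X)
  strataLevels <- unique(d$strata[d$ok])
  ## per-stratum full and per-block crossproducts
  cross <- list()
  for (s in strataLevels) {
    idx <- which(d$ok & d$strata == s)
    Xs <- d$X[idx, , drop = FALSE]
    ys <- d$y[idx]
    bs <- blocks[match(d$ids[idx], estIds)]
    perBlock <- lapply(seq_len(B), function(b) {
      sel <- which(bs == b)
      if (!length(sel)) return(NULL)
      Xb <- Xs[sel, , drop = FALSE]
      list(G = crossprod(Xb), v = crossprod(Xb, ys[sel]),
           yy = sum(ys[sel]^2), n = length(sel))
    })
    cross[[as.character(s)]] <- list(
      G = crossprod(Xs), v = crossprod(Xs, ys), yy = sum(ys^2),
      n = length(ys), perBlock = perBlock)
  }
  fullFit <- function(cr) {
    beta <- tryCatch(solve(cr$G, cr$v), error = function(e) NULL)
    if (is.null(beta)) return(NULL)
    rss <- max(cr$yy - 2 * sum(beta * cr$v) + sum(beta * (cr$G %*% beta)), 0)
    df <- cr$n - p
    if (df < 1L) return(NULL)
    XtXinv <- tryCatch(solve(cr$G), error = function(e) NULL)
    if (is.null(XtXinv)) return(NULL)
    list(coef = as.numeric(beta)[d$snpCols],
         se = sqrt(rss / df * diag(XtXinv))[d$snpCols])
  }
  perBlockBetas <- matrix(NA_real_, B, length(d$snpIds),
                          dimnames = list(NULL, d$snpIds))
  for (b in seq_len(B)) {
    fits <- list()
    for (s in names(cross)) {
      cr <- cross[[s]]
      pb <- cr$perBlock[[b]]
      sub <- if (is.null(pb)) cr else
        list(G = cr$G - pb$G, v = cr$v - pb$v, yy = cr$yy - pb$yy,
             n = cr$n - pb$n)
      f <- fullFit(sub)
      if (is.null(f))
        stop("leave-one-block-out fit failed for block ", b,
             " in stratum ", s)
      fits[[s]] <- f
    }
    pooled <- poolSnpCoefs(fits, d$snpIds)
    perBlockBetas[b, ] <- pooled$betas
  }
  full <- fitLocusWeights(dosages, rintLdl, covariates, strata)
  ScoreWeights(snpIds = d$snpIds, betas = weightBetas(full),
               ses = weightSes(full),
               blockMap = blocks, perBlockBetas = perBlockBetas)
}

#' @rdname buildScore
#' @export
setMethod("buildScore", "matrix", function(x, weights, ...) {
  if (!all(weights@snpIds %in% colnames(x)))
    stop("dosage matrix lacks SNP(s): ",
         paste(setdiff(weights@snpIds, colnames(x)), collapse = ", "))
  G <- x[, weights@snpIds, drop = FALSE]
  if (anyNA(G)) stop("missing dosage values; no imputation is performed")
  score <- as.numeric(G %*% weights@betas)
  names(score) <- rownames(x)
  if (nrow(weights@perBlockBetas) > 0L && length(weights@blockMap)) {
    bm <- weights@blockMap[match(rownames(x), names(weights@blockMap))]
    has <- which(!is.na(bm))
    if (length(has))
      score[has] <- rowSums(G[has, , drop = FALSE] *
                              weights@perBlockBetas[bm[has], , drop = FALSE])
  }
  score
})

#' @rdname buildScore
#' @export
setMethod("buildScore", "GeneticCohort", function(x, weights, ...) {
  buildScore(t(dosages(x)), weights)
})

#' Instrument strength of a genetic score
#'
#' Partial R-squared of the score for rank-normalised LDL-C given the
#' covariates, and the corresponding 1-degree-of-freedom F-statistic
#' \code{F = r2 / (1 - r2) * (n - 2)}.
#'
#' @param score Genetic score vector.
#' @param rintLdl Rank-normalised LDL-C (rows with NA are dropped).
#' @param covariates Optional covariates to partial out.
#' @return List with \code{rSquared}, \code{fStatistic} (infinite when the
#'   score explains the phenotype exactly) and \code{n}.
#' @examples
#' # the closed form at published instrument strength:
#' r2 <- 0.0115; r2 / (1 - r2) * (17687 - 2)  # about 206
#' @export
instrumentStrength <- function(score, rintLdl, covariates = NULL) {
  cv <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  ok <- !is.na(score) & !is.na(rintLdl)
  if (!is.null(cv)) ok <- ok & stats::complete.cases(cv)
  n <- sum(ok)
  if (n < 10L) stop("need at least 10 complete rows")
  y <- rintLdl[ok]
  cv <- if (is.null(cv)) NULL else cv[ok, , drop = FALSE]
  rss0 <- sum(residualize(y, cv)^2)
  X1 <- if (is.null(cv)) data.frame(score = score[ok])
        else cbind(cv, score = score[ok])
  rss1 <- sum(residualize(y, X1)^2)
  r2 <- max((rss0 - rss1) / rss0, 0)
  f <- if (1 - r2 < 1e-12) Inf else r2 / (1 - r2) * (n - 2)
  structure(list(rSquared = r2, fStatistic = f, n = n),
            class = "InstrumentDiagnostics")
}

#' @export
print.InstrumentDiagnostics <- function(x, ...) {
  cat(sprintf("Instrument strength: R^2 = %.4f, F = %.1f, n = %d\n",
              x$rSquared, x$fStatistic, x$n))
  invisible(x)
}

#' Marginal (single-SNP) internal weights
#'
#' Fits each SNP separately with the same stratified model and IVW pooling
#' as \code{\link{fitLocusWeights}}; used to compare internal effect
#' estimates against external (consortium) weights when filtering a
#' polygenic score. Monomorphic SNPs return \code{NA}.
#'
#' @inheritParams fitLocusWeights
#' @return \code{data.frame(snp, beta, se)}.
#' @export
fitMarginalWeights <- function(dosages, rintLdl, covariates = NULL,
                               strata = NULL) {
  dosages <- as.matrix(dosages)
  out <- data.frame(snp = colnames(dosages), beta = NA_real_, se = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(dosages))) {
    w <- tryCatch(
      suppressWarnings(fitLocusWeights(dosages[, j, drop = FALSE], rintLdl,
                                       covariates, strata)),
      error = function(e) NULL)
    if (!is.null(w)) {
      out$beta[j] <- w@betas
      out$se[j] <- w@ses
    }
  }
  out
}

#' Build a filtered polygenic score from external weights
#'
#' Drops monomorphic SNPs, then keeps a SNP when its internal effect is
#' directionally consistent with the external one \emph{or} shows no
#' significant effect-size heterogeneity (two-sample z-test at Bonferroni
#' level \code{alpha / m}, where \code{m} counts the non-monomorphic
#' candidates). The score is the dosage-weighted sum of the kept external
#' betas.
#'
#' @param dosages Participant-by-SNP dosage matrix (named columns).
#' @param externalBetas,externalSes Named external per-allele estimates.
#' @param internalBetas,internalSes Named internal estimates on the same
#'   effect alleles.
#' @param alpha Heterogeneity test level before Bonferroni division
#'   (default 0.05).
#' @param externalAlleles,internalAlleles Optional effect-allele labels;
#'   when both are given, any mismatch is an error (no strand flipping is
#'   attempted).
#' @return List with \code{kept} (SNP ids), \code{score}, \code{mTested}
#'   and the per-SNP \code{pHet}.
#' @export
buildPolygenicScore <- function(dosages, externalBetas, externalSes,
                                internalBetas, internalSes, alpha = 0.05,
                                externalAlleles = NULL,
                                internalAlleles = NULL) {
  dosages <- as.matrix(dosages)
  snps <- colnames(dosages)
  stopifnot(length(externalBetas) == length(snps),
            length(internalBetas) == length(snps))
  if (!is.null(externalAlleles) && !is.null(internalAlleles)) {
    bad <- externalAlleles != internalAlleles
    if (any(bad))
      stop("effect-allele mismatch (no strand resolution attempted) for: ",
           paste(snps[bad], collapse = ", "))
  }
  poly <- apply(dosages, 2L, function(x) var(x, na.rm = TRUE) > 0)
  m <- sum(poly)
  if (m == 0L) stop("all candidate SNPs are monomorphic")
  zHet <- (internalBetas - externalBetas) /
    sqrt(internalSes^2 + externalSes^2)
  pHet <- 2 * pnorm(-abs(zHet))
  consistent <- internalBetas * externalBetas >= 0
  keep <- poly & (consistent | pHet >= alpha / m)
  keep[is.na(keep)] <- FALSE
  score <- as.numeric(dosages[, keep, drop = FALSE] %*% externalBetas[keep])
  names(score) <- rownames(dosages)
  list(kept = snps[keep], score = score, mTested = m,
       pHet = setNames(pHet, snps))
}
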