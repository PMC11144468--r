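#' Back-calculate a log-scale estimate from a printed OR and CI
#'
#' Converts a published odds (or hazard) ratio with its confidence interval
#' to \code{beta = log(point)} and
#' \code{se = (log(hi) - log(lo)) / (2 * z)}, using the exact normal
#' quantile for the interval level (1.959964 at 95\%, not 1.96). The point
#' estimate may sit slightly off-centre of the interval because published
#' values are rounded; a 2\% relative mis-centring is tolerated.
#'
#' @param point,lo,hi Positive ratio-scale point estimate and CI bounds.
#' @param level Confidence level (default 0.95).
#' @return List with \code{beta} and \code{se}.
#' @examples
#' seFromCi(2.18, 1.34, 3.53)$se  # 0.2471
#' @export
seFromCi <- function(point, lo, hi, level = 0.95) {
  if (any(c(point, lo, hi) <= 0)) stop("ratio and CI bounds must be positive")
  if (lo > hi) stop("'lo' must not exceed 'hi'")
  if (point < lo * 0.98 || point > hi * 1.02)
    stop("point estimate lies outside its confidence interval")
  z <- qnorm((1 + level) / 2)
  se <- (log(hi) - log(lo)) / (2 * z)
  if (se <= 0) stop("degenerate interval: se must be positive")
  list(beta = log(point), se = se)
}

#' Two-sided Wald p-value
#'
#' @param beta,se Estimate and positive standard error (log scale for
#'   ratios).
#' @return \code{2 * pnorm(-abs(beta) / se)}.
#' @examples
#' est <- seFromCi(0.61, 0.45, 0.83)
#' waldP(est$beta, est$se)  # 0.0015
#' @export
waldP <- function(beta, se) {
  if (any(se <= 0)) stop("'se' must be positive")
  2 * pnorm(-abs(beta) / se)
}

#' Scaling constants for trans-ancestry comparison
#'
#' @param ukbPerAlleleSd Per-allele LDL-C effect (SD units) of the external
#'   functional variant used to convert per-allele disease estimates to the
#'   per-1-SD-LDL-C scale (default 0.497, the consortium estimate for
#'   rs11591147).
#' @param sdLdlMgdl One SD of LDL-C in mg/dL (default 27.41).
#' @param ciLevel Confidence level for interval back-calculation.
#' @return A classed list.
#' @export
scalingConstants <- function(ukbPerAlleleSd = 0.497, sdLdlMgdl = 27.41,
                             ciLevel = 0.95) {
  if (ukbPerAlleleSd == 0) stop("'ukbPerAlleleSd' must be non-zero")
  structure(list(ukbPerAlleleSd = ukbPerAlleleSd, sdLdlMgdl = sdLdlMgdl,
                 ciLevel = ciLevel), class = "ScalingConstants")
}

#' Rescale a per-allele estimate to per 1-SD-lower LDL-C
#'
#' Divides a per-allele log-scale estimate and its SE by the per-allele
#' LDL-C effect (in SD units) of the instrument variant, putting it on the
#' same per-1-SD-lower-LDL-C scale as score-based estimates. The sign is
#' kept: the convention is that the counted allele lowers LDL-C, so the
#' input is already oriented per LDL-C-lowering allele.
#'
#' @param beta,se Per-allele log-scale estimate and SE.
#' @param constants A \code{\link{scalingConstants}} list.
#' @return List with rescaled \code{beta}, \code{se} and
#'   \code{scale = "per-SD-ldl"}.
#' @export
rescalePerAllele <- function(beta, se, constants = scalingConstants()) {
  d <- constants$ukbPerAlleleSd
  if (d == 0) stop("zero per-allele scaling divisor")
  list(beta = beta / d, se = se / abs(d), scale = "per-SD-ldl")
}

#' Inverse-variance-weighted fixed-effect meta-analysis
#'
#' Pools estimates with weights \code{1/se^2}; the pooled SE is
#' \code{1/sqrt(sum(w))}. Cochran's Q and its chi-square p-value are filled
#' whenever two or more estimates are pooled. All inputs must share one
#' scale; the function cannot check units, so mixing is the caller's
#' responsibility and \code{labels} are carried for bookkeeping.
#'
#' @param beta,se Numeric vectors of estimates and positive SEs.
#' @param labels Optional labels, recorded in the result's names.
#' @return A \linkS4class{MetaResult}.
#' @examples
#' ckb <- seFromCi(2.18, 1.34, 3.53)
#' ukb <- seFromCi(1.70, 1.15, 2.51)
#' ivwMeta(c(ckb$beta, ukb$beta), c(ckb$se, ukb$se))  # pooled OR 1.87
#' @export
ivwMeta <- function(beta, se, labels = NULL) {
  k <- length(beta)
  if (k < 1L) stop("need at least one estimate")
  if (length(se) != k) stop("'beta' and 'se' lengths differ")
  if (anyNA(beta) || anyNA(se)) stop("missing values in estimates")
  if (any(se <= 0)) stop("all 'se' must be positive")
  w <- 1 / se^2
  bp <- sum(w * beta) / sum(w)
  sp <- 1 / sqrt(sum(w))
  if (k >= 2L) {
    het <- cochranQ(beta, se)
    q <- het$q; df <- het$df; pHet <- het$pHet
  } else {
    q <- NA_real_; df <- 0L; pHet <- NA_real_
  }
  new("MetaResult", beta = bp, se = sp, p = waldP(bp, sp),
      q = q, df = df, pHet = pHet, k = as.integer(k))
}

#' Cochran's Q heterogeneity test
#'
#' \code{Q = sum(w * (beta - pooled)^2)} with \code{w = 1/se^2}, referred to
#' a chi-square distribution on \code{k - 1} degrees of freedom.
#'
#' @param beta,se At least two estimates on a common scale, with positive
#'   SEs.
#' @return List with \code{q}, \code{df} and \code{pHet}.
#' @examples
#' cochranQ(c(0, 2), c(1, 1))  # q = 2, pHet = 0.157
#' @export
cochranQ <- function(beta, se) {
  k <- length(beta)
  if (k < 2L) stop("heterogeneity needs at least two estimates")
  if (length(se) != k) stop("'beta' and 'se' lengths differ")
  if (any(se <= 0)) stop("all 'se' must be positive")
  w <- 1 / se^2
  bp <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - bp)^2)
  list(q = q, df = k - 1L, pHet = pchisq(q, k - 1L, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up rejections
#'
#' Flags the hypotheses rejected by the standard step-up procedure at FDR
#' level \code{qLevel} (computed through \code{p.adjust}).
#'
#' @param pvalues P-values in (0, 1].
#' @param qLevel Target false discovery rate (default 0.05).
#' @return Logical rejection flags aligned with the input.
#' @export
bhFdr <- function(pvalues, qLevel = 0.05) {
  if (any(pvalues <= 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH") <= qLevel
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param m Number of tests.
#' @param digits Decimal places for the reported threshold (default 4,
#'   matching how such thresholds are usually printed); \code{NULL} returns
#'   the exact value.
#' @return \code{alpha / m}, rounded if requested.
#' @examples
#' bonferroniThreshold(0.05, 7)       # 0.0071
#' bonferroniThreshold(0.05, 41 + 7)  # 0.0010
#' @export
bonferroniThreshold <- function(alpha, m, digits = 4L) {
  if (m < 1L) stop("'m' must be at least 1")
  x <- alpha / m
  if (is.null(digits)) x else round(x, digits)
}
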