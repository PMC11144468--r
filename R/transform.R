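#' Ordinary least-squares residualisation
#'
#' Regresses \code{values} on the covariate columns (an intercept is always
#' added) and returns the residuals, which are orthogonal to every covariate
#' column. Rank-deficient designs are refused with the offending columns
#' named rather than silently dropped.
#'
#' @param values Numeric response vector with no missing values.
#' @param covariates Numeric matrix or data frame of covariates (may be
#'   \code{NULL} for intercept-only).
#' @return Residual vector of the same length.
#' @examples
#' residualize(c(1, 2, 4), cbind(x = c(0, 1, 2)))  # (1/6, -1/3, 1/6)
#' @export
residualize <- function(values, covariates = NULL) {
  if (anyNA(values)) stop("'values' contains missing values; filter rows first")
  X <- designMatrix(covariates, length(values))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  as.numeric(qr.resid(qrX, values))
}

designMatrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  X <- as.matrix(as.data.frame(covariates))
  if (!is.numeric(X)) stop("covariates must be numeric")
  if (nrow(X) != n) stop("covariate rows do not match the response length")
  if (anyNA(X)) stop("covariates contain missing values; filter rows first")
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  cbind("(Intercept)" = 1, X)
}

#' Rank inverse-normal transformation
#'
#' Maps the value with (average, for ties) rank \code{i} to
#' \code{qnorm((i - offset) / (n - 2*offset + 1))}. The default offset 3/8
#' is the Blom constant, the standard choice in human-genetics pipelines.
#'
#' @param values Numeric vector, length at least 2, not all identical.
#' @param offset Rank offset in \[0, 0.5\].
#' @return Rank-preserving transformed vector with near-normal margins.
#' @examples
#' rintTransform(c(10, 2, 5))  # (0.869, -0.869, 0)
#' @export
rintTransform <- function(values, offset = 3 / 8) {
  if (anyNA(values)) stop("'values' contains missing values; filter rows first")
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  if (offset < 0 || offset > 0.5) stop("'offset' must lie in [0, 0.5]")
  if (diff(range(values)) == 0)
    stop("all values identical; rank transform undefined")
  r <- rank(values, ties.method = "average")
  qnorm((r - offset) / (n - 2 * offset + 1))
}

#' Stratum-specific residualise-then-RINT
#'
#' Within each stratum, residualises the phenotype on the covariates and
#' rank-inverse-normal transforms the residuals, so every stratum
#' contributes a standard-normal-margin phenotype. Rows with missing
#' phenotype or covariates are listwise deleted; strata smaller than
#' \code{minStratumSize} after deletion are dropped with a warning. Dropped
#' and missing rows return \code{NA}.
#'
#' @param values Numeric phenotype vector.
#' @param covariates Covariate matrix/data frame (rows aligned), or
#'   \code{NULL}.
#' @param strata Stratum labels (e.g. recruitment region), or \code{NULL}
#'   for a single stratum.
#' @param minStratumSize Minimum usable stratum size (default 30).
#' @param offset RINT rank offset (default 3/8).
#' @return Transformed vector aligned with the input; attribute
#'   \code{"nUsed"} records the number of transformed rows.
#' @export
stratifiedTransform <- function(values, covariates = NULL, strata = NULL,
                                minStratumSize = 30L, offset = 3 / 8) {
  n <- length(values)
  if (n == 0L) stop("empty input")
  if (is.null(strata)) strata <- rep(1L, n)
  if (length(strata) != n) stop("'strata' length must match 'values'")
  cv <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  ok <- !is.na(values) & !is.na(strata)
  if (!is.null(cv)) ok <- ok & complete.cases(cv)
  out <- rep(NA_real_, n)
  dropped <- character()
  for (s in unique(strata[ok])) {
    idx <- which(ok & strata == s)
    if (length(idx) < minStratumSize) {
      dropped <- c(dropped, sprintf("%s (n=%d)", s, length(idx)))
      next
    }
    res <- residualize(values[idx],
                       if (is.null(cv)) NULL else cv[idx, , drop = FALSE])
    out[idx] <- rintTransform(res, offset = offset)
  }
  if (length(dropped))
    warning("dropped strata below minimum size ", minStratumSize, ": ",
            paste(dropped, collapse = "; "))
  if (all(is.na(out))) stop("no stratum met the minimum size")
  attr(out, "nUsed") <- sum(!is.na(out))
  out
}

#' Phenotype-transform specification
#'
#' Bundles the covariate list, stratification column and RINT offset used by
#' \code{\link{runPipeline}}; expressible in the YAML pipeline config.
#'
#' @param covariates Character vector of covariate column names; the names
#'   \code{"age2"} and \code{"fasting_time2"} denote the squares of
#'   \code{age} and \code{fasting_time}.
#' @param strata Stratum column name, or \code{"none"}.
#' @param rintOffset Rank offset in \[0, 0.5\].
#' @param minStratumSize Minimum usable stratum size.
#' @return A classed list.
#' @export
transformSpec <- function(covariates = c("age", "age2", "sex",
                                         "fasting_time", "fasting_time2"),
                          strata = "region", rintOffset = 3 / 8,
                          minStratumSize = 30L) {
  if (rintOffset < 0 || rintOffset > 0.5)
    stop("'rintOffset' must lie in [0, 0.5]")
  structure(list(covariates = covariates, strata = strata,
                 rintOffset = rintOffset,
                 minStratumSize = as.integer(minStratumSize)),
            class = "TransformSpec")
}

#' Materialise covariate columns from participant data
#'
#' Expands a covariate-name specification against a participant table,
#' materialising derived squared terms: a name ending in \code{2} whose stem
#' is a column (e.g. \code{"age2"}, \code{"fasting_time2"}) becomes the
#' square of that column.
#'
#' @param pd Participant \code{data.frame} (see
#'   \code{\link{participantData}}).
#' @param covariates Character vector of column names / derived terms.
#' @return Numeric \code{data.frame} with one column per requested term.
#' @export
covariateColumns <- function(pd, covariates) {
  out <- list()
  for (nm in covariates) {
    if (nm %in% names(pd)) out[[nm]] <- pd[[nm]]
    else if (grepl("2$", nm) && sub("2$", "", nm) %in% names(pd))
      out[[nm]] <- pd[[sub("2$", "", nm)]]^2
    else stop("unknown covariate column: ", nm)
  }
  as.data.frame(out, optional = TRUE)
}
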