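#' Construct an LMS reference
#'
#' @param male,female Lists with \code{l}, \code{s} (polynomial coefficients
#'   in age, increasing order) and \code{m} (length-3:
#'   \code{m[1] + m[2]*age + m[3]*height_cm}).
#' @param centile Lower-limit-of-normal quantile (default 0.05).
#' @param ageRange Supported age range in years.
#' @return A validated \linkS4class{LmsReference}.
#' @export
lmsReference <- function(male, female, centile = 0.05,
                         ageRange = c(30, 79)) {
  new("LmsReference", male = male, female = female, centile = centile,
      ageRange = ageRange)
}

#' Synthetic default LMS reference for FEV1/FVC
#'
#' A self-consistent reference matched to the cohort generator: skewness
#' L = 1 (so ratio z-scores are exactly Gaussian), median ratio declining
#' linearly with age from about 0.90 at age 30, scatter S = 0.08, no height
#' dependence, a small sex difference. It is a synthetic stand-in carried so
#' the lower-limit-of-normal machinery runs without external lookup tables;
#' analyses of real spirometry must load published coefficients via
#' \code{\link{lmsReference}} or \code{\link{readLmsReference}}.
#'
#' @return An \linkS4class{LmsReference}.
#' @export
defaultLmsReference <- function() {
  lmsReference(
    male = list(l = 1, m = c(0.945, -0.0015, 0), s = 0.08),
    female = list(l = 1, m = c(0.955, -0.0015, 0), s = 0.08))
}

polyval <- function(coefs, x) {
  out <- 0
  for (k in rev(seq_along(coefs))) out <- out * x + coefs[k]
  out
}

lmsCoefs <- function(ref, age, sex, height) {
  cf <- list(l = numeric(length(age)), m = numeric(length(age)),
             s = numeric(length(age)))
  for (sx in c(0L, 1L)) {   # 0 male, 1 female
    idx <- which(sex == sx)
    if (!length(idx)) next
    tab <- if (sx == 1L) ref@female else ref@male
    cf$l[idx] <- polyval(tab$l, age[idx])
    m <- rep(tab$m, length.out = 3L)
    cf$m[idx] <- m[1L] + m[2L] * age[idx] + m[3L] * height[idx]
    cf$s[idx] <- polyval(tab$s, age[idx])
  }
  cf
}

#' LMS z-score of an FEV1/FVC ratio
#'
#' \code{z = ((ratio/M)^L - 1) / (L * S)}, with the L-to-zero limit
#' \code{log(ratio/M) / S}; L, M, S are evaluated from the reference's
#' per-sex coefficient tables at the participant's age and height.
#'
#' @param ratio FEV1/FVC in (0, 1.5].
#' @param age Age in years; must lie within the reference's range unless
#'   \code{extrapolate = TRUE}.
#' @param sex 0 = male, 1 = female.
#' @param height Height in cm.
#' @param ref An \linkS4class{LmsReference}.
#' @param extrapolate Allow ages outside the reference range.
#' @return Numeric z-score vector.
#' @examples
#' ref <- lmsReference(male = list(l = 1, m = c(0.8, 0, 0), s = 0.08),
#'                     female = list(l = 1, m = c(0.8, 0, 0), s = 0.08))
#' lmsZscore(0.672, 50, 0, 165, ref)  # -2
#' @export
lmsZscore <- function(ratio, age, sex, height, ref, extrapolate = FALSE) {
  stopifnot(is(ref, "LmsReference"))
  if (any(ratio <= 0 | ratio > 1.5, na.rm = TRUE))
    stop("'ratio' must lie in (0, 1.5]")
  if (!extrapolate &&
      any(age < ref@ageRange[1L] | age > ref@ageRange[2L], na.rm = TRUE))
    stop("age outside reference range [", ref@ageRange[1L], ", ",
         ref@ageRange[2L], "]; set extrapolate = TRUE to override")
  cf <- lmsCoefs(ref, age, sex, height)
  ifelse(abs(cf$l) < 1e-7,
         log(ratio / cf$m) / cf$s,
         ((ratio / cf$m)^cf$l - 1) / (cf$l * cf$s))
}

## Inverse transform used by the spirometry generator: ratio at z.
lmsRatioFromZ <- function(z, age, sex, height, ref) {
  cf <- lmsCoefs(ref, age, sex, height)
  ifelse(abs(cf$l) < 1e-7,
         cf$m * exp(cf$s * z),
         cf$m * (1 + cf$l * cf$s * z)^(1 / cf$l))
}

#' Prevalent airflow obstruction at the lower limit of normal
#'
#' Flags ratios strictly below the reference centile (default the 5th,
#' z < -1.6449); a z exactly at the limit is not flagged.
#'
#' @param z LMS z-scores from \code{\link{lmsZscore}}.
#' @param centile Lower-limit-of-normal quantile (default 0.05).
#' @return Logical vector (NA where z is NA).
#' @export
prevalentCopd <- function(z, centile = 0.05) {
  z < qnorm(centile)
}

#' Classify COPD events against baseline spirometry
#'
#' Partitions the spirometry-usable cohort into: \code{none},
#' \code{prevalent-only} (airflow obstruction at baseline, no follow-up
#' event), \code{incident-fatal}/\code{incident-nonfatal} (no baseline
#' obstruction), and \code{exacerbation-fatal}/\code{exacerbation-nonfatal}
#' (follow-up event on top of baseline obstruction). A participant is
#' "fatal" when any qualifying event carries a fatal flag, regardless of
#' event order. Participants in spirometry-unusable regions are excluded
#' from the table.
#'
#' @param cohort A \linkS4class{GeneticCohort} with \code{spiro_usable} in
#'   its participant data.
#' @param prevalent Named (or cohort-aligned) logical flags from
#'   \code{\link{prevalentCopd}}.
#' @param copdCodes ICD-10 codes/ranges identifying COPD events (default
#'   \code{"J41-J44"}).
#' @param baselineYear Calendar year of baseline; any matching event before
#'   it is an error (events must be follow-up).
#' @return \code{data.frame(id, category, first_event_year)}.
#' @export
classifyCopdEvents <- function(cohort, prevalent, copdCodes = "J41-J44",
                               baselineYear = NULL) {
  stopifnot(is(cohort, "GeneticCohort"))
  pd <- participantData(cohort)
  if (!"spiro_usable" %in% names(pd))
    stop("cohort lacks a 'spiro_usable' column")
  if (is.null(baselineYear)) {
    cfg <- metadata(cohort)$config
    baselineYear <- if (!is.null(cfg)) cfg@baselineYear else -Inf
  }
  ev <- eventData(cohort)
  ev <- ev[icdMatches(ev$code, copdCodes), , drop = FALSE]
  if (nrow(ev) && any(ev$year < baselineYear))
    stop("COPD event before baseline year ", baselineYear,
         "; events must be follow-up")
  keep <- pd$spiro_usable
  ids <- pd$id[keep]
  prev <- if (!is.null(names(prevalent))) prevalent[ids]
          else prevalent[keep]
  prev[is.na(prev)] <- FALSE
  firstYear <- vapply(ids, function(i) {
    yrs <- ev$year[ev$id == i]
    if (length(yrs)) min(yrs) else NA_real_
  }, 0)
  anyFatal <- vapply(ids, function(i) any(ev$fatal[ev$id == i]), TRUE)
  hasEvent <- !is.na(firstYear)
  category <- rep("none", length(ids))
  category[prev & !hasEvent] <- "prevalent-only"
  category[!prev & hasEvent & anyFatal] <- "incident-fatal"
  category[!prev & hasEvent & !anyFatal] <- "incident-nonfatal"
  category[prev & hasEvent & anyFatal] <- "exacerbation-fatal"
  category[prev & hasEvent & !anyFatal] <- "exacerbation-nonfatal"
  data.frame(id = ids, category = category, first_event_year = firstYear,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter upper-respiratory-tract-infection cases by calendar year
#'
#' Keeps case events at or after \code{minYear} (default 2009, discarding a
#' reporting-spike era) and applies optional (region, year-range)
#' exclusions. When a region map is supplied, a spike report is attached:
#' any region holding more than \code{spikeThreshold} of all cases within
#' the pre-\code{minYear} window is flagged.
#'
#' @param events Event \code{data.frame(id, code, year, fatal)} already
#'   restricted to the endpoint's codes.
#' @param minYear Minimum calendar year kept (use \code{-Inf} for no
#'   filter).
#' @param regionMap Optional named vector id -> region for spike detection
#'   and region exclusions.
#' @param regionExclusions Optional \code{data.frame(region, year_start,
#'   year_end)} of additional exclusions.
#' @param spikeThreshold Fraction of all cases concentrated in one region's
#'   pre-\code{minYear} window that triggers a flag (default 0.10).
#' @return Filtered events; attribute \code{"spikeReport"} when a region
#'   map was supplied.
#' @export
urtiFilter <- function(events, minYear = 2009, regionMap = NULL,
                       regionExclusions = NULL, spikeThreshold = 0.10) {
  report <- NULL
  if (!is.null(regionMap) && nrow(events)) {
    reg <- regionMap[events$id]
    pre <- events$year < minYear
    tot <- nrow(events)
    tab <- tapply(pre, reg, sum)
    report <- data.frame(region = names(tab),
                         pre_window_cases = as.integer(tab),
                         fraction_of_all_cases = as.numeric(tab) / tot,
                         flagged = as.numeric(tab) / tot > spikeThreshold,
                         row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- events[events$year >= minYear, , drop = FALSE]
  if (!is.null(regionExclusions) && !is.null(regionMap) && nrow(out)) {
    reg <- regionMap[out$id]
    drop <- rep(FALSE, nrow(out))
    for (i in seq_len(nrow(regionExclusions)))
      drop <- drop | (reg == regionExclusions$region[i] &
                      out$year >= regionExclusions$year_start[i] &
                      out$year <= regionExclusions$year_end[i])
    out <- out[!drop, , drop = FALSE]
  }
  attr(out, "spikeReport") <- report
  out
}
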