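#' Read a dosage matrix
#'
#' TSV layout: first column participant id, remaining columns one SNP each
#' (header = SNP ids). VCF files are read through the \pkg{vcfR} package and
#' must carry a per-sample \code{DS} FORMAT field. Dosages outside \[0, 2\]
#' are refused with the offending row and column named.
#'
#' @param path File path.
#' @param format \code{"tsv"} or \code{"vcf"}.
#' @return Participant-by-SNP numeric matrix; attribute \code{"manifest"}
#'   is a data frame of SNP ids and (for VCF) REF/ALT alleles, with the ALT
#'   allele counted.
#' @export
readDosages <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("dosage TSV needs an id column plus SNPs")
    ids <- as.character(tab[[1L]])
    m <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    manifest <- data.frame(snp_id = colnames(m), effect_allele = NA_character_,
                           stringsAsFactors = FALSE)
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF dosages requires the 'vcfR' package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fmt <- unique(v@gt[, "FORMAT"])
    if (!all(vapply(strsplit(fmt, ":"), function(f) "DS" %in% f, TRUE)))
      stop("VCF lacks a DS FORMAT field")
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    rownames(ds) <- vcfR::getID(v)
    m <- t(ds)
    manifest <- data.frame(snp_id = colnames(m),
                           effect_allele = vcfR::getALT(v),
                           ref_allele = vcfR::getREF(v),
                           stringsAsFactors = FALSE)
  }
  bad <- which(is.na(m) | m < 0 | m > 2, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid dosage at participant '%s', SNP '%s'",
                 rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  attr(m, "manifest") <- manifest
  m
}

#' Write cohort tables to a directory
#'
#' Canonical TSV interchange: \code{phenotypes.tsv} (participant data),
#' \code{dosages.tsv} (id column + one column per SNP), \code{events.tsv}
#' (id, code, year, fatal) and \code{config.yaml} (generator parameters,
#' when the cohort was simulated).
#'
#' @param cohort A \linkS4class{GeneticCohort}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeCohortTables <- function(cohort, dir) {
  stopifnot(is(cohort, "GeneticCohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(phenotypes = file.path(dir, "phenotypes.tsv"),
             dosages = file.path(dir, "dosages.tsv"),
             events = file.path(dir, "events.tsv"))
  utils::write.table(participantData(cohort), paths["phenotypes"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  d <- t(dosages(cohort))
  utils::write.table(cbind(data.frame(id = rownames(d)), as.data.frame(d)),
                     paths["dosages"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(eventData(cohort), paths["events"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- metadata(cohort)$config
  if (!is.null(cfg)) {
    paths <- c(paths, config = file.path(dir, "config.yaml"))
    yaml::write_yaml(configToList(cfg), paths["config"])
  }
  invisible(paths)
}

configToList <- function(cfg) {
  list(n_participants = cfg@nParticipants, n_regions = cfg@nRegions,
       locus_maf = cfg@locusMaf,
       locus_ld = if (is.character(cfg@locusLd)) cfg@locusLd
                  else as.list(cfg@locusLd),
       locus_betas = cfg@locusBetas, grs_n_snps = cfg@grsNSnps,
       grs_mafs = cfg@grsMafs, grs_betas = cfg@grsBetas,
       covariate_effects = as.list(cfg@covariateEffects),
       ldl_mean_mmol = cfg@ldlMeanMmol, ldl_sd_mmol = cfg@ldlSdMmol,
       ldl_measured_fraction = cfg@ldlMeasuredFraction,
       followup_years = cfg@followupYears, baseline_year = cfg@baselineYear,
       spiro_unusable_regions = cfg@spiroUnusableRegions,
       n_pcs = cfg@nPcs, seed = cfg@seed)
}

#' Read summary estimates from TSV
#'
#' Expected columns: \code{label}, \code{source}, \code{or}, \code{ci_low},
#' \code{ci_high} and optionally \code{scale} (\code{"per-allele"} or
#' \code{"per-SD-ldl"}); log-scale \code{beta}/\code{se} are derived with
#' \code{\link{seFromCi}}.
#'
#' @param path TSV path.
#' @param level Confidence level of the printed intervals.
#' @return Data frame with added \code{beta} and \code{se} columns.
#' @export
readSummaryEstimates <- function(path, level = 0.95) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "or", "ci_low", "ci_high")
  if (!all(need %in% names(tab)))
    stop("summary TSV needs columns: ", paste(need, collapse = ", "))
  bs <- mapply(function(o, l, h) unlist(seFromCi(o, l, h, level)),
               tab$or, tab$ci_low, tab$ci_high)
  tab$beta <- bs["beta", ]
  tab$se <- bs["se", ]
  tab
}

#' Read an LMS reference from YAML
#'
#' Layout: top-level keys \code{male}/\code{female} each with \code{l},
#' \code{m}, \code{s} coefficient vectors, plus optional \code{centile} and
#' \code{age_range}; an optional \code{ancestry} key is carried as an
#' attribute (which ancestry group to apply is the caller's choice).
#'
#' @param path YAML path.
#' @return An \linkS4class{LmsReference}.
#' @export
readLmsReference <- function(path) {
  y <- yaml::read_yaml(path)
  ref <- lmsReference(
    male = lapply(y$male, as.numeric),
    female = lapply(y$female, as.numeric),
    centile = if (is.null(y$centile)) 0.05 else y$centile,
    ageRange = if (is.null(y$age_range)) c(30, 79) else as.numeric(y$age_range))
  attr(ref, "ancestry") <- y$ancestry
  ref
}

#' Read endpoint definitions from YAML
#'
#' Each top-level entry is one endpoint; fields mirror the arguments of
#' \code{\link{endpointDefinition}} in snake_case, with code ranges as
#' strings like \code{"J40-J44"}.
#'
#' @param path YAML path.
#' @return List of \code{\link{endpointDefinition}}s.
#' @export
readEndpointDefinitions <- function(path) {
  y <- yaml::read_yaml(path)
  lapply(names(y), function(nm) {
    e <- y[[nm]]
    endpointDefinition(
      outcomeId = nm,
      caseCodes = as.character(e$case_codes),
      controlExclusionCodes = as.character(e$control_exclusion_codes %||%
                                             character()),
      baselineSelfReportExclusions =
        as.character(e$baseline_self_report_exclusions %||% character()),
      controlSet = e$control_set %||% "disease-specific",
      ascertainmentExclusions = as.character(e$ascertainment_exclusions %||%
                                               character()),
      restrictToPopulationSubset =
        isTRUE(e$restrict_to_population_subset),
      minYear = e$min_year)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
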