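# Shared fixtures and independent oracles, all built in code.

# Tiny cohort with hand-specified events and flags, for endpoint logic.
makeToyCohort <- function(n = 10L,
                          events = data.frame(id = character(),
                                              code = character(),
                                              year = numeric(),
                                              fatal = logical()),
                          selfChd = rep(FALSE, n),
                          region = rep(1L, n),
                          ascertainment = rep("population", n),
                          spiroUsable = rep(TRUE, n),
                          fev1 = NULL, fvc = NULL) {
  ids <- sprintf("t%03d", seq_len(n))
  d <- matrix(rep(c(0, 1, 2), length.out = 3L * n), nrow = 3L,
              dimnames = list(c("s1", "s2", "s3"), ids))
  cd <- S4Vectors::DataFrame(
    id = ids, region = region, age = seq(40, 60, length.out = n),
    sex = rep_len(c(0L, 1L), n), fasting_time = rep(4, n),
    height = rep(160, n),
    self_chd = selfChd, self_stroke_tia = rep(FALSE, n),
    self_diabetes = rep(FALSE, n), self_asthma = rep(FALSE, n),
    self_copd = rep(FALSE, n),
    ascertainment_category = ascertainment,
    spiro_usable = spiroUsable, row.names = ids)
  if (!is.null(fev1)) { cd$fev1 <- fev1; cd$fvc <- fvc }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = d),
    rowData = S4Vectors::DataFrame(snp_id = rownames(d),
                                   effect_allele = "A",
                                   maf = c(0.1, 0.2, 0.3),
                                   class = "locus", true_beta = 0),
    colData = cd)
  obj <- new("GeneticCohort", se)
  S4Vectors::metadata(obj) <- list(events = events)
  obj
}

# Brute-force Benjamini-Hochberg step-up oracle, straight from the
# definition: reject all i <= max{ i : p_(i) <= i q / m }.
bhOracle <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  reject <- rep(FALSE, m)
  if (length(k)) reject[o[seq_len(max(k))]] <- TRUE
  reject
}

# Brute-force leave-one-block-out weights: explicit refit per block.
jackknifeOracle <- function(dosages, y, covariates, blocks) {
  B <- max(blocks)
  t(vapply(seq_len(B), function(b) {
    keep <- blocks != b
    X <- cbind(1, dosages[keep, , drop = FALSE],
               if (is.null(covariates)) NULL
               else as.matrix(covariates)[keep, , drop = FALSE])
    qr.coef(qr(X), y[keep])[1L + seq_len(ncol(dosages))]
  }, numeric(ncol(dosages))))
}
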