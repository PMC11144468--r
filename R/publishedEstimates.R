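#' Published summary estimates for the worked examples
#'
#' Odds ratios with 95\% confidence intervals, as printed by the source
#' biobank analyses of LDL-C-lowering variants at the PCSK9 locus (a
#' Chinese biobank score and a UK biobank functional-variant study), all
#' scaled to 1-SD lower LDL-C. These are the inputs to the summary-level
#' worked examples: trans-ancestry pooling, heterogeneity between the locus
#' score and a genome-wide LDL-C score, and Wald p-value back-calculation.
#'
#' @return Data frame with columns \code{label}, \code{cohort},
#'   \code{instrument}, \code{or}, \code{ci_low}, \code{ci_high},
#'   \code{n_cases}, plus derived \code{beta}/\code{se}.
#' @examples
#' est <- publishedEstimates()
#' urti <- est[est$label == "urti" & est$instrument == "pcsk9_score", ]
#' ivwMeta(urti$beta, urti$se)  # pooled trans-ancestry OR
#' @export
publishedEstimates <- function() {
  path <- system.file("extdata", "published_estimates.tsv",
                      package = "scoreMR", mustWork = TRUE)
  readSummaryEstimates(path)
}
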