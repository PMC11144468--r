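---
title: "Drug-target genetic scores: weighting, jackknife calibration and meta-analysis"
author: "scoreMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target genetic scores: weighting, jackknife calibration and meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scoreMR)
```

## The problem

Variants in and around a drug-target gene that alter the drug's biomarker
(here: *PCSK9* variants that lower LDL cholesterol) can proxy lifelong
pharmacological modulation of the target. Scanning such a *gene score*
across many disease endpoints — and contrasting it with a genome-wide
biomarker score — separates effects mediated by the biomarker from effects
specific to the target. scoreMR implements the full analysis chain for a
region-stratified biobank design:

1. stratum-specific residualisation and rank inverse-normal transformation
   (RINT) of the biomarker;
2. mutually adjusted per-allele weights for the locus SNPs, with 100-fold
   block-jackknifed *internal* weights;
3. a dosage-weighted score calibrated to predicted SD units of LDL-C;
4. an externally weighted polygenic LDL-C score with a directional/
   heterogeneity SNP filter;
5. region-stratified logistic or linear association, pooled by
   inverse-variance-weighted fixed-effect (IVW-FE) meta-analysis and
   reoriented to "per 1-SD lower LDL-C";
6. summary-statistic operators: CI back-calculation, Wald tests, per-allele
   rescaling, IVW-FE pooling across biobanks, Cochran's Q, FDR and
   Bonferroni control;
7. spirometry-based classification of prevalent COPD at the LMS lower
   limit of normal, and typing of follow-up COPD events.

A synthetic-cohort generator (`simulateCohort()`) emulates the statistical
structure this design assumes, so every stage is testable without any
access-controlled data.

## The weight model

Within each recruitment region $s$, RINT LDL-C is regressed jointly on the
three locus dosages and covariates (age, age$^2$, sex, fasting time,
fasting time$^2$, genetic principal components):

$$\tilde y_i \;=\; \alpha_s + \sum_{j=1}^{3}\beta_{js}\,g_{ij} +
  \gamma_s^\top x_i + \varepsilon_i .$$

Mutual adjustment makes the weights valid under linkage disequilibrium
between the SNPs. Per-SNP coefficients are pooled across regions with the
same IVW-FE operator used everywhere else in the package
($w_s = 1/\mathrm{se}_s^2$); the stratified design with IVW pooling was
chosen over a single model with region main effects because it matches the
association engine (the two agree asymptotically; the test suite checks
agreement within 0.1 SE at $n = 20{,}000$).

The score is $S_i = \sum_j \hat\beta_j\, g_{ij}$, so a one-unit difference
in $S$ predicts one SD of RINT LDL-C; estimates are reported per 1-SD
*lower* LDL-C by a sign flip (`orientPerSdLowerLdl()`), with orientation an
explicit field rather than something inferred from signs.

## Why jackknifed internal weights

When weights are estimated in the same sample that is scored, each
participant's phenotype error leaks into their own weights. The effect is
easiest to see under an all-null locus: the regression of LDL-C on the
naively weighted score has slope *identically 1* — the score appears
perfectly calibrated when it is pure noise — and its F-statistic behaves
like a $\chi^2_p$ ($p$ = number of SNPs) rather than a null $F_{1,n}$.

`jackknifeWeights()` removes this by 100-fold block jackknifing: each
weight-estimation participant is scored with weights fit on the sample
*excluding their own block* (participants outside the estimation sample
keep the full-sample weights). The leave-one-block-out fits are computed by
exact downdating of the per-region normal equations
($X^\top X - X_b^\top X_b$); a test verifies agreement with brute-force
refits to $10^{-10}$.

A methodological note on diagnostics: cross-fitting makes
$\mathrm{cov}(S_i, \tilde y_i)$ unbiased at zero under the null — the
spurious slope-1 calibration disappears, and downstream score–disease
z-scores are standard normal (both tested). The *in-sample* score–exposure
F-statistic of the cross-fit score, however, is **not** $F_{1,n}$ under an
exact null: its numerator is the off-block-diagonal part of a quadratic
form in the same estimation data, and its null mean is approximately $2p$
with a heavy right tail. We verified this with an independent from-scratch
simulation (Gaussian instruments, explicit leave-block-out OLS): mean null
F $\approx 6.7 \approx 2p$ at $p = 3$. Mean-F should therefore not be used
as a null-calibration diagnostic for cross-fit scores; the package's
calibration claims rest on the slope and on downstream z-scores instead.

## Summary-statistic layer

`seFromCi()` back-computes $\beta = \log \mathrm{OR}$ and
$\mathrm{se} = (\log hi - \log lo) / (2 z_{0.975})$ with the exact normal
quantile 1.959964; published point estimates may sit slightly off-centre of
their printed intervals, so a 2% mis-centring is tolerated. `ivwMeta()` and
`cochranQ()` implement fixed-effect pooling and heterogeneity exactly as
defined ($Q = \sum w_i (\beta_i - \bar\beta)^2$, $\chi^2_{k-1}$); `ivwMeta`
is cross-checked against an established meta-analysis package in the test
suite. Per-allele estimates from an external functional-variant study are
rescaled to per-1-SD-LDL-C by dividing by the variant's per-allele
biomarker effect (0.497 SD by default). Benjamini–Hochberg control uses the
standard step-up procedure (tested against an exhaustive oracle over all
small/large patterns of a 4-vector); Bonferroni thresholds are reported at
4 decimals, matching how such thresholds are printed (0.05/7 = 0.0071,
0.05/48 = 0.0010).

## Endpoints and the respiratory module

`endpointDefinition()` encodes case codes/ranges in ICD-10 category
arithmetic ("J40-J44"), control exclusions by baseline self-report and by
follow-up events (e.g. a common-vascular control set that drops anyone with
a major vascular event during follow-up), ascertainment-category exclusions
(participants genotyped for a *different* disease panel are removed from
both groups), an optional restriction to the population-representative
subset, and a minimum calendar year for endpoints with reporting artefacts
(the URTI filter defaults to 2009, and `urtiFilter()` reports any region
holding >10% of all cases in the pre-window). Counts always reconcile:
cases + controls + excluded = cohort size.

Prevalent COPD is defined as FEV$_1$/FVC below the LMS lower limit of
normal, $z = ((R/M)^L - 1)/(LS)$ with the $L \to 0$ limit $\log(R/M)/S$ and
a strict inequality at the 5th-centile threshold $\Phi^{-1}(0.05)$.
Published spirometry reference tables are external artifacts, so
`LmsReference` is a pluggable per-sex polynomial coefficient table (YAML
loadable, with an ancestry key left to the caller); the package ships a
synthetic default matched to its own generator ($L = 1$, median ratio
declining linearly with age, $S = 0.08$), which makes the generator and
classifier self-consistent: a null-liability cohort shows 5% prevalence by
construction. Follow-up COPD events in participants with baseline
obstruction are exacerbations; "fatal" means any qualifying event carries a
fatal flag, regardless of event order, because cases — not event sequences
— are dichotomised.

## The synthetic cohort: what it emulates, and what it does not

Defaults emulate a 10-region biobank genotyping substudy of an East Asian
population: LDL-C 2.36 (SD 0.69) mmol/L assayed in a random 25% subset;
age 52.1 (SD 10.7), 59.7% female; a 3-SNP locus whose lead loss-of-function
variant has frequency 0.013 and effect 0.65 SD per allele, with secondary
effects of 0.10 and 0.16 SD; 64 independent polygenic SNPs; binary
endpoints generated from a logistic model with an LDL-mediated path and a
direct (pleiotropic) locus path, the latter existing precisely so that
locus-vs-polygenic heterogeneity has simulated power; multi-year event
histories with fatal flags; and two regions flagged spirometry-unusable.

Parameter choices worth recording:

* **Secondary locus frequencies.** These are not published for the emulated
  design. The defaults 0.35 and 0.032 are back-derived from the printed
  standard errors of the per-allele effects via
  $\mathrm{se} \approx 1/\sqrt{2p(1-p)\,n}$ at $n = 17{,}687$ — the same
  arithmetic that reproduces the lead variant's frequency 0.013 from its
  SE of 0.05. Under independent haplotypes these frequencies put the
  analytic locus variance at
  $\sum_j 2p_j(1-p_j)\beta_j^2 = 1.70\%$ of LDL-C; the published 1.2%
  reflects LD between the real SNPs that an independence default does not
  carry. (An earlier candidate default calibrated to 1.2% exactly required
  a frequency so low that the variant could not have been fine-mapped at
  genome-wide significance in the first place, and was rejected.)
* **LD.** Specified at the haplotype level (8 frequencies) rather than by
  pairwise $r^2$, because the weights are mutually adjusted and haplotype
  sampling is exact and simple. The default is independence.
* **Missingness.** LDL-C is missing completely at random outside the
  measured subset: the real measurement subset was assay-driven, not
  outcome-driven.
* **Event times.** Uniform over follow-up: the analysis is cumulative
  logistic, so time structure only feeds the calendar filter and
  fatal/non-fatal splits.
* **Randomness.** Every generator substream derives deterministically from
  one config seed, so identical configs give byte-identical cohorts and
  result files.

What passing tests on this cohort do *not* show: robustness to genotyping
error, fine-scale ancestry structure beyond region intercepts, assay batch
effects, outcome-dependent measurement, or real LD at the locus. Results on
real data depend on those, and on the curated ICD-10 endpoint lists that
live outside this package.

## Numerical choices and degenerate inputs

* RINT offset 3/8 (Blom), ties averaged before mapping; both configurable.
* Rank-deficient designs are refused with the collinear columns named, not
  silently dropped; monomorphic SNPs and |r| > 0.999 dosage pairs are
  errors naming the SNP.
* Logistic fits converge at deviance change $< 10^{-10}$ or 100
  iterations; separation (non-convergence, exploding Wald SE) drops the
  stratum with a logged warning rather than switching to penalised
  regression — conservative and transparent. Strata need 5 cases and 5
  controls by default.
* A leave-one-block-out subsample whose fit is singular is an error naming
  the block and stratum; small fixtures should use block counts and
  measured fractions that keep rare-allele copies per region-block cell
  well above zero.
* An exact-fit instrument ($r^2 = 1$) reports an infinite F flag rather
  than an error.

## Problem sizes used for validation

The test suite and the acceptance script validate parameter recovery with
100 replicates of $n = 100{,}000$ cohorts (weights within 2 SE of truth),
null calibration with 200+ simulated endpoints on one $n = 20{,}000$
cohort (Kolmogorov–Smirnov on z-scores and heterogeneity p-values), and
jackknife behaviour with 50–200 all-null replicates at $n = 20{,}000$.
These sizes mirror the order of magnitude of the emulated design while
keeping a full run in a few minutes on one CPU.

## A worked summary-level example

```{r}
est <- publishedEstimates()
urti <- est[est$label == "urti" & est$instrument == "pcsk9_score", ]
ivwMeta(urti$beta, urti$se)

a <- est[est$label == "urti" & est$instrument == "pcsk9_score" &
           est$cohort == "CKB", ]
b <- est[est$label == "urti" & est$instrument == "ldl_grs", ]
cochranQ(c(a$beta, b$beta), c(a$se, b$se))$pHet
```

## Known limitations

* The phenome-scan grouping shipped by `defaultPhewasGroups()` partitions
  A00–N99 into equal-width category ranges; it exercises the machinery but
  is not a curated clinical grouping.
* The polygenic-score filter assumes effect alleles are already aligned
  between internal and external sources; allele mismatches are an error,
  and no strand flipping is attempted.
* Fixed-effect pooling with estimated per-stratum SEs slightly
  underestimates the pooled SE for very rare variants in small strata
  (2–5% in our simulations); confidence intervals for such variants should
  be read accordingly.
* Survival modelling is out of scope: the association engine is logistic
  (cumulative risk) by design.
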