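---
title: "Region-based blood methylation EWAS with genotype-exposure model selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-based blood methylation EWAS with genotype-exposure model selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methgxe)
```

## The analysis

`methgxe` implements a sex-stratified, region-based epigenome-wide association
analysis of blood DNA methylation for early-stage Parkinson's disease (PD),
together with the downstream question the design exists to answer: once a
region is associated with disease status, how much of that association is
better explained by cis genotype (G), pesticide exposure (E), their sum
(G + E), or their interaction (G×E)?

The pipeline, per sex stratum:

1. **Cell composition.** Predicted immune cell-type proportions (an input;
   deconvolution itself is out of scope) are converted to robust principal
   components of their centered log-ratio (clr) coordinates and used as
   covariates, so compositional constraints never enter the regression
   directly.
2. **Regions.** Probes are grouped into co-methylated regions (CMRs): runs of
   adjacent probes on one chromosome, at most 1 kb apart, with pairwise
   Spearman correlation at least 0.3. A CMR is summarized per sample by the
   median beta of its member probes, and only CMRs whose 10th-to-90th
   percentile range of median beta exceeds 0.05 are analyzed. A reference CMR
   set may be supplied instead of calling regions from the data.
3. **Balance.** A probit propensity model on smoking, alcohol, head trauma,
   and age feeds full matching: controls are grouped with their nearest
   treated unit on the logit-score scale (caliper 0.2 SD of the logit score),
   and matched-set structure yields analysis weights. The EWAS still adjusts
   for the matching covariates (double robustness).
4. **EWAS.** Per CMR, a case-weighted Huber regression of median beta on
   disease status plus age, smoking, alcohol, head trauma, cell-type PCs 1-6,
   genotype PCs 1-3, plate and row. The disease coefficient is the adjusted
   case-control difference `delta_beta_adj`; p-values are BH-adjusted across
   the stratum's CMRs, and a hit requires `p_adj <= 0.05` and
   `|delta_beta_adj| >= 0.03` (the effect floor sits above
   technical-replicate error on the beta scale). Enrichment of the hit count
   is assessed by shuffling case labels and repeating the EWAS.
5. **Replication.** Effects are compared across cohorts by Pearson
   correlation of `delta_beta_adj` over covered CMRs, sign concordance with a
   label-permutation null, and a replication call requiring coverage, the
   same sign, and `|delta_beta_adj| >= 0.03` in the replication cohort.
6. **Model selection.** For each hit CMR, every SNP within a 75-kb window
   centered on the region and every exposure with at least 10% mean
   prevalence across imputations define the G / E / G+E / G×E model family on
   top of the base covariates. Exposure-containing models are fit once per
   imputed exposure copy (default 10) and pooled by Rubin's rules. Models are
   ranked by AIC; an F-test against the base model, corrected for selection
   and multiplicity (below), flags CMRs whose methylation is genuinely better
   explained; and the change in `|delta_beta_adj|` for disease under the best
   model quantifies how much of the apparent disease effect the genotype or
   exposure absorbs.
7. **Sensitivity.** Exposures can be split at the interpolated median lag
   time into recent (`lag < median`) and past (`lag >= median`) indicators
   and the selection re-run; a levodopa-dose model
   (`CMR beta ~ LED + age + plate + cell PC1`) runs on treated cases.

## The synthetic-cohort generator

Because the motivating cohort data are access-restricted, every stage is
exercised on seeded synthetic cohorts with known ground truth
(`simulate_cohort()`). The generator's defaults are the study conditions: 100
samples at a 33% case fraction (the female discovery arm), CMRs of three
probes, three binary pesticide exposures (insecticide, fungicide,
gardening-level) observed through 10 imputations, and small additive
plate/row shifts (SD 0.005 on the beta scale).

Methylation is built from a per-CMR latent Gaussian factor shared by member
probes, mapped through a logistic squash to (0, 1), plus independent probe
noise (`noise_sd`, default 0.03); planted effects are added on the beta scale
and values clipped to [0.001, 0.999], because every threshold and coefficient
in the analysis is stated on the beta scale. Two generator choices deserve
comment:

* **Biological scale.** The logit-scale latent SD defaults to 0.2. This was
  calibrated to the magnitude of real region-based summary statistics: at
  n = 100 the top associations in comparable blood studies show
  `delta_beta_adj` of 0.03-0.05 with p near 1e-5 to 1e-7, implying standard
  errors around 0.006-0.01, which is what `latent_sd = 0.2` (per-probe beta
  SD roughly 0.03-0.05) reproduces.
* **Correlation target.** The within-CMR correlation in `cmr_layout()` is the
  *observed* correlation: the generator inflates the latent correlation to
  compensate for the independent probe noise (capped at 1 where the target is
  unattainable), so configured and measured Spearman correlations agree.

The generator emulates a post-QC cohort. It does not emulate array chemistry,
probe-level QC artifacts, linkage disequilibrium between SNPs, or
cell-composition effects on methylation; passing tests therefore demonstrate
the statistical machinery under the assumed data-generating structure, not
robustness to raw-data pathologies.

## Numerical and inferential choices

Several places where the obvious textbook formula fails under this design are
worth recording.

**Standard errors.** The naive variance of the final weighted least-squares
step is badly anti-conservative here: on null cohorts the raw `p <= 0.05`
fraction reaches ~0.17 instead of 0.05, with roughly equal contributions from
the Huber approximation and from variable matching weights. `huber_wls()`
therefore defaults to the M-estimator sandwich variance — bread
`X' diag(w psi') X`, meat `X' diag(w^2 psi^2) X`, with a small-sample
`n_eff/(n_eff - p)` factor — which restores the nominal rate (0.04-0.06 across
all combinations of weighting and tuning). The naive formula remains
available via `se_type = "final_wls"`.

**AIC.** Two corrections keep the model ranking honest. First, the RSS inside
the AIC uses the robust fit's residuals under *case* weights only: the
robustness weights (and the Huber scale behind them) are re-estimated per
model, so a robustness-weighted RSS is not comparable across the family.
Second, the sample-size multiplier is the effective sample size
`ESS = (sum w)^2 / sum(w^2)` rather than n: under variable weights the
expected chance RSS gain of a junk parameter is `sigma^2 * sum(w^2)/sum(w)`,
and `ESS * log(RSS)` prices that at exactly 1 per parameter (the same
calibration `n * log(RSS)` provides for unit weights). Without these, junk
interaction terms gained 5-18 AIC units over the true model and planted
genotype effects were almost never recovered as G.

**Parsimony band.** Models within 2 AIC units of the minimum are treated as
equivalent and the smallest class (G < E < G+E < G×E), then the
lexicographically smallest SNP and exposure, is reported
(`parsimony_aic = 2`; set 0 for a strict minimum). Minimizing AIC over a grid
of nested models otherwise carries an irreducible bias toward the largest
class.

**Post-selection F-test.** The F-test of the selected model against the base
is a maximum over the evaluated grid, so its p-value is Bonferroni-adjusted
by the grid size before the BH adjustment within each exposure family (G-only
models form their own family). On fully null cohorts this keeps the fraction
of CMRs flagged "improved" below 10%.

**IRLS.** The Huber fit re-estimates scale each iteration as the
case-weighted median absolute residual over 0.6745. `huber_wls()` defaults to
150 iterations at a 1e-8 relative coefficient tolerance; pipeline callers
allow 2000 iterations because small strata with many covariates approach the
fixed point slowly (the solution then matches `MASS::rlm`, whose looser 1e-4
criterion simply stops earlier). Fits that still fail to converge — typically
regions whose robust scale implodes — are flagged, excluded from results and
from the BH denominator, and counted.

**Matching.** The caliper applies on the logit-score scale (0.2 SD), the
common convention; a raw-probability scale is available. Full matching
assigns each control to its nearest treated unit (treated units left without
controls join their nearest matched control's set); treated weight is 1, and
control weights are the set's treated:control ratio rescaled so total control
weight equals the number of matched controls. Caliper trimming can remove an
entire batch level, so the EWAS design is reduced to a full-rank column set
on the weighted support before fitting.

**Permutation enrichment.** Case labels are shuffled within the stratum and
the full EWAS plus hit calling repeated; the one-sided p is floored at
`1/n_perm`. Matching weights are kept fixed under permutation by default
(they are a property of the samples' covariates; refitting per permutation is
available), and when both sexes are analyzed the two permutation p-values are
BH-adjusted together.

**Compositional PCs.** The clr transform (multiplicative zero replacement,
default 1e-5) feeds a minimum-covariance-determinant scatter estimated in
orthonormal ilr coordinates and mapped back — the clr covariance is singular,
so MCD cannot run on it directly. The MCD subsample search is run under a
fixed, localized RNG seed so pipelines are bit-reproducible without
disturbing the caller's stream. With `robust = FALSE` the result equals
standard PCA on clr data exactly. clr (rather than ilr) coordinates are
reported for interpretability; loadings have their largest-magnitude entry
made positive.

**Imputation pooling.** Coefficients pool by Rubin's rules (mean estimate;
within + (1 + 1/m) between variance). AIC pools as the arithmetic mean of
per-imputation AICs and the F statistic as the mean statistic with unchanged
degrees of freedom — the simplest defensible rule, isolated in
`fit_and_pool()` for substitution.

**Conventions.** Coordinates are 1-based inclusive internally and in all
printed tables; BED export is 0-based half-open. A CMR's printed length is
`end - start`. Medians (CMR summaries, lag split) use the midpoint for even
counts and interpolation for quantiles; ties at the median lag count as past
exposure. Spearman correlations use average ranks for ties.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(
  n_samples = 200, case_fraction = 0.33,
  cmr_layout = cmr_layout(200, probe_count = 3),
  n_probes = 700,
  effects = c(lapply(1:5, function(i) effect_spec(i, "PD", 0.05)),
              list(effect_spec(5, "G", 0.05, snp_index = 5))),
  seed = 42)
bundle <- simulate_cohort(cfg)
res <- run_stratum_ewas(bundle)
head(res$ewas[order(res$ewas$p), ])
sel <- run_model_selection(res$cmr_matrix, res$hits, res$cmr_set, res$table,
                           res$weights, res$covariates, bundle$genotypes,
                           bundle$snp_manifest, bundle$exposures)
sel$records
```

## Problem sizes

The shipped tests and the acceptance script validate, at sizes chosen to make
the Monte-Carlo error small relative to the property being checked: null
calibration on cohorts of 100 samples and 2000-5000 CMRs across 12-50 seeds;
effect recovery at n = 200 with 20 planted regions over 10-12 seeds;
model-class recovery over 25-100 seeds per class; balance and permutation
properties over 20 seeds. Larger cohorts change none of the conclusions, only
the runtime.

## Limitations

* The generator's latent-Gaussian-plus-squash family is a stand-in; nothing
  is claimed about the true distributional family of cohort beta values.
* Full matching is nearest-treated assignment, not a provably optimal
  network-flow solution; on well-separated score clusters it attains the
  optimum (verified against exhaustive enumeration on small instances), but
  pathological configurations may differ from an optimal matcher.
* AIC pooling across imputations by arithmetic mean has no exact
  likelihood justification; it is a documented, replaceable rule.
* Sign concordance builds its null by permuting labels in the replication
  cohort; other defensible nulls exist and would give different p-values.
* Chromosome X is treated as an ordinary chromosome within a sex stratum;
  male dosage coding is the caller's responsibility.
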