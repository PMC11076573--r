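# methgxe

Region-based blood DNA-methylation association analysis for early-stage
Parkinson's disease (PD), with AIC-ranked genotype/exposure model selection.

Blood methylation studies of PD face three entangled problems: methylation is
spatially correlated along the array, so single-CpG tests waste power and
replicate poorly; cases and controls differ in demographics and cell
composition; and both the disease and methylation are influenced by genotype
and by environmental exposures such as pesticides. `methgxe` packages the
full analysis chain that addresses these at once, for epidemiologists and
epigeneticists running sex-stratified case-control methylation studies:

* **Co-methylated regions (CMRs)** — maximal runs of probes ≤ 1 kb apart with
  pairwise Spearman ρ ≥ 0.3, summarized per sample by the median β, filtered
  to regions whose 10th–90th percentile range of median β exceeds 0.05.
* **Propensity full matching** — probit scores on smoking, alcohol, head
  trauma, and age; matched-set weights with a 0.2-SD logit-scale caliper;
  balance reported as standardized mean differences (SMD).
* **Weighted robust EWAS** — per CMR, a case-weighted Huber regression
  `β ~ PD + age + smoking + alcohol + head trauma + cell PCs 1–6 +
  genotype PCs 1–3 + plate + row`; the PD coefficient is the adjusted
  case-control difference Δβ_adj; BH adjustment across CMRs; a hit requires
  p_adj ≤ 0.05 and |Δβ_adj| ≥ 0.03; label-permutation enrichment p-values.
* **Replication** — cross-cohort correlation of Δβ_adj, sign concordance
  with a permutation null, and replication calls (covered, same sign,
  |Δβ_adj| ≥ 0.03).
* **G×E model selection** — for each hit CMR, the model family
  {base, +G, +E, +G+E, +G×E} over SNPs within a 75-kb window and exposures
  with ≥ 10 % prevalence, pooled over multiply-imputed exposures by Rubin's
  rules, ranked by AIC, with a selection-corrected F-test and the change in
  |Δβ_adj(PD)| under the best model.
* **Synthetic cohorts** — a seeded generator (`simulate_cohort()`) with
  planted PD/G/E/G×E effects and ground-truth tables, so every stage is
  testable without access-restricted cohort data, plus an empirical power
  harness (`power_by_simulation()`).

The methods vignette (`vignettes/methods.Rmd`) documents the model, the
numerical choices (sandwich standard errors, effective-sample-size AIC,
parsimony band, post-selection correction), and known limitations.

## Worked example

Simulate a cohort of 200 samples (33 % cases) with disease effects of
Δβ = 0.05 planted at five CMRs, one of which also carries a cis genotype
effect, then run the per-stratum analysis and model selection:

```r
library(methgxe)

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
#>       cmr_id delta_beta_adj      se        p    p_adj   hit
#> 2   CMR00002         0.0443 0.00719 5.16e-09 1.03e-06  TRUE
#> 1   CMR00001         0.0493 0.00889 1.13e-07 1.13e-05  TRUE
#> 4   CMR00004         0.0429 0.00934 8.74e-06 5.81e-04  TRUE
#> 5   CMR00005         0.0534 0.01181 1.16e-05 5.81e-04  TRUE
#> 3   CMR00003         0.0324 0.00946 7.87e-04 3.15e-02  TRUE
#> 100 CMR00100         0.0177 0.00661 8.11e-03 2.70e-01 FALSE

sel <- run_model_selection(res$cmr_matrix, res$hits, res$cmr_set, res$table,
                           res$weights, res$covariates, bundle$genotypes,
                           bundle$snp_manifest, bundle$exposures)
sel$records[, c("cmr_id", "best_class", "snp_id", "coef_G",
                "daic_vs_base", "pd_change", "improved")]
#>     cmr_id best_class   snp_id coef_G daic_vs_base pd_change improved
#> 1 CMR00001       BASE     <NA>     NA          0.0   0.00000    FALSE
#> 2 CMR00002       BASE     <NA>     NA          0.0   0.00000    FALSE
#> 3 CMR00003       BASE     <NA>     NA          0.0   0.00000    FALSE
#> 4 CMR00004       BASE     <NA>     NA          0.0   0.00000    FALSE
#> 5 CMR00005          G rs000005 0.0458        -42.4   0.00624     TRUE
```

All five planted disease CMRs are recovered with Δβ_adj near the planted
0.05 (standard errors ≈ 0.01, p_adj ≤ 0.05). Model selection leaves the four
purely disease-driven regions at the base model and identifies the planted
genotype effect at CMR00005: the correct SNP, a coefficient near the planted
0.05 per allele, an AIC improvement of 42 units, and a selection-corrected
F-test flagging it as a genuine improvement. `run_pipeline()` wraps the same
stages (plus permutation enrichment and lag-time sensitivity) across sex
strata and writes TSV reports and a JSON run log.

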