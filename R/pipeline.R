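#' Standard EWAS covariate set
#'
#' Age, smoking, alcohol, head trauma, cell-type PCs 1-6, genotype PCs 1-3,
#' plate and row (chip is deliberately not a covariate). Factors reduced to a
#' single level in a stratum are dropped automatically by
#' [run_stratum_ewas()].
#' @export
ewas_covariates <- function() {
  c("age", "smoking", "alcohol", "head_trauma",
    paste0("cpc", 1:6), paste0("gpc", 1:3), "plate", "row")
}

#' Run the per-stratum region-based EWAS
#'
#' One stratum end to end: robust compositional cell-type PCs, probit
#' propensity scores and full-matching weights, CMR median-beta
#' summarization against the (reference) CMR set, variability filter, and the
#' weighted Huber-regression EWAS with BH adjustment and hit calling.
#'
#' @param bundle a `cohort_bundle`.
#' @param subset optional logical/integer index selecting the stratum's
#'   samples (e.g. one sex); default all samples.
#' @param target main-effect column (default `"case"`).
#' @param p_thr,effect_thr hit thresholds.
#' @param n_pcs cell-type PCs used as covariates (default 6).
#' @param match_vars propensity-matching covariates.
#' @param caliper full-matching caliper (default 0.2, logit scale).
#' @param apply_filter apply the 10th-90th percentile variability filter.
#' @param match smoothing switch: set FALSE to skip matching (unit weights).
#' @param reference_cmrs optional external `cmr_set`; defaults to the
#'   bundle's.
#' @return list: `ewas` (an `ewas_table`), `hits`, `weights`, `cmr_matrix`
#'   (filtered), `table` (stratum covariate table incl. cell PCs),
#'   `covariates` (columns used), `retained` (ids passing the filter),
#'   `balance` (SMD report), `cmr_set`.
#' @export
run_stratum_ewas <- function(bundle, subset = NULL, target = "case",
                             p_thr = 0.05, effect_thr = 0.03, n_pcs = 6L,
                             match_vars = c("smoking", "alcohol",
                                            "head_trauma", "age"),
                             caliper = 0.2, apply_filter = TRUE,
                             match = TRUE, reference_cmrs = NULL) {
  idx <- if (is.null(subset)) seq_len(nrow(bundle$samples)) else
    seq_len(nrow(bundle$samples))[subset]
  tab <- bundle$samples[idx, , drop = FALSE]
  tab$plate <- droplevels(factor(tab$plate))
  tab$row <- droplevels(factor(tab$row))
  pcs <- robust_compositional_pcs(bundle$cell_props[idx, , drop = FALSE],
                                  n_pcs = n_pcs)
  colnames(pcs$scores) <- paste0("cpc", seq_len(n_pcs))
  tab <- cbind(tab, pcs$scores)

  weights <- NULL
  balance <- NULL
  if (match) {
    pf <- fit_propensity(tab, match_vars, group_col = target)
    weights <- full_match_weights(pf$scores, tab[[target]], caliper = caliper)
    balance <- balance_report(tab, match_vars, weights, group_col = target)
  }

  cmrs <- reference_cmrs %||% bundle$cmr_set
  cmr_mat <- summarize_cmr_beta(bundle$beta[, idx, drop = FALSE], cmrs)
  retained <- if (apply_filter) variability_filter(cmr_mat) else rownames(cmr_mat)
  cmr_mat <- cmr_mat[retained, , drop = FALSE]

  covs <- intersect(ewas_covariates(), names(tab))
  covs <- covs[vapply(covs, function(v) {
    x <- tab[[v]]
    if (is.factor(x)) nlevels(x) >= 2 else stats::var(as.numeric(x)) > 0
  }, TRUE)]
  ew <- run_cmr_ewas(cmr_mat, tab, weights, target = target,
                     covariates = covs, p_thr = p_thr, effect_thr = effect_thr)
  list(ewas = ew, hits = call_hits(ew, p_thr, effect_thr), weights = weights,
       cmr_matrix = cmr_mat, table = tab, covariates = covs,
       retained = retained, balance = balance, cmr_set = cmrs,
       stratum_index = idx)
}

#' Pipeline configuration
#'
#' Thresholds and switches for [run_pipeline()], with the analysis defaults:
#' hit thresholds `p_thr = 0.05`, `effect_thr = 0.03`; CMR calling
#' `min_corr = 0.3`, `max_gap = 1000`; caliper 0.2; SNP window 75 kb
#' (centered); exposure eligibility 10%; 1000 permutations; 10 imputations.
#'
#' @param out_dir output directory.
#' @param stratify_by stratification column (default `"sex"`).
#' @param p_thr,effect_thr,min_corr,max_gap,caliper,window_bp,window_mode,min_prev
#'   analysis thresholds (see module functions).
#' @param n_perm permutations for the enrichment test; 0 disables it.
#' @param run_gxe,run_sensitivity stage switches.
#' @param seed integer seed for all randomized stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, stratify_by = "sex", p_thr = 0.05,
                            effect_thr = 0.03, min_corr = 0.3, max_gap = 1000,
                            caliper = 0.2, window_bp = 75000,
                            window_mode = "centered", min_prev = 0.10,
                            n_perm = 1000L, run_gxe = TRUE,
                            run_sensitivity = FALSE, seed = 1L) {
  check_number(p_thr, "p_thr", lo = 0, hi = 1)
  check_number(effect_thr, "effect_thr", lo = 0, hi = 1)
  check_number(min_corr, "min_corr", lo = -1, hi = 1)
  check_number(max_gap, "max_gap", lo = 1)
  check_number(caliper, "caliper", lo = 0)
  check_number(window_bp, "window_bp", lo = 0)
  check_number(min_prev, "min_prev", lo = 0, hi = 1)
  check_number(n_perm, "n_perm", lo = 0, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  structure(list(out_dir = out_dir, stratify_by = stratify_by, p_thr = p_thr,
                 effect_thr = effect_thr, min_corr = min_corr,
                 max_gap = max_gap, caliper = caliper, window_bp = window_bp,
                 window_mode = window_mode, min_prev = min_prev,
                 n_perm = as.integer(n_perm), run_gxe = run_gxe,
                 run_sensitivity = run_sensitivity, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(unclass(config)[order(names(unclass(config)))], tf)
  unname(tools::md5sum(tf))
}

#' Run the full analysis pipeline on a cohort bundle
#'
#' Per stratum: cell-type PCs, propensity full matching, CMR summarization and
#' variability filter, weighted robust EWAS with hit calling, optional
#' permutation enrichment, and optional AIC-ranked genotype/exposure model
#' selection (plus lag-time sensitivity) on the hits. All report tables and a
#' JSON run log (config hash, seed, per-stage record counts, warnings) are
#' written under `config$out_dir`; repeated runs with the same inputs, config
#' and seed are byte-identical.
#'
#' @param bundle a validated `cohort_bundle`.
#' @param config a [pipeline_config()].
#' @return (invisibly) list of per-stratum results plus the run log.
#' @export
run_pipeline <- function(bundle, config) {
  validate_inputs(bundle)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  strata <- sort(unique(bundle$samples[[config$stratify_by]]))
  results <- list()
  log <- list(config_hash = config_hash(config), seed = config$seed,
              strata = list(), warnings = list())
  enrich_p <- c()
  for (s in strata) {
    idx <- bundle$samples[[config$stratify_by]] == s
    res <- run_stratum_ewas(bundle, subset = idx, p_thr = config$p_thr,
                            effect_thr = config$effect_thr,
                            caliper = config$caliper)
    stage <- list(n_samples = sum(idx),
                  n_cmrs = nrow(bundle$cmr_set$regions),
                  n_retained = length(res$retained),
                  n_fit = nrow(res$ewas),
                  n_hits = length(res$hits))
    coords <- res$cmr_set$regions[match(res$ewas$cmr_id,
                                        res$cmr_set$regions$cmr_id), ]
    out_tab <- cbind(coords[, c("cmr_id", "chrom", "start", "end", "n_probes")],
                     res$ewas[, c("delta_beta_adj", "se", "p", "p_adj", "hit")])
    write_tsv(out_tab, file.path(config$out_dir, sprintf("ewas_%s.tsv", s)))
    if (!is.null(res$balance))
      write_tsv(res$balance, file.path(config$out_dir,
                                       sprintf("balance_%s.tsv", s)))
    if (config$n_perm > 0) {
      pe <- permutation_enrichment(res$cmr_matrix, res$table, res$weights,
                                   covariates = res$covariates,
                                   p_thr = config$p_thr,
                                   effect_thr = config$effect_thr,
                                   n_perm = config$n_perm,
                                   seed = derive_seed(config$seed,
                                                      paste0("perm_", s)))
      stage$enrichment_p <- pe$p
      enrich_p[s] <- pe$p
      res$enrichment <- pe
    }
    if (config$run_gxe && length(res$hits) && nrow(bundle$genotypes)) {
      sel <- run_model_selection(res$cmr_matrix, res$hits, res$cmr_set,
                                 res$table, res$weights, res$covariates,
                                 bundle$genotypes[, res$stratum_index,
                                                  drop = FALSE],
                                 bundle$snp_manifest, bundle$exposures,
                                 panel_subset = res$stratum_index,
                                 window_bp = config$window_bp,
                                 window_mode = config$window_mode,
                                 min_prev = config$min_prev)
      stage$n_improved <- sum(sel$records$improved %||% logical(0))
      write_tsv(sel$records, file.path(config$out_dir,
                                       sprintf("model_selection_%s.tsv", s)))
      res$selection <- sel
      if (config$run_sensitivity && nrow(sel$records)) {
        lag <- rerank_with_lag(sel, res$cmr_matrix, res$hits, res$cmr_set,
                               res$table, res$weights, res$covariates,
                               bundle$genotypes[, res$stratum_index,
                                                drop = FALSE],
                               bundle$snp_manifest, bundle$exposures,
                               panel_subset = res$stratum_index,
                               window_bp = config$window_bp,
                               window_mode = config$window_mode)
        stage$lag_retained_class_fraction <- lag$retained_class_fraction
        write_tsv(lag$stability, file.path(config$out_dir,
                                           sprintf("lag_stability_%s.tsv", s)))
        res$lag <- lag
      }
    }
    log$strata[[as.character(s)]] <- stage
    results[[as.character(s)]] <- res
  }
  if (length(enrich_p) > 1)
    log$enrichment_p_adj <- as.list(stats::setNames(bh_adjust(enrich_p),
                                                    names(enrich_p)))
  jsonlite::write_json(log, file.path(config$out_dir, "runlog.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(results = results, log = log))
}
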