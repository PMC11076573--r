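#' SNPs in a cis window around a CMR
#'
#' `"centered"` mode (default) returns SNPs within `width_bp / 2` of the CMR
#' midpoint, i.e. a window of total width `width_bp` centered on the region;
#' `"flank"` mode returns SNPs within `width_bp` of the interval
#' \[start, end\].
#'
#' @param cmr list or one-row data frame with `chrom`, `start`, `end`.
#' @param snp_manifest data frame (`snp_id`, `chrom`, `pos`), 1-based.
#' @param width_bp window size in bp (default 75000).
#' @param mode `"centered"` or `"flank"`.
#' @return character vector of SNP ids.
#' @export
snp_window <- function(cmr, snp_manifest, width_bp = 75000,
                       mode = c("centered", "flank")) {
  mode <- match.arg(mode)
  same <- snp_manifest$chrom == cmr$chrom
  keep <- if (mode == "centered") {
    mid <- (cmr$start + cmr$end) / 2
    same & abs(snp_manifest$pos - mid) <= width_bp / 2
  } else {
    same & snp_manifest$pos >= cmr$start - width_bp &
      snp_manifest$pos <= cmr$end + width_bp
  }
  snp_manifest$snp_id[keep]
}

#' Exposures meeting the prevalence eligibility rule
#'
#' An exposure is eligible when its mean prevalence across imputations (within
#' the analysis stratum) is at least `min_prev` (default 10%).
#'
#' @param panel an `exposure_panel`.
#' @param min_prev minimum mean prevalence (inclusive).
#' @param subset optional logical/integer index restricting to a stratum.
#' @return character vector of eligible exposure names.
#' @export
eligible_exposures <- function(panel, min_prev = 0.10, subset = NULL) {
  names(which(vapply(panel$exposures, function(e) {
    im <- e$imputations
    if (!is.null(subset)) im <- im[subset, , drop = FALSE]
    mean(colMeans(im)) >= min_prev
  }, TRUE)))
}

#' Model specification for the G/E/G+E/GxE family
#'
#' @param class one of `"BASE"`, `"G"`, `"E"`, `"G_plus_E"`, `"GxE"`.
#' @param snp_id SNP id (required for G-containing classes).
#' @param exposure exposure name (required for E-containing classes).
#' @export
model_spec <- function(class, snp_id = NULL, exposure = NULL) {
  class <- match.arg(class, c("BASE", "G", "E", "G_plus_E", "GxE"))
  if (class %in% c("G", "G_plus_E", "GxE") && is.null(snp_id))
    stop("snp_id required for class ", class)
  if (class %in% c("E", "G_plus_E", "GxE") && is.null(exposure))
    stop("exposure required for class ", class)
  if (class %in% c("BASE", "G")) exposure <- NULL
  if (class %in% c("BASE", "E")) snp_id <- NULL
  structure(list(class = class, snp_id = snp_id, exposure = exposure),
            class = "model_spec")
}

class_rank <- function(class) {
  match(class, c("BASE", "G", "E", "G_plus_E", "GxE"))
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Point estimate is the mean; total variance is the mean within-imputation
#' variance plus `(1 + 1/m)` times the between-imputation variance. Degrees of
#' freedom follow the classical formula `(m - 1) (1 + U / ((1 + 1/m) B))^2`
#' (infinite when the estimates agree exactly).
#'
#' @param estimates per-imputation point estimates.
#' @param variances per-imputation squared standard errors.
#' @return list: `estimate`, `variance`, `se`, `df`, `m`, `between`, `within`.
#' @export
pool_rubin <- function(estimates, variances) {
  m <- length(estimates)
  stopifnot(length(variances) == m, m >= 1)
  qbar <- mean(estimates)
  U <- mean(variances)
  B <- if (m > 1) stats::var(estimates) else 0
  Tvar <- U + (1 + 1 / m) * B
  df <- if (B > 0) (m - 1) * (1 + U / ((1 + 1 / m) * B))^2 else Inf
  list(estimate = qbar, variance = Tvar, se = sqrt(Tvar), df = df, m = m,
       between = B, within = U)
}

# Extended design columns for a spec at one imputation.
spec_columns <- function(spec, g, e) {
  switch(spec$class,
    BASE = NULL,
    G = cbind(G = g),
    E = cbind(E = e),
    G_plus_E = cbind(G = g, E = e),
    GxE = cbind(G = g, E = e, GxE = g * e))
}

#' Fit one model spec and pool over exposure imputations
#'
#' Fits the extended model per exposure imputation with [huber_wls()], pools
#' the added coefficients by Rubin's rules, averages per-imputation AIC, and
#' reports the mean F statistic of the extended model against the base design
#' (weighted RSS compared on each extended fit's final IRLS weights, with
#' degrees of freedom equal to the number of added parameters). Classes
#' without an exposure term are single fits.
#'
#' @param y response (CMR median beta across the stratum's samples).
#' @param base_design base-model design matrix (disease status + covariates).
#' @param spec a [model_spec()].
#' @param genotypes SNPs x samples dosage matrix (for G classes).
#' @param panel an `exposure_panel` (for E classes); `subset` selects the
#'   stratum rows aligned with `y`.
#' @param weights case weights.
#' @param subset optional index into the panel's samples.
#' @param tuning,max_iter passed to [huber_wls()].
#' @return list with `spec`, `aic`, `f`, `p_f`, `df1`, `df2`, pooled
#'   coefficients `coef` (named by added term), their `se`, and `pd_coef` /
#'   `pd_se` (pooled disease-status coefficient under this model); or NULL
#'   when the spec is degenerate in the stratum (monomorphic SNP, constant
#'   exposure) or fails to fit.
#' @export
fit_and_pool <- function(y, base_design, spec, genotypes = NULL, panel = NULL,
                         weights = NULL, subset = NULL, tuning = 1.345,
                         max_iter = 2000L) {
  n <- length(y)
  if (is.null(weights)) weights <- rep(1, n)
  active <- weights > 0
  g <- NULL
  if (!is.null(spec$snp_id)) {
    g <- as.numeric(genotypes[spec$snp_id, ])
    if (stats::var(g[active]) == 0) return(NULL)  # monomorphic in stratum
  }
  e_mat <- NULL
  if (!is.null(spec$exposure)) {
    e_mat <- panel$exposures[[spec$exposure]]$imputations
    if (is.null(e_mat)) stop("unknown exposure: ", spec$exposure)
    if (!is.null(subset)) e_mat <- e_mat[subset, , drop = FALSE]
    if (nrow(e_mat) != n) stop("exposure panel does not align with y")
    if (any(apply(e_mat[active, , drop = FALSE], 2, stats::var) == 0))
      return(NULL)  # exposure constant in the stratum in some imputation
  }
  m <- if (is.null(e_mat)) 1L else ncol(e_mat)
  pd_col <- 2L  # target immediately follows intercept in build_design output

  ests <- list(); vars <- list()
  aics <- fs <- pds <- pdv <- numeric(m)
  df1 <- df2 <- NA_real_
  for (i in seq_len(m)) {
    e <- if (is.null(e_mat)) NULL else e_mat[, i]
    extra <- spec_columns(spec, g, e)
    X1 <- if (is.null(extra)) base_design else cbind(base_design, extra)
    fit <- tryCatch(huber_wls(y, X1, case_weights = weights, tuning = tuning,
                              max_iter = max_iter),
                    error = function(err) NULL)
    if (is.null(fit) || !fit$converged) return(NULL)
    aics[i] <- fit$aic
    pds[i] <- fit$coefficients[pd_col]
    pdv[i] <- fit$se[pd_col]^2
    if (!is.null(extra)) {
      q <- ncol(extra)
      rss0 <- wls_rss(y, base_design, fit$total_weights)
      fs[i] <- ((rss0 - fit$wrss) / q) / (fit$wrss / fit$df)
      df1 <- q; df2 <- fit$df
      idx <- (ncol(X1) - q + 1):ncol(X1)
      ests[[i]] <- stats::setNames(fit$coefficients[idx], colnames(extra))
      vars[[i]] <- fit$se[idx]^2
    }
  }
  coef <- se <- NULL
  if (length(ests)) {
    nm <- names(ests[[1]])
    pooled <- lapply(seq_along(nm), function(j)
      pool_rubin(vapply(ests, `[[`, 0, j), vapply(vars, `[[`, 0, j)))
    coef <- stats::setNames(vapply(pooled, `[[`, 0, "estimate"), nm)
    se <- stats::setNames(vapply(pooled, `[[`, 0, "se"), nm)
  }
  pd_pool <- pool_rubin(pds, pdv)
  f_mean <- if (spec$class == "BASE") NA_real_ else mean(fs)
  list(spec = spec, aic = mean(aics),
       f = f_mean,
       p_f = if (is.na(f_mean)) NA_real_ else
         stats::pf(f_mean, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, coef = coef, se = se,
       pd_coef = pd_pool$estimate, pd_se = pd_pool$se, m = m)
}

#' Select the minimum-AIC model for one CMR
#'
#' Takes the evaluated grid for one CMR (a list of [fit_and_pool()] results,
#' the first of which must be the base model) and returns the selection
#' record. Models within `parsimony_aic` units of the minimum AIC are treated
#' as equivalent (the conventional delta-AIC < 2 equivalence band), and the
#' most parsimonious is selected: smallest model class (BASE < G < E < G+E <
#' GxE), then lexicographically by SNP id and exposure. Set
#' `parsimony_aic = 0` for a strict lowest-AIC rule.
#'
#' @param cmr_id CMR identifier.
#' @param grid list of fit results; element 1 is the BASE fit.
#' @param parsimony_aic AIC equivalence band (default 2).
#' @return one-row data frame: best class/snp/exposure, pooled coefficients,
#'   `aic`, `daic_vs_base`, `f`, `p_f`, PD effect under base and best, and the
#'   signed `pd_change` = |pd_best| - |pd_base|.
#' @export
select_best_model <- function(cmr_id, grid, parsimony_aic = 2) {
  stopifnot(length(grid) >= 1, grid[[1]]$spec$class == "BASE")
  base <- grid[[1]]
  aics <- vapply(grid, `[[`, 0, "aic")
  cand <- which(aics <= min(aics) + parsimony_aic + 1e-9)
  if (length(cand) > 1) {
    ord <- order(vapply(cand, function(i) class_rank(grid[[i]]$spec$class), 0),
                 vapply(cand, function(i) grid[[i]]$spec$snp_id %||% "", ""),
                 vapply(cand, function(i) grid[[i]]$spec$exposure %||% "", ""))
    cand <- cand[ord]
  }
  best <- grid[[cand[1]]]
  get_coef <- function(fit, nm) if (!is.null(fit$coef) && nm %in% names(fit$coef))
    unname(fit$coef[nm]) else NA_real_
  data.frame(
    cmr_id = cmr_id,
    best_class = best$spec$class,
    snp_id = best$spec$snp_id %||% NA_character_,
    exposure = best$spec$exposure %||% NA_character_,
    coef_G = get_coef(best, "G"),
    coef_E = get_coef(best, "E"),
    coef_GxE = get_coef(best, "GxE"),
    aic = best$aic,
    daic_vs_base = best$aic - base$aic,
    f = best$f, p_f = best$p_f,
    pd_base = base$pd_coef, pd_best = best$pd_coef,
    pd_change = abs(best$pd_coef) - abs(base$pd_coef),
    stringsAsFactors = FALSE)
}

#' Signed change in the disease effect under the best model
#'
#' `|delta_beta_adj(PD, best)| - |delta_beta_adj(PD, base)|`; negative values
#' indicate attenuation of the disease effect once genotype/exposure terms are
#' accounted for.
#'
#' @param record a selection record row from [select_best_model()].
#' @return signed change.
#' @export
pd_effect_change <- function(record) {
  abs(record$pd_best) - abs(record$pd_base)
}

#' Rank genotype/exposure models across PD-associated CMRs
#'
#' For each hit CMR, fits the base model plus every G, E, G+E, and GxE spec
#' over the cis-SNP window and eligible exposures, pools E-containing models
#' over imputations, selects the minimum-AIC model, and BH-adjusts the
#' F-test p-values of the selected models within families: one family per
#' exposure (all selected models involving that exposure) and one family for
#' the G-only models. A record is flagged `improved` when a non-base model was
#' selected and its family-adjusted F p-value is at most `alpha`.
#'
#' @param cmr_matrix CMRs x samples median-beta matrix for the stratum.
#' @param hit_ids CMR ids to analyze (rows of `cmr_matrix`).
#' @param cmr_set `cmr_set` providing coordinates for the hits.
#' @param table stratum sample table.
#' @param weights case weights (e.g. full-matching weights).
#' @param covariates adjustment covariates for the base model.
#' @param genotypes SNPs x samples dosages aligned with `table`.
#' @param snp_manifest SNP positions.
#' @param panel `exposure_panel` aligned with `table` (or use `panel_subset`).
#' @param panel_subset optional index mapping `table` rows into the panel.
#' @param window_bp,window_mode passed to [snp_window()].
#' @param min_prev exposure eligibility threshold.
#' @param alpha significance level on the adjusted F p-value (default 0.05).
#' @param parsimony_aic AIC equivalence band for [select_best_model()].
#' @param target disease-status column (default `"case"`).
#' @param tuning,max_iter passed to [huber_wls()].
#' @return list: `records` (one row per CMR with `p_adj_f` and `improved`),
#'   `n_skipped` (degenerate specs), and `grid_sizes`.
#' @export
run_model_selection <- function(cmr_matrix, hit_ids, cmr_set, table, weights,
                                covariates, genotypes, snp_manifest, panel,
                                panel_subset = NULL, window_bp = 75000,
                                window_mode = "centered", min_prev = 0.10,
                                alpha = 0.05, target = "case",
                                parsimony_aic = 2,
                                tuning = 1.345, max_iter = 2000L) {
  d <- build_design(table, target, covariates)
  w <- resolve_weights(weights, table)
  d$X <- reduce_design(d$X, w, d$target_col)
  elig <- eligible_exposures(panel, min_prev, subset = panel_subset)
  records <- list()
  n_skipped <- 0L
  grid_sizes <- integer(0)
  for (cid in hit_ids) {
    y <- cmr_matrix[cid, ]
    reg <- cmr_set$regions[cmr_set$regions$cmr_id == cid, ]
    snps <- if (nrow(reg)) snp_window(reg, snp_manifest, window_bp, window_mode)
            else character(0)
    specs <- list(model_spec("BASE"))
    for (s in snps) specs <- c(specs, list(model_spec("G", snp_id = s)))
    for (e in elig) specs <- c(specs, list(model_spec("E", exposure = e)))
    for (s in snps) for (e in elig) {
      specs <- c(specs, list(model_spec("G_plus_E", snp_id = s, exposure = e),
                             model_spec("GxE", snp_id = s, exposure = e)))
    }
    grid <- list()
    for (sp in specs) {
      r <- fit_and_pool(y, d$X, sp, genotypes = genotypes, panel = panel,
                        weights = w, subset = panel_subset, tuning = tuning,
                        max_iter = max_iter)
      if (is.null(r)) { if (sp$class != "BASE") n_skipped <- n_skipped + 1L; next }
      grid[[length(grid) + 1L]] <- r
    }
    if (!length(grid) || grid[[1]]$spec$class != "BASE")
      stop(sprintf("base model failed to fit for %s", cid))
    grid_sizes <- c(grid_sizes, length(grid) - 1L)
    rec1 <- select_best_model(cid, grid, parsimony_aic)
    rec1$n_grid <- length(grid) - 1L
    records[[cid]] <- rec1
  }
  rec <- do.call(rbind, records)
  if (is.null(rec)) {
    return(list(records = data.frame(), n_skipped = n_skipped,
                grid_sizes = grid_sizes))
  }
  rownames(rec) <- NULL
  # the F-test of the *selected* model is a post-selection test: Bonferroni
  # over the CMR's evaluated grid first, then BH within families (per
  # exposure; G-only models across their own grid)
  rec$p_f_sel <- pmin(1, rec$p_f * pmax(rec$n_grid, 1L))
  rec$p_adj_f <- NA_real_
  fam <- ifelse(rec$best_class == "G", "G",
                ifelse(is.na(rec$exposure), NA, rec$exposure))
  for (f in unique(stats::na.omit(fam))) {
    i <- which(fam == f & !is.na(rec$p_f_sel))
    if (length(i)) rec$p_adj_f[i] <- bh_adjust(rec$p_f_sel[i])
  }
  rec$improved <- !is.na(rec$p_adj_f) & rec$best_class != "BASE" &
    rec$p_adj_f <= alpha
  list(records = rec, n_skipped = n_skipped, grid_sizes = grid_sizes)
}

#' Proximity of SNPs to independent GWAS hits
#'
#' @param snp_ids SNPs to test.
#' @param snp_manifest data frame (`snp_id`, `chrom`, `pos`).
#' @param gwas_hits data frame (`chrom`, `pos`), 1-based.
#' @param window_bp proximity window (default 1 Mb).
#' @return named logical: TRUE iff any GWAS hit lies on the same chromosome
#'   within `window_bp`.
#' @export
gwas_proximity <- function(snp_ids, snp_manifest, gwas_hits, window_bp = 1e6) {
  i <- match(snp_ids, snp_manifest$snp_id)
  if (anyNA(i)) stop("unknown SNP id(s)")
  out <- vapply(i, function(j) {
    same <- gwas_hits$chrom == snp_manifest$chrom[j]
    any(same & abs(gwas_hits$pos - snp_manifest$pos[j]) <= window_bp)
  }, TRUE)
  stats::setNames(out, snp_ids)
}
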