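#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (wraps `stats::p.adjust(method = "BH")` with input
#' validation).
#'
#' @param p vector of p-values in \[0,1\]; NA/NaN is an error.
#' @return adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p)) stop("p-values must not contain NA/NaN")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

# Design matrix for the EWAS formula; returns the matrix and the name of the
# target coefficient column.
build_design <- function(table, target = "case", covariates) {
  miss <- setdiff(c(target, covariates), names(table))
  if (length(miss))
    stop(sprintf("column(s) not found in sample table: %s", paste(miss, collapse = ", ")))
  fml <- stats::as.formula(paste("~", paste(c(target, covariates), collapse = " + ")))
  X <- stats::model.matrix(fml, data = table)
  tcol <- grep(paste0("^", target), colnames(X), value = TRUE)[1L]
  list(X = X, target_col = tcol)
}

# Drop design columns that are degenerate on the weighted support (e.g. a
# batch level wholly trimmed by the caliper), keeping a full-rank column set.
# The target column must survive.
reduce_design <- function(X, w, target_col) {
  q <- qr(X * sqrt(w))
  if (q$rank < ncol(X)) {
    keep <- sort(q$pivot[seq_len(q$rank)])
    if (!(match(target_col, colnames(X)) %in% keep))
      stop(sprintf("target '%s' is collinear on the weighted support", target_col))
    X <- X[, keep, drop = FALSE]
  }
  X
}

resolve_weights <- function(weights, table) {
  if (is.null(weights)) return(rep(1, nrow(table)))
  if (is.data.frame(weights)) {
    i <- match(table$sample_id, weights$sample_id)
    if (anyNA(i)) stop("weights do not cover all samples")
    return(weights$weight[i])
  }
  stopifnot(length(weights) == nrow(table))
  as.numeric(weights)
}

#' Region-based weighted robust-regression EWAS
#'
#' Fits, per CMR, a weighted Huber regression of CMR median beta on the target
#' variable and covariates, and reports the target coefficient as the adjusted
#' effect (for disease status, the adjusted case-control difference
#' `delta_beta_adj`). P-values are BH-adjusted across the CMRs of the stratum.
#' CMRs whose fit fails (rank deficiency, non-convergence) are excluded from
#' both the results and the BH denominator and counted in the `n_excluded`
#' attribute.
#'
#' @param cmr_matrix CMRs x samples median-beta matrix (typically after
#'   [variability_filter()]).
#' @param table sample covariate table; rows align with the columns of
#'   `cmr_matrix`.
#' @param weights propensity full-matching weights (a `weight_vector`, a
#'   numeric vector, or NULL for unweighted).
#' @param target column whose coefficient is reported (default `"case"`; any
#'   column, e.g. a pesticide-exposure indicator, may be used as the main
#'   effect).
#' @param covariates character vector of adjustment covariate columns.
#' @param p_thr,effect_thr hit-calling thresholds (defaults 0.05 and 0.03).
#' @param tuning,max_iter passed to [huber_wls()].
#' @return data frame of class `ewas_table`: `cmr_id`, `delta_beta_adj`, `se`,
#'   `p`, `p_adj`, `hit`, with attributes `n_excluded` and `excluded_ids`.
#' @export
run_cmr_ewas <- function(cmr_matrix, table, weights = NULL, target = "case",
                         covariates, p_thr = 0.05, effect_thr = 0.03,
                         tuning = 1.345, max_iter = 2000L) {
  if (ncol(cmr_matrix) != nrow(table))
    stop("cmr_matrix columns must align with sample table rows")
  d <- build_design(table, target, covariates)
  w <- resolve_weights(weights, table)
  d$X <- reduce_design(d$X, w, d$target_col)
  ids <- rownames(cmr_matrix)
  nr <- nrow(cmr_matrix)
  est <- se <- p <- rep(NA_real_, nr)
  ok <- logical(nr)
  for (i in seq_len(nr)) {
    fit <- tryCatch(huber_wls(cmr_matrix[i, ], d$X, case_weights = w,
                              tuning = tuning, max_iter = max_iter),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    j <- match(d$target_col, colnames(d$X))
    est[i] <- fit$coefficients[j]
    se[i] <- fit$se[j]
    p[i] <- fit$p[j]
    ok[i] <- TRUE
  }
  out <- data.frame(cmr_id = ids[ok], delta_beta_adj = est[ok], se = se[ok],
                    p = p[ok], stringsAsFactors = FALSE)
  out$p_adj <- if (nrow(out)) bh_adjust(out$p) else numeric(0)
  out$hit <- out$p_adj <= p_thr & abs(out$delta_beta_adj) >= effect_thr
  attr(out, "n_excluded") <- sum(!ok)
  attr(out, "excluded_ids") <- ids[!ok]
  class(out) <- c("ewas_table", "data.frame")
  out
}

#' Call differentially methylated CMRs
#'
#' A CMR is a hit when `p_adj <= p_thr` and `|delta_beta_adj| >= effect_thr`
#' (defaults 0.05 and 0.03; the effect threshold is chosen to exceed
#' technical-replicate error on the beta scale).
#'
#' @param ewas an `ewas_table`.
#' @param p_thr,effect_thr thresholds.
#' @return character vector of hit CMR ids.
#' @export
call_hits <- function(ewas, p_thr = 0.05, effect_thr = 0.03) {
  ewas$cmr_id[ewas$p_adj <= p_thr & abs(ewas$delta_beta_adj) >= effect_thr]
}

#' Permutation test for enrichment of differentially methylated CMRs
#'
#' Shuffles the target labels (e.g. disease status) within the stratum,
#' repeats the full EWAS and hit calling per permutation, and reports the
#' one-sided permutation p-value `#{permuted count >= observed} / n_perm`,
#' floored at `1/n_perm`. Matching weights are kept fixed by default; set
#' `refit_weights` with `match_vars` to re-estimate the propensity weights for
#' each permuted labelling. When both sexes are analyzed, BH-adjust the two
#' permutation p-values together with [bh_adjust()].
#'
#' @inheritParams run_cmr_ewas
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param refit_weights refit propensity full-matching weights per permutation.
#' @param match_vars matching covariates, required when `refit_weights`.
#' @return list: `observed` (hit count), `p`, `perm_counts`.
#' @export
permutation_enrichment <- function(cmr_matrix, table, weights = NULL,
                                   target = "case", covariates,
                                   p_thr = 0.05, effect_thr = 0.03,
                                   n_perm = 1000L, seed = 1L,
                                   refit_weights = FALSE, match_vars = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  obs_tab <- run_cmr_ewas(cmr_matrix, table, weights, target, covariates,
                          p_thr, effect_thr)
  observed <- length(call_hits(obs_tab, p_thr, effect_thr))
  set.seed(seed)
  perm_counts <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    tb <- table
    tb[[target]] <- sample(tb[[target]])
    wb <- weights
    if (refit_weights) {
      if (is.null(match_vars)) stop("match_vars required when refit_weights = TRUE")
      pf <- fit_propensity(tb, match_vars, group_col = target)
      wb <- full_match_weights(pf$scores, tb[[target]])
    }
    et <- run_cmr_ewas(cmr_matrix, tb, wb, target, covariates, p_thr, effect_thr)
    perm_counts[b] <- length(call_hits(et, p_thr, effect_thr))
  }
  p <- max(sum(perm_counts >= observed), 1L) / n_perm
  list(observed = observed, p = p, perm_counts = perm_counts)
}
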