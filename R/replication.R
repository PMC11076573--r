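#' Cross-cohort correlation of adjusted CMR effects
#'
#' Pearson correlation between discovery and replication `delta_beta_adj`
#' values over the given CMR ids (restricted to CMRs present in both tables,
#' i.e. covered on both platforms), with a two-sided p-value from the t
#' transform.
#'
#' @param discovery,replication `ewas_table` data frames.
#' @param ids CMR ids to compare (default: all shared ids).
#' @return list: `r`, `p`, `n` (pairs used).
#' @export
correlate_effects <- function(discovery, replication, ids = NULL) {
  shared <- intersect(discovery$cmr_id, replication$cmr_id)
  if (!is.null(ids)) shared <- intersect(ids, shared)
  if (length(shared) < 3) stop("need at least 3 shared CMRs")
  a <- discovery$delta_beta_adj[match(shared, discovery$cmr_id)]
  b <- replication$delta_beta_adj[match(shared, replication$cmr_id)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in effect estimates; correlation undefined")
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shared))
}

#' Sign concordance of effects between cohorts with a permutation null
#'
#' Reports the fraction of covered CMRs whose adjusted effects have the same
#' sign in both cohorts. The null is built by shuffling case-control labels in
#' the replication cohort, re-running its covariate-adjusted EWAS, and
#' recomputing the fraction; p = `#{permuted fraction >= observed} / n_perm`,
#' floored at `1/n_perm`. CMRs with an exactly zero effect in either table are
#' excluded from the fraction (and counted in `n_zero`).
#'
#' @param discovery discovery `ewas_table`.
#' @param replication replication `ewas_table`.
#' @param ids CMR ids to consider (default: all shared).
#' @param n_perm permutations (default 1000); requires `rep_data`.
#' @param seed integer seed.
#' @param rep_data optional list with the replication cohort's `cmr_matrix`,
#'   `table`, `weights`, `covariates` (and optionally `target`), needed to
#'   rebuild the null. Without it only the observed fraction is returned.
#' @return list: `fraction`, `n`, `n_zero`, and (with `rep_data`) `p`.
#' @export
sign_concordance <- function(discovery, replication, ids = NULL,
                             n_perm = 1000L, seed = 1L, rep_data = NULL) {
  shared <- intersect(discovery$cmr_id, replication$cmr_id)
  if (!is.null(ids)) shared <- intersect(ids, shared)
  if (length(shared) < 1) stop("need at least 1 shared CMR")
  frac_of <- function(rep_tab) {
    a <- discovery$delta_beta_adj[match(shared, discovery$cmr_id)]
    b <- rep_tab$delta_beta_adj[match(shared, rep_tab$cmr_id)]
    nz <- a != 0 & b != 0 & !is.na(b)
    list(fraction = mean(sign(a[nz]) == sign(b[nz])), n = sum(nz),
         n_zero = sum(!nz))
  }
  obs <- frac_of(replication)
  out <- list(fraction = obs$fraction, n = obs$n, n_zero = obs$n_zero)
  if (!is.null(rep_data)) {
    target <- rep_data$target %||% "case"
    set.seed(seed)
    perm <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      tb <- rep_data$table
      tb[[target]] <- sample(tb[[target]])
      et <- run_cmr_ewas(rep_data$cmr_matrix, tb, rep_data$weights, target,
                         rep_data$covariates)
      perm[b] <- frac_of(et)$fraction
    }
    out$p <- max(sum(perm >= obs$fraction), 1L) / n_perm
    out$perm_fractions <- perm
  }
  out
}

#' Call replicated CMRs
#'
#' A discovery hit replicates when it is covered in the replication cohort,
#' its adjusted effect there has the same sign as in discovery, and
#' `|delta_beta_adj| >= effect_thr` in the replication cohort. "Replicated
#' overall" means replicated in at least one replication cohort: pass a list
#' of tables to apply that rule.
#'
#' @param discovery_hits data frame with `cmr_id` and `delta_beta_adj` for the
#'   discovery hits (e.g. the hit rows of an `ewas_table`).
#' @param replication one `ewas_table` or a list of them.
#' @param effect_thr replication effect threshold (default 0.03).
#' @return data frame: `cmr_id`, `delta_disc`, and per-cohort columns
#'   `covered`, `delta_rep`, `same_sign`, `replicated`, plus `replicated_any`.
#' @export
call_replicated <- function(discovery_hits, replication, effect_thr = 0.03) {
  if (is.data.frame(replication)) replication <- list(rep1 = replication)
  if (is.null(names(replication)))
    names(replication) <- paste0("rep", seq_along(replication))
  out <- data.frame(cmr_id = discovery_hits$cmr_id,
                    delta_disc = discovery_hits$delta_beta_adj,
                    stringsAsFactors = FALSE)
  any_rep <- rep(FALSE, nrow(out))
  for (nm in names(replication)) {
    rt <- replication[[nm]]
    i <- match(out$cmr_id, rt$cmr_id)
    covered <- !is.na(i)
    delta_rep <- rt$delta_beta_adj[i]
    same_sign <- covered & !is.na(delta_rep) & delta_rep != 0 &
      sign(delta_rep) == sign(out$delta_disc)
    replicated <- same_sign & abs(delta_rep) >= effect_thr
    out[[paste0("covered_", nm)]] <- covered
    out[[paste0("delta_", nm)]] <- delta_rep
    out[[paste0("same_sign_", nm)]] <- same_sign
    out[[paste0("replicated_", nm)]] <- replicated
    any_rep <- any_rep | replicated
  }
  out$replicated_any <- any_rep
  out
}
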