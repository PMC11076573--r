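#' Split a binary exposure into recent and past components by lag time
#'
#' The median lag is computed (with linear interpolation) across the exposed
#' samples of the stratum. A sample is "recent" when exposed with lag strictly
#' below the median and "past" when exposed with lag at or above the median
#' (ties at the median count as past). Unexposed samples are (0, 0).
#'
#' @param exposure binary 0/1 vector.
#' @param lag_times per-sample lag (years since last use); must be non-missing
#'   for every exposed sample.
#' @return list of class `lag_split`: `recent`, `past` (0/1 vectors),
#'   `median_lag`.
#' @export
split_exposure_by_lag <- function(exposure, lag_times) {
  stopifnot(length(exposure) == length(lag_times), all(exposure %in% c(0, 1)))
  exposed <- exposure == 1
  if (!any(exposed)) stop("no exposed samples; lag split undefined")
  if (anyNA(lag_times[exposed])) stop("lag must be defined for all exposed samples")
  med <- stats::median(lag_times[exposed])
  recent <- as.integer(exposed & lag_times < med)
  past <- as.integer(exposed & lag_times >= med)
  structure(list(recent = recent, past = past, median_lag = med),
            class = "lag_split")
}

# Build an exposure panel in which each original exposure is replaced by its
# recent/past pair, imputation by imputation.
lag_split_panel <- function(panel) {
  out <- list()
  for (nm in names(panel$exposures)) {
    e <- panel$exposures[[nm]]
    m <- ncol(e$imputations)
    rec <- past <- matrix(0L, nrow(e$imputations), m)
    for (i in seq_len(m)) {
      if (!any(e$imputations[, i] == 1)) next
      sp <- split_exposure_by_lag(e$imputations[, i], e$lag)
      rec[, i] <- sp$recent
      past[, i] <- sp$past
    }
    colnames(rec) <- colnames(past) <- colnames(e$imputations)
    out[[paste0(nm, "_recent")]] <- list(name = paste0(nm, "_recent"),
                                         truth = NULL, lag = e$lag,
                                         imputations = rec)
    out[[paste0(nm, "_past")]] <- list(name = paste0(nm, "_past"),
                                       truth = NULL, lag = e$lag,
                                       imputations = past)
  }
  structure(list(exposures = out, sample_id = panel$sample_id, m = panel$m),
            class = "exposure_panel")
}

#' Re-run model selection with lag-split exposures
#'
#' Rebuilds the exposure panel, replacing each exposure with its recent and
#' past indicators (each entering the E, G+E, and GxE classes as a separate
#' exposure), re-runs [run_model_selection()] over the same CMRs, and reports
#' a stability summary against the original records.
#'
#' @param original result of [run_model_selection()] on the same CMRs.
#' @param min_prev eligibility threshold applied to the split exposures
#'   (default 0: the splits inherit eligibility from their parent exposure).
#' @inheritParams run_model_selection
#' @return list: `records`, `stability` (per CMR: same best class / SNP as the
#'   original), and `retained_class_fraction`.
#' @export
rerank_with_lag <- function(original, cmr_matrix, hit_ids, cmr_set, table,
                            weights, covariates, genotypes, snp_manifest,
                            panel, panel_subset = NULL, window_bp = 75000,
                            window_mode = "centered", min_prev = 0,
                            alpha = 0.05, target = "case") {
  split_panel <- lag_split_panel(panel)
  res <- run_model_selection(cmr_matrix, hit_ids, cmr_set, table, weights,
                             covariates, genotypes, snp_manifest, split_panel,
                             panel_subset = panel_subset, window_bp = window_bp,
                             window_mode = window_mode, min_prev = min_prev,
                             alpha = alpha, target = target)
  orig <- original$records
  new <- res$records
  i <- match(new$cmr_id, orig$cmr_id)
  stability <- data.frame(
    cmr_id = new$cmr_id,
    orig_class = orig$best_class[i],
    new_class = new$best_class,
    same_class = orig$best_class[i] == new$best_class,
    same_snp = (is.na(orig$snp_id[i]) & is.na(new$snp_id)) |
      (!is.na(orig$snp_id[i]) & !is.na(new$snp_id) &
         orig$snp_id[i] == new$snp_id),
    stringsAsFactors = FALSE)
  list(records = new, stability = stability,
       retained_class_fraction = mean(stability$same_class))
}

#' Levodopa-dosage association at hit CMRs
#'
#' Among treated cases with a levodopa daily dose (LED), fits per CMR the
#' robust regression `CMR median beta ~ LED + age + plate + cell-type PC1` and
#' BH-adjusts across the hit CMRs.
#'
#' @param cmr_matrix CMRs x samples matrix restricted (by `subset`) or already
#'   subset to treated cases with LED.
#' @param led LED values for those samples.
#' @param age,plate,cell_pc1 covariates for the same samples.
#' @param tuning,max_iter passed to [huber_wls()].
#' @return data frame: `cmr_id`, `led_coef`, `se`, `p`, `p_adj`.
#' @export
led_association <- function(cmr_matrix, led, age, plate, cell_pc1,
                            tuning = 1.345, max_iter = 2000L) {
  n <- ncol(cmr_matrix)
  stopifnot(length(led) == n, length(age) == n, length(cell_pc1) == n)
  if (n < 5) stop("need at least 5 treated cases with LED")
  if (stats::var(led) == 0) stop("LED is constant; association undefined")
  tab <- data.frame(led = led, age = age, plate = factor(plate),
                    cell_pc1 = cell_pc1)
  X <- stats::model.matrix(~ led + age + plate + cell_pc1, data = tab)
  ids <- rownames(cmr_matrix)
  est <- se <- p <- rep(NA_real_, length(ids))
  for (i in seq_along(ids)) {
    fit <- tryCatch(huber_wls(cmr_matrix[i, ], X, tuning = tuning,
                              max_iter = max_iter),
                    error = function(e) NULL)
    if (is.null(fit)) next
    est[i] <- fit$coefficients["led"]
    se[i] <- fit$se[match("led", colnames(X))]
    p[i] <- fit$p[match("led", colnames(X))]
  }
  ok <- !is.na(p)
  data.frame(cmr_id = ids[ok], led_coef = est[ok], se = se[ok], p = p[ok],
             p_adj = bh_adjust(p[ok]), stringsAsFactors = FALSE)
}
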