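#' Fit a probit propensity-score model
#'
#' Regresses the binary group label (disease status) on the matching
#' covariates with a probit-link GLM (fit by iteratively reweighted least
#' squares) and returns per-sample propensity scores.
#'
#' @param table data frame containing the group column and covariates.
#' @param vars character vector of covariate column names; no missing values
#'   allowed.
#' @param group_col name of the binary group column (default `"case"`).
#' @return list of class `propensity_fit`: `coefficients`, `scores` (in
#'   (0,1), named by `sample_id` when present), `converged`, and the fitted
#'   `glm` object.
#' @export
fit_propensity <- function(table, vars, group_col = "case") {
  if (!group_col %in% names(table)) stop("group column not found")
  g <- table[[group_col]]
  if (!all(g %in% c(0, 1))) stop("group label must be binary 0/1")
  missing_vars <- setdiff(vars, names(table))
  if (length(missing_vars))
    stop(sprintf("covariate(s) not found: %s", paste(missing_vars, collapse = ", ")))
  sub <- table[, vars, drop = FALSE]
  if (anyNA(sub) || anyNA(g)) stop("missing values in matching covariates or group")
  dat <- cbind(.group = g, sub)
  fml <- stats::as.formula(paste(".group ~", paste(vars, collapse = " + ")))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = dat, family = stats::binomial(link = "probit")),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  scores <- stats::fitted(fit)
  eps <- 1e-8
  if (sep_warn || !fit$converged ||
      all(scores[g == 1] > 1 - eps) || all(scores[g == 0] < eps))
    stop("propensity model shows (quasi-)separation; review the matching covariates")
  scores <- pmin(pmax(scores, eps), 1 - eps)
  if ("sample_id" %in% names(table)) names(scores) <- table$sample_id
  structure(list(coefficients = stats::coef(fit), scores = scores,
                 converged = fit$converged, link = "probit", glm = fit),
            class = "propensity_fit")
}

#' Full-matching weights from propensity scores
#'
#' Units with no opposite-group unit within the caliper (by default 0.2
#' standard deviations of the logit propensity score) are trimmed to weight
#' zero. Remaining units are partitioned into matched sets, each containing at
#' least one treated and one control unit, by assigning every control to its
#' nearest treated unit on the logit-score scale (treated units left without
#' controls join the set of their nearest matched control). Treated units keep
#' weight 1; a control's weight is the treated:control ratio of its set,
#' rescaled so total control weight equals the number of matched controls.
#'
#' @param scores propensity scores in (0,1) (e.g. from [fit_propensity()]).
#' @param group binary treated indicator (1 = treated/case).
#' @param caliper caliper width (default 0.2).
#' @param caliper_scale `"logit"` (default: width is `caliper * sd(logit
#'   score)`) or `"probability"` (raw score scale).
#' @return data frame of class `weight_vector` with columns `sample_id`
#'   (names of `scores`, or index), `set_id` (0 = trimmed), `weight`.
#' @export
full_match_weights <- function(scores, group, caliper = 0.2,
                               caliper_scale = c("logit", "probability")) {
  caliper_scale <- match.arg(caliper_scale)
  n <- length(scores)
  stopifnot(length(group) == n, all(group %in% c(0, 1)))
  if (!any(group == 1) || !any(group == 0)) stop("both groups must be present")
  ids <- names(scores) %||% as.character(seq_len(n))
  # normalize processing order for deterministic tie-breaking
  ord <- order(ids)
  x <- if (caliper_scale == "logit") stats::qlogis(scores) else scores
  width <- if (stats::sd(x) > 0) caliper * stats::sd(x) else Inf

  treated <- which(group == 1)
  control <- which(group == 0)
  # trim units farther than the caliper from every opposite-group unit
  min_dist_to <- function(from, to) {
    vapply(from, function(i) min(abs(x[i] - x[to])), 0)
  }
  keep_t <- treated[min_dist_to(treated, control) <= width]
  keep_c <- control[min_dist_to(control, treated) <= width]
  if (!length(keep_t) || !length(keep_c))
    stop("no overlap between groups within the caliper")

  set_of <- integer(n)  # 0 = trimmed/unmatched
  # deterministic: process controls in sample-id order; nearest treated wins,
  # ties to the smaller sample id
  keep_t_sorted <- keep_t[order(ids[keep_t])]
  for (ci in keep_c[order(ids[keep_c])]) {
    d <- abs(x[ci] - x[keep_t_sorted])
    set_of[ci] <- keep_t_sorted[which.min(d)]
  }
  for (ti in keep_t_sorted) set_of[ti] <- ti
  # treated with no controls join their nearest matched control's set
  counts <- table(factor(set_of[keep_c], levels = keep_t_sorted))
  empty <- keep_t_sorted[counts == 0]
  for (ti in empty[order(ids[empty])]) {
    d <- abs(x[ti] - x[keep_c])
    set_of[ti] <- set_of[keep_c[which.min(d)]]
  }

  weight <- numeric(n)
  sets <- unique(set_of[set_of > 0])
  set_id <- integer(n)
  for (k in seq_along(sets)) {
    mem <- which(set_of == sets[k])
    set_id[mem] <- k
    tr <- mem[group[mem] == 1]; co <- mem[group[mem] == 0]
    weight[tr] <- 1
    weight[co] <- length(tr) / length(co)
  }
  matched_c <- which(group == 0 & weight > 0)
  if (length(matched_c))
    weight[matched_c] <- weight[matched_c] * length(matched_c) / sum(weight[matched_c])
  structure(data.frame(sample_id = ids, set_id = set_id, weight = weight,
                       stringsAsFactors = FALSE),
            class = c("weight_vector", "data.frame"))
}

#' Standardized mean difference
#'
#' `(mean1 - mean2) / sqrt((s1^2 + s2^2) / 2)`; the weighted variant uses
#' weighted means and (reliability-weighted) variances.
#'
#' @param x numeric covariate.
#' @param group binary indicator; group 1 minus group 0.
#' @param weights optional non-negative weights.
#' @return signed SMD.
#' @export
smd <- function(x, group, weights = NULL) {
  stopifnot(length(x) == length(group), all(group %in% c(0, 1)))
  if (is.null(weights)) weights <- rep(1, length(x))
  wm <- function(v, w) sum(w * v) / sum(w)
  wv <- function(v, w) {
    w <- w / sum(w)
    m <- sum(w * v)
    sum(w * (v - m)^2) / (1 - sum(w^2))
  }
  i1 <- group == 1 & weights > 0; i0 <- group == 0 & weights > 0
  if (!any(i1) || !any(i0)) stop("both groups must have positive weight")
  m1 <- wm(x[i1], weights[i1]); m0 <- wm(x[i0], weights[i0])
  s2 <- (wv(x[i1], weights[i1]) + wv(x[i0], weights[i0])) / 2
  if (s2 <= 0) stop("zero pooled SD; SMD undefined")
  (m1 - m0) / sqrt(s2)
}

#' Covariate balance report before and after weighting
#'
#' @param table sample table.
#' @param vars covariates to report.
#' @param weights a `weight_vector` (or numeric weights).
#' @param group_col binary group column (default `"case"`).
#' @return data frame: variable, `smd_before`, `smd_after`.
#' @export
balance_report <- function(table, vars, weights, group_col = "case") {
  w <- if (is.data.frame(weights)) weights$weight else weights
  g <- table[[group_col]]
  safe_smd <- function(v, weights = NULL) {
    tryCatch(smd(as.numeric(table[[v]]), g, weights),
             error = function(e) NA_real_)  # degenerate covariate in a group
  }
  data.frame(
    variable = vars,
    smd_before = vapply(vars, safe_smd, 0),
    smd_after = vapply(vars, function(v) safe_smd(v, w), 0),
    row.names = NULL)
}
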