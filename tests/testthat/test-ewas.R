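test_that("huber_wls with infinite tuning equals closed-form weighted least squares", {
  td <- toy_design()
  set.seed(71)
  w <- runif(td$n, 0.2, 3)
  fit <- huber_wls(td$y, td$X, case_weights = w, tuning = Inf)
  # normal-equations oracle
  oracle <- unname(drop(solve(t(td$X) %*% (td$X * w), t(td$X) %*% (w * td$y))))
  expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-10)
  # gaussian data without outliers: default tuning agrees with WLS closely
  fit2 <- huber_wls(td$y, td$X, case_weights = w)
  expect_lt(max(abs(unname(fit2$coefficients) - oracle)), 0.05)
})

test_that("huber_wls agrees with an independent robust-regression implementation", {
  td <- toy_design(n = 80, seed = 72)
  y <- td$y
  y[5] <- y[5] + 4  # a genuine outlier
  fit <- huber_wls(y, td$X)
  ref <- MASS::rlm(td$X, y, k = 1.345, maxit = 150, scale.est = "MAD")
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-4)
})

test_that("a gross outlier pulls Huber less than it pulls OLS", {
  set.seed(73)
  n <- 50
  x <- rnorm(n)
  y <- 1 + 0.8 * x + rnorm(n, 0, 0.3)
  X <- cbind(1, x)
  clean_slope <- coef(lm(y ~ x))[2]
  y_out <- y
  y_out[1] <- y_out[1] + 30  # > 10 sigma
  contaminated_slope <- coef(lm(y_out ~ x))[2]
  huber_slope <- huber_wls(y_out, X)$coefficients[2]
  expect_lt(abs(huber_slope - clean_slope), abs(contaminated_slope - clean_slope))
})

test_that("exact linear responses are fit exactly for any tuning", {
  set.seed(74)
  X <- cbind(1, rnorm(30))
  y <- 2 - 3 * X[, 2]
  for (k in c(0.5, 1.345, Inf)) {
    fit <- huber_wls(y, X, tuning = k)
    expect_equal(unname(fit$coefficients), c(2, -3), tolerance = 1e-10)
    expect_lt(max(abs(fit$residuals)), 1e-10)
    expect_true(fit$converged)
  }
})

test_that("rank deficiency and undersized designs raise errors", {
  set.seed(75)
  X <- cbind(1, 1:20, 2 * (1:20))
  expect_error(huber_wls(rnorm(20), X), "rank deficient")
  expect_error(huber_wls(rnorm(3), cbind(1, rnorm(3), rnorm(3), rnorm(3))),
               "effective sample size")
})

test_that("bh_adjust matches the step-up procedure and validates input", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  # order invariance
  p <- c(0.04, 0.001, 0.2, 0.8, 0.01)
  o <- sample(5)
  expect_equal(bh_adjust(p)[o], bh_adjust(p[o]))
  expect_error(bh_adjust(c(0.1, NA)), "NA")
  expect_error(bh_adjust(c(0.1, 1.2)), "0,1")
})

test_that("hit calling applies both thresholds", {
  tab <- data.frame(cmr_id = c("a", "b", "c"),
                    delta_beta_adj = c(0.05, 0.02, 0.10),
                    p = c(0.001, 0.001, 0.02),
                    p_adj = c(0.04, 0.04, 0.06))
  expect_equal(call_hits(tab), "a")
})

test_that("a planted case-control shift is recovered at the planted size", {
  # +0.08 planted at CMRs 1-5; estimates within [0.06, 0.10] and hits called
  b <- planted_pd_bundle()
  res <- run_stratum_ewas(b)
  planted <- sprintf("CMR%05d", 1:5)
  est <- res$ewas$delta_beta_adj[match(planted, res$ewas$cmr_id)]
  expect_true(all(abs(est - 0.08) < 0.03))
  expect_lt(abs(mean(est) - 0.08), 0.01)
  expect_true(all(planted %in% res$hits))
})

test_that("p-values are approximately uniform when labels carry no signal", {
  # three independent null cohorts; the sandwich variance is mildly
  # conservative in the extreme tail, so uniformity is required to hold for
  # the majority of cohorts and the rejection rate must stay nominal
  ks_p <- frac <- numeric(3)
  for (i in 1:3) {
    b <- simulate_cohort(sim_config(n_samples = 100L,
                                    cmr_layout = cmr_layout(500, 3),
                                    n_probes = 1700L, n_snps = 0L,
                                    seed = 400L + i))
    res <- run_stratum_ewas(b)
    ks_p[i] <- suppressWarnings(ks.test(res$ewas$p, "punif"))$p.value
    frac[i] <- mean(res$ewas$p <= 0.05)
    expect_length(res$hits, 0L)
  }
  expect_gte(sum(ks_p > 0.01), 2)
  expect_gt(mean(frac), 0.03)
  expect_lt(mean(frac), 0.07)
})

test_that("failed CMRs are dropped from results and the BH denominator", {
  b <- small_null_bundle()
  res <- run_stratum_ewas(b)
  cm <- res$cmr_matrix
  cm <- rbind(cm, bad = rep(c(NA_real_, 0.5), length.out = ncol(cm)))
  ew <- run_cmr_ewas(cm, res$table, res$weights, covariates = res$covariates)
  expect_false("bad" %in% ew$cmr_id)
  expect_true("bad" %in% attr(ew, "excluded_ids"))
  expect_gte(attr(ew, "n_excluded"), 1L)
  # BH recomputed over the fitted rows only
  expect_equal(ew$p_adj, bh_adjust(ew$p))
})

test_that("permutation enrichment floors at 1/n_perm and is 1 for zero observed hits", {
  b <- small_null_bundle()
  res <- run_stratum_ewas(b)
  pe <- permutation_enrichment(res$cmr_matrix[1:10, ], res$table, res$weights,
                               covariates = res$covariates, n_perm = 20,
                               seed = 81)
  expect_equal(pe$observed, 0L)
  expect_equal(pe$p, 1)
  expect_error(permutation_enrichment(res$cmr_matrix, res$table, res$weights,
                                      covariates = res$covariates, n_perm = 0),
               "n_perm")
})
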