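snp_fixture <- function() {
  data.frame(snp_id = sprintf("rs%02d", 1:6), chrom = c(rep("chr1", 5), "chr2"),
             pos = c(100000, 130000, 137000, 137501, 200000, 100000),
             stringsAsFactors = FALSE)
}

test_that("snp_window boundaries match the stated conventions", {
  cmr <- list(chrom = "chr1", start = 99000, end = 101000)  # midpoint 100000
  man <- snp_fixture()
  # centered, 75 kb total width: cutoff at +/- 37500
  got <- snp_window(cmr, man, width_bp = 75000, mode = "centered")
  expect_true("rs01" %in% got)               # at the midpoint
  expect_true("rs03" %in% got)               # +37000 included
  expect_false("rs04" %in% got)              # +37501 excluded
  expect_false("rs06" %in% got)              # other chromosome
  # flank mode reaches width_bp beyond the interval
  gotf <- snp_window(cmr, man, width_bp = 75000, mode = "flank")
  expect_true(all(c("rs01", "rs02", "rs03", "rs04") %in% gotf))
  expect_false("rs05" %in% gotf)             # 200000 > 101000 + 75000? no: 176000 < 200000
  # random manifests vs brute-force distance scan
  set.seed(111)
  for (i in 1:20) {
    man2 <- data.frame(snp_id = sprintf("s%03d", 1:50),
                       chrom = sample(c("chr1", "chr2"), 50, TRUE),
                       pos = sample.int(3e5, 50))
    cmr2 <- list(chrom = "chr1", start = 120000, end = 125000)
    mid <- (cmr2$start + cmr2$end) / 2
    brute <- man2$snp_id[man2$chrom == "chr1" & abs(man2$pos - mid) <= 37500]
    expect_equal(snp_window(cmr2, man2), brute)
    brutef <- man2$snp_id[man2$chrom == "chr1" & man2$pos >= cmr2$start - 75000 &
                            man2$pos <= cmr2$end + 75000]
    expect_equal(snp_window(cmr2, man2, mode = "flank"), brutef)
  }
})

test_that("exposure eligibility uses mean prevalence across imputations, inclusive", {
  mk_panel <- function(prev) {
    im <- matrix(0L, 40, 4)
    for (j in 1:4) im[seq_len(round(prev * 40)), j] <- 1L
    structure(list(exposures = list(e1 = list(name = "e1", imputations = im)),
                   sample_id = sprintf("s%02d", 1:40), m = 4L),
              class = "exposure_panel")
  }
  expect_equal(eligible_exposures(mk_panel(0.10)), "e1")   # exactly 10%: eligible
  expect_equal(eligible_exposures(mk_panel(0.05)), character(0))
})

test_that("Rubin pooling matches hand-evaluated formulas on an m = 2 toy", {
  # estimates 0.4, 0.6 with variances 0.01, 0.02
  got <- pool_rubin(c(0.4, 0.6), c(0.01, 0.02))
  expect_equal(got$estimate, 0.5)
  U <- 0.015
  B <- var(c(0.4, 0.6))          # 0.02
  expect_equal(got$within, U)
  expect_equal(got$between, B)
  expect_equal(got$variance, U + 1.5 * B)
  expect_equal(got$df, (2 - 1) * (1 + U / (1.5 * B))^2)
  # identical imputations: zero between-variance, single-fit equivalence
  same <- pool_rubin(c(0.3, 0.3, 0.3), c(0.01, 0.01, 0.01))
  expect_equal(same$estimate, 0.3)
  expect_equal(same$between, 0)
  expect_equal(same$variance, 0.01)
  expect_equal(same$df, Inf)
  # m = 1 equals the single fit exactly
  one <- pool_rubin(0.7, 0.02)
  expect_equal(one$estimate, 0.7)
  expect_equal(one$variance, 0.02)
})

test_that("fit_and_pool with identical imputations equals the single fit", {
  b <- small_null_bundle()
  res <- run_stratum_ewas(b)
  d <- methgxe:::build_design(res$table, "case", res$covariates)
  w <- methgxe:::resolve_weights(res$weights, res$table)
  y <- res$cmr_matrix[1, ]
  # panel whose copies are all identical
  e <- b$exposures$exposures$gardening$truth
  panel <- structure(list(exposures = list(gardening = list(
    name = "gardening", imputations = matrix(rep(e, 3), ncol = 3))),
    sample_id = b$samples$sample_id, m = 3L), class = "exposure_panel")
  pooled <- fit_and_pool(y, d$X, model_spec("E", exposure = "gardening"),
                         panel = panel, weights = w)
  single <- huber_wls(y, cbind(d$X, E = e), case_weights = w,
                      max_iter = 2000L)
  expect_equal(unname(pooled$coef["E"]),
               unname(single$coefficients["E"]), tolerance = 1e-12)
  expect_equal(pooled$aic, single$aic, tolerance = 1e-12)
  # degenerate specs are skipped, not errors
  geno0 <- matrix(1, 1, length(y), dimnames = list("rsX", NULL))
  expect_null(fit_and_pool(y, d$X, model_spec("G", snp_id = "rsX"),
                           genotypes = geno0, weights = w))
})

test_that("empty grids select the base model with zero change", {
  b <- small_null_bundle()
  res <- run_stratum_ewas(b)
  # no SNP manifest entries anywhere near, prevalence bar too high
  sel <- run_model_selection(res$cmr_matrix, res$ewas$cmr_id[1], res$cmr_set,
                             res$table, res$weights, res$covariates,
                             b$genotypes,
                             data.frame(snp_id = "rs1", chrom = "chrZ", pos = 1L),
                             b$exposures, min_prev = 0.99)
  expect_equal(sel$records$best_class, "BASE")
  expect_equal(sel$records$daic_vs_base, 0)
  expect_equal(pd_effect_change(sel$records[1, ]), 0)
  expect_false(sel$records$improved)
})

test_that("AIC ranking is invariant to adding a constant to the response", {
  b <- small_null_bundle()
  res <- run_stratum_ewas(b)
  d <- methgxe:::build_design(res$table, "case", res$covariates)
  w <- methgxe:::resolve_weights(res$weights, res$table)
  y <- res$cmr_matrix[2, ]
  g <- as.numeric(b$genotypes[1, ])
  a1 <- huber_wls(y, cbind(d$X, G = g), case_weights = w)$aic -
    huber_wls(y, d$X, case_weights = w)$aic
  a2 <- huber_wls(y + 5, cbind(d$X, G = g), case_weights = w)$aic -
    huber_wls(y + 5, d$X, case_weights = w)$aic
  expect_equal(a1, a2, tolerance = 1e-4)
})

test_that("a planted genotype effect selects a G-class model", {
  classes <- vapply(1:12, function(s) {
    cfg <- sim_config(n_samples = 100L, cmr_layout = cmr_layout(20, 3),
                      n_probes = 100L, n_snps = 4L,
                      effects = list(effect_spec(1, "G", 0.05, snp_index = 1),
                                     effect_spec(1, "PD", 0.05)),
                      seed = 800L + s)
    b <- simulate_cohort(cfg)
    r <- run_stratum_ewas(b)
    sel <- run_model_selection(r$cmr_matrix, "CMR00001", r$cmr_set, r$table,
                               r$weights, r$covariates, b$genotypes,
                               b$snp_manifest, b$exposures)
    sel$records$best_class[1]
  }, "")
  expect_gt(mean(classes == "G"), 0.5)
  expect_true(all(classes %in% c("G", "G_plus_E", "GxE")))
})

test_that("orthogonal added terms leave the disease effect nearly unchanged", {
  set.seed(112)
  n <- 200
  case <- rep(c(1, 0), each = n / 2)
  g <- rbinom(n, 2, 0.3)          # independent of case by construction
  y <- 0.4 + 0.05 * case + 0.02 * g + rnorm(n, 0, 0.03)
  X0 <- cbind(1, case = case)
  f0 <- huber_wls(y, X0)
  f1 <- huber_wls(y, cbind(X0, G = g))
  expect_lt(abs(abs(f1$coefficients["case"]) - abs(f0$coefficients["case"])),
            0.01)
})

test_that("gwas proximity equals a brute-force scan including boundaries", {
  man <- data.frame(snp_id = c("a", "b", "c"), chrom = c("chr1", "chr1", "chr2"),
                    pos = c(5e6, 9e6, 5e6))
  hits <- data.frame(chrom = "chr1", pos = c(5e6, 10000001 + 1e6))
  got <- gwas_proximity(c("a", "b", "c"), man, hits)
  expect_equal(unname(got), c(TRUE, FALSE, FALSE))  # b: nearest 1,000,001 away? 11,000,001-9e6=2,000,001 & 5e6: 4e6 -> FALSE
  # exact boundary: hit exactly window_bp away counts
  hits2 <- data.frame(chrom = "chr1", pos = 6e6)
  expect_true(gwas_proximity("a", man, hits2, window_bp = 1e6)[[1]])
  expect_false(gwas_proximity("a", man, hits2, window_bp = 1e6 - 1)[[1]])
  # random lists vs brute force
  set.seed(113)
  man2 <- data.frame(snp_id = sprintf("s%02d", 1:30),
                     chrom = sample(c("chr1", "chr2"), 30, TRUE),
                     pos = sample.int(5e6, 30))
  h2 <- data.frame(chrom = sample(c("chr1", "chr2"), 10, TRUE),
                   pos = sample.int(5e6, 10))
  got2 <- gwas_proximity(man2$snp_id, man2, h2, window_bp = 5e5)
  brute <- vapply(seq_len(30), function(i)
    any(h2$chrom == man2$chrom[i] & abs(h2$pos - man2$pos[i]) <= 5e5), TRUE)
  expect_equal(unname(got2), brute)
})

test_that("null cohorts rarely flag improved models", {
  frac <- vapply(1:10, function(s) {
    cfg <- sim_config(n_samples = 100L, cmr_layout = cmr_layout(12, 3),
                      n_probes = 60L, n_snps = 4L, seed = 900L + s)
    b <- simulate_cohort(cfg)
    r <- run_stratum_ewas(b, apply_filter = FALSE)
    ids <- r$ewas$cmr_id[1:4]
    sel <- run_model_selection(r$cmr_matrix, ids, r$cmr_set, r$table, r$weights,
                               r$covariates, b$genotypes, b$snp_manifest,
                               b$exposures)
    if (!nrow(sel$records)) return(0)
    mean(sel$records$improved)
  }, 0)
  expect_lt(mean(frac), 0.10)
})
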