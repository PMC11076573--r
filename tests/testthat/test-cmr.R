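test_that("adjacent-pair rules link and break as specified", {
  set.seed(61)
  x <- runif(10)
  # two identical probes 500 bp apart -> one CMR of 2 probes
  fx <- chain_fixture(rbind(x, x), c(1000, 1500))
  cs <- call_cmrs(fx$beta, fx$manifest)
  expect_equal(nrow(cs$regions), 1L)
  expect_equal(cs$regions$n_probes, 2L)
  expect_equal(cmr_length(cs$regions[1, ]), 500L)
  # perfectly correlated but 1500 bp apart -> no CMR
  fx2 <- chain_fixture(rbind(x, x), c(1000, 2500))
  expect_equal(nrow(call_cmrs(fx2$beta, fx2$manifest)$regions), 0L)
  # a constant probe breaks the chain without an exception
  fx3 <- chain_fixture(rbind(x, rep(0.5, 10), x), c(1000, 1400, 1800))
  cs3 <- call_cmrs(fx3$beta, fx3$manifest)
  expect_equal(nrow(cs3$regions), 0L)
  expect_gte(attr(cs3, "n_undefined_pairs"), 1L)
  # different chromosomes never link
  fx4 <- chain_fixture(rbind(x, x), c(1000, 1200), chrom = c("chr1", "chr2"))
  expect_equal(nrow(call_cmrs(fx4$beta, fx4$manifest)$regions), 0L)
})

test_that("segmentation equals the exhaustive adjacent-pair oracle on random instances", {
  set.seed(62)
  for (rep in 1:100) {
    np <- sample(4:9, 1)
    n <- sample(c(5, 8, 12), 1)
    pos <- cumsum(sample(c(200, 600, 1400), np, replace = TRUE))
    beta <- matrix(runif(np * n), np)
    # induce some correlated neighbours
    for (i in seq_len(np - 1)) if (runif(1) < 0.5) beta[i + 1, ] <- beta[i, ] + rnorm(n, 0, 0.1)
    fx <- chain_fixture(beta, pos)
    got <- call_cmrs(fx$beta, fx$manifest)
    want <- oracle_cmr_segments(fx$beta, fx$manifest)
    expect_equal(unname(got$probes), want, info = paste("rep", rep))
  }
})

test_that("calling is invariant to sample order and monotone transforms", {
  b <- small_null_bundle()
  sub <- b$manifest$probe_id[1:30]
  beta <- b$beta[sub, ]
  man <- b$manifest[b$manifest$probe_id %in% sub, ]
  ref <- call_cmrs(beta, man)
  perm <- sample(ncol(beta))
  expect_equal(call_cmrs(beta[, perm], man)$probes, ref$probes)
  expect_equal(call_cmrs(qlogis(beta), man)$probes, ref$probes)
})

test_that("median summarization matches a sort-and-pick oracle", {
  # hand cases
  fx <- chain_fixture(matrix(c(0.2, 0.4), 2, 1), c(100, 200))
  cs <- new_cmr_set(data.frame(cmr_id = "c1", chrom = "chr1", start = 100,
                               end = 200, n_probes = 2),
                    list(c1 = c("cg001", "cg002")))
  expect_equal(as.numeric(summarize_cmr_beta(fx$beta, cs)), 0.3)
  fx3 <- chain_fixture(matrix(c(0.1, 0.5, 0.9), 3, 1), c(100, 200, 300))
  cs3 <- new_cmr_set(data.frame(cmr_id = "c1", chrom = "chr1", start = 100,
                                end = 300, n_probes = 3),
                     list(c1 = paste0("cg00", 1:3)))
  expect_equal(as.numeric(summarize_cmr_beta(fx3$beta, cs3)), 0.5)
  # random 5-probe CMR vs independent sort-based median
  set.seed(63)
  vals <- matrix(runif(5 * 9), 5)
  fx5 <- chain_fixture(vals, seq(100, 500, by = 100))
  cs5 <- new_cmr_set(data.frame(cmr_id = "c1", chrom = "chr1", start = 100,
                                end = 500, n_probes = 5),
                     list(c1 = rownames(fx5$beta)))
  oracle <- apply(vals, 2, function(v) {
    s <- sort(v); k <- length(s)
    if (k %% 2 == 1) s[(k + 1) / 2] else (s[k / 2] + s[k / 2 + 1]) / 2
  })
  expect_equal(as.numeric(summarize_cmr_beta(fx5$beta, cs5)), oracle)
  # missing probe errors with the CMR named
  expect_error(summarize_cmr_beta(fx5$beta[1:3, ], cs5), "c1")
})

test_that("variability filter uses a strict 10th-90th percentile range rule", {
  n <- 100
  set.seed(64)
  m <- rbind(constant = rep(0.4, n),
             uniform = runif(n),
             boundary = rep(c(0.40, 0.45), each = n / 2))
  # boundary row: 10-90 range exactly 0.05 -> removed (strict >)
  expect_equal(unname(quantile(m["boundary", ], 0.9) - quantile(m["boundary", ], 0.1)),
               0.05)
  kept <- variability_filter(m)
  expect_equal(kept, "uniform")  # uniform 10-90 range ~0.8 retained
  expect_error(variability_filter(m[, 1, drop = FALSE]), "2 samples")
})

test_that("summarize-then-filter is idempotent on the retained set", {
  b <- planted_pd_bundle()
  cm <- summarize_cmr_beta(b$beta, b$cmr_set)
  keep <- variability_filter(cm)
  cm2 <- cm[keep, , drop = FALSE]
  expect_identical(variability_filter(cm2), keep)
})

test_that("printed CMR length convention is end minus start", {
  # worked examples from published region tables
  expect_equal(cmr_length(list(start = 57630202, end = 57630662)), 460L)
  expect_equal(cmr_length(list(start = 32294470, end = 32295230)), 760L)
  expect_equal(cmr_length(list(start = 100, end = 101)), 1L)
})

test_that("reference overlap equals a brute-force probe-intersection oracle", {
  b <- small_null_bundle()
  cs <- b$cmr_set
  half <- subset_cmr_set(cs, cs$regions$cmr_id[1:25])
  expect_equal(reference_overlap(cs, cs)$fraction, 1.0)
  expect_equal(reference_overlap(half, cs)$fraction, 0.5)
  # disjoint sets
  other <- subset_cmr_set(cs, cs$regions$cmr_id[26:50])
  expect_equal(reference_overlap(half, other)$fraction, 0.0)
  # random query vs brute force
  set.seed(65)
  q <- subset_cmr_set(cs, sample(cs$regions$cmr_id, 12))
  qp <- unique(unlist(q$probes))
  brute <- mean(vapply(cs$probes, function(p) length(intersect(p, qp)) > 0, TRUE))
  expect_equal(reference_overlap(q, cs)$fraction, brute)
  expect_error(reference_overlap(q, new_cmr_set(cs$regions[0, ], list())),
               "nonempty")
})

test_that("CMRs never span chromosomes and probe sets are disjoint", {
  b <- planted_pd_bundle()
  cs <- call_cmrs(b$beta, b$manifest)
  expect_gt(nrow(cs$regions), 0)
  for (id in cs$regions$cmr_id) {
    pr <- cs$probes[[id]]
    chroms <- b$manifest$chrom[match(pr, b$manifest$probe_id)]
    expect_equal(length(unique(chroms)), 1L)
  }
  all_probes <- unlist(cs$probes)
  expect_equal(anyDuplicated(all_probes), 0L)
})
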