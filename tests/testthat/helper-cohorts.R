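# Shared fixture builders. Everything is generated in code at test time;
# bundles used by several files are cached per session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small null cohort: 50 CMRs x 3 probes, n = 60, no planted effects
small_null_bundle <- function() {
  cached("small_null", function() {
    simulate_cohort(sim_config(n_samples = 60L, cmr_layout = cmr_layout(50, 3),
                               n_probes = 200L, n_snps = 6L, seed = 401L))
  })
}

# cohort with planted PD effects at CMRs 1-5
planted_pd_bundle <- function() {
  cached("planted_pd", function() {
    eff <- lapply(1:5, function(i) effect_spec(i, "PD", 0.08))
    simulate_cohort(sim_config(n_samples = 120L, cmr_layout = cmr_layout(60, 3),
                               n_probes = 250L, n_snps = 6L, effects = eff,
                               seed = 402L))
  })
}

# deterministic tiny design matrix for regression tests
toy_design <- function(n = 40, seed = 7) {
  set.seed(seed)
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  y <- 0.3 + 0.5 * X[, "x1"] - 0.25 * X[, "x2"] + rnorm(n, 0, 0.4)
  list(y = y, X = X, n = n)
}

# beta matrix + manifest for a hand-specified probe chain
chain_fixture <- function(values, positions, chrom = "chr1",
                          probe_ids = sprintf("cg%03d", seq_along(positions))) {
  stopifnot(nrow(values) == length(positions))
  rownames(values) <- probe_ids
  list(beta = values,
       manifest = data.frame(probe_id = probe_ids, chrom = chrom,
                             pos = positions, stringsAsFactors = FALSE))
}

# independent oracle for call_cmrs: test every adjacent pair on its own and
# chain maximal runs
oracle_cmr_segments <- function(beta, manifest, min_corr = 0.3, max_gap = 1000) {
  o <- order(manifest$chrom, manifest$pos)
  m <- manifest[o, ]
  b <- beta[m$probe_id, , drop = FALSE]
  np <- nrow(b)
  linked <- logical(max(np - 1, 0))
  for (i in seq_len(np - 1)) {
    if (m$chrom[i] != m$chrom[i + 1]) next
    if (m$pos[i + 1] - m$pos[i] > max_gap) next
    if (stats::sd(b[i, ]) == 0 || stats::sd(b[i + 1, ]) == 0) next
    rho <- suppressWarnings(stats::cor(b[i, ], b[i + 1, ], method = "spearman"))
    if (is.finite(rho) && rho >= min_corr) linked[i] <- TRUE
  }
  segs <- list()
  i <- 1
  while (i < np) {
    if (linked[i]) {
      j <- i
      while (j < np && linked[j]) j <- j + 1
      segs[[length(segs) + 1]] <- m$probe_id[i:j]
      i <- j + 1
    } else i <- i + 1
  }
  segs
}
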