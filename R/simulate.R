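#' Simulation configuration for a synthetic methylation cohort
#'
#' Builds and validates the configuration consumed by [simulate_cohort()]. The
#' defaults mirror the female arm of an agricultural case-control design:
#' 100 samples at 33% case fraction, co-methylated regions (CMRs) of 3 probes
#' each, three binary pesticide exposures observed through 10 imputations, and
#' small additive plate/row batch shifts. Planted disease, genotype, and
#' exposure effects are specified with [effect_spec()] and recorded in a ground
#' truth table so recovery can be scored downstream.
#'
#' @param n_samples number of samples.
#' @param case_fraction proportion of cases in (0,1). Without a `case_logit`
#'   model, exactly `round(n_samples * case_fraction)` cases are drawn.
#' @param n_probes total probes; probes not used by `cmr_layout` become
#'   isolated singletons.
#' @param cmr_layout data frame with columns `probe_count` (>= 2), `corr`
#'   (target within-CMR correlation in \[0,1\]) and `gap_bp` (inter-probe gap).
#'   See [cmr_layout()].
#' @param n_snps number of independent SNPs, placed in cis of CMRs.
#' @param maf_range minor-allele-frequency interval within (0, 0.5\].
#' @param exposures list of exposure definitions: each a list with `name`,
#'   `prevalence`, and lognormal lag-time parameters `lag_meanlog`,
#'   `lag_sdlog` (years since last use).
#' @param m_imputations imputed copies of each exposure (default 10).
#' @param missing_rate fraction of exposure entries subject to imputation.
#' @param imputation_flip_rate per-copy disagreement rate of imputed entries
#'   with the underlying truth.
#' @param effects list of [effect_spec()] objects.
#' @param noise_sd beta-scale standard deviation of independent probe noise.
#' @param latent_sd logit-scale SD of the shared biological variation (the
#'   per-CMR latent factor plus probe-specific deviations). The default 0.2
#'   gives per-probe beta SDs of roughly 0.03-0.05 and CMR-median standard
#'   errors near 0.007-0.01 at n = 100, the scale seen in real blood
#'   region-based EWAS summary statistics.
#' @param n_plates,n_rows batch level counts; `batch_sd` is the SD of the
#'   additive per-level mean shift on beta (default 0.005).
#' @param batch_sd see above.
#' @param female_fraction fraction of samples assigned female sex.
#' @param case_logit optional named numeric vector of log-odds loadings of
#'   case status on covariates (`age`, `smoking`, `alcohol`, `head_trauma`),
#'   exposure names, or SNPs (`snp1`, `snp2`, ...); used to build confounded
#'   cohorts.
#' @param seed integer seed; identical config + seed reproduces the bundle
#'   bit-for-bit.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 100L,
                       case_fraction = 0.33,
                       n_probes = 700L,
                       cmr_layout = methgxe::cmr_layout(200L, 3L, 0.5, 150L),
                       n_snps = 50L,
                       maf_range = c(0.05, 0.5),
                       exposures = default_exposures(),
                       m_imputations = 10L,
                       missing_rate = 0.1,
                       imputation_flip_rate = 0.1,
                       effects = list(),
                       noise_sd = 0.03,
                       latent_sd = 0.2,
                       n_plates = 2L,
                       n_rows = 8L,
                       batch_sd = 0.005,
                       female_fraction = 1,
                       case_logit = NULL,
                       seed = 1L) {
  check_number(n_samples, "n_samples", lo = 4, integer = TRUE)
  check_number(case_fraction, "case_fraction", lo = 1e-9, hi = 1 - 1e-9)
  if (case_fraction * n_samples < 2)
    stop_field("case_fraction", "case_fraction * n_samples must be >= 2")
  check_number(n_probes, "n_probes", lo = 1, integer = TRUE)
  if (!is.data.frame(cmr_layout) ||
      !all(c("probe_count", "corr", "gap_bp") %in% names(cmr_layout)))
    stop_field("cmr_layout", "must be a data.frame with probe_count, corr, gap_bp")
  if (any(cmr_layout$probe_count < 2))
    stop_field("cmr_layout", "probe_count must be >= 2 for every CMR")
  if (any(cmr_layout$corr < 0 | cmr_layout$corr > 1))
    stop_field("cmr_layout", "corr must be in [0, 1]")
  if (sum(cmr_layout$probe_count) > n_probes)
    stop_field("cmr_layout", "probe counts sum exceeds n_probes")
  check_number(n_snps, "n_snps", lo = 0, integer = TRUE)
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop_field("maf_range", "must be an interval within (0, 0.5]")
  for (e in exposures) {
    if (is.null(e$name)) stop_field("exposures", "each exposure needs a name")
    if (e$prevalence < 0 || e$prevalence > 1)
      stop_field("exposures", sprintf("prevalence of '%s' must be in [0,1]", e$name))
  }
  check_number(m_imputations, "m_imputations", lo = 1, integer = TRUE)
  check_number(missing_rate, "missing_rate", lo = 0, hi = 1)
  check_number(imputation_flip_rate, "imputation_flip_rate", lo = 0, hi = 1)
  check_number(noise_sd, "noise_sd", lo = 0)
  check_number(latent_sd, "latent_sd", lo = 1e-9)
  check_number(batch_sd, "batch_sd", lo = 0)
  check_number(female_fraction, "female_fraction", lo = 0, hi = 1)
  check_number(seed, "seed", integer = TRUE)
  n_cmrs <- nrow(cmr_layout)
  exposure_names <- vapply(exposures, `[[`, "", "name")
  for (ef in effects) {
    if (!inherits(ef, "effect_spec")) stop_field("effects", "entries must be effect_spec objects")
    if (ef$cmr_index < 1 || ef$cmr_index > n_cmrs)
      stop_field("effects", sprintf("cmr_index %d does not exist", ef$cmr_index))
    if (!is.null(ef$snp_index) && (ef$snp_index < 1 || ef$snp_index > n_snps))
      stop_field("effects", sprintf("snp_index %d does not exist", ef$snp_index))
    if (!is.null(ef$exposure_name) && !(ef$exposure_name %in% exposure_names))
      stop_field("effects", sprintf("exposure '%s' does not exist", ef$exposure_name))
  }
  structure(list(
    n_samples = as.integer(n_samples), case_fraction = case_fraction,
    n_probes = as.integer(n_probes), cmr_layout = cmr_layout,
    n_snps = as.integer(n_snps), maf_range = maf_range,
    exposures = exposures, m_imputations = as.integer(m_imputations),
    missing_rate = missing_rate, imputation_flip_rate = imputation_flip_rate,
    effects = effects, noise_sd = noise_sd, latent_sd = latent_sd,
    n_plates = as.integer(n_plates), n_rows = as.integer(n_rows),
    batch_sd = batch_sd, female_fraction = female_fraction,
    case_logit = case_logit, seed = as.integer(seed)
  ), class = "sim_config")
}

#' CMR layout helper
#'
#' @param n_cmrs number of CMRs.
#' @param probe_count probes per CMR (recycled).
#' @param corr target within-CMR correlation (recycled).
#' @param gap_bp inter-probe spacing in bp (recycled).
#' @return data frame suitable for `sim_config(cmr_layout = ...)`.
#' @export
cmr_layout <- function(n_cmrs, probe_count = 3L, corr = 0.5, gap_bp = 150L) {
  data.frame(probe_count = rep_len(as.integer(probe_count), n_cmrs),
             corr = rep_len(corr, n_cmrs),
             gap_bp = rep_len(as.integer(gap_bp), n_cmrs))
}

#' Default exposure panel: three pesticide-class exposures
#'
#' Insecticide and fungicide occupational exposure plus overall
#' gardening-level exposure, all above the 10% eligibility prevalence.
#' Lag times (years since last use) are lognormal.
#' @export
default_exposures <- function() {
  list(
    list(name = "insecticide", prevalence = 0.15, lag_meanlog = 2.3, lag_sdlog = 0.5),
    list(name = "fungicide",   prevalence = 0.20, lag_meanlog = 2.3, lag_sdlog = 0.5),
    list(name = "gardening",   prevalence = 0.35, lag_meanlog = 2.0, lag_sdlog = 0.6)
  )
}

#' Planted effect specification
#'
#' @param cmr_index CMR the effect is planted in (1-based index into the
#'   layout).
#' @param kind one of `"PD"`, `"G"`, `"E"`, `"G_plus_E"`, `"GxE"`, `"LED"`.
#' @param delta_beta beta-scale effect size(s): one value for PD/G/E/LED; for
#'   `G_plus_E`, `c(G, E)`; for `GxE`, `c(G, E, GxE)` (a single value is taken
#'   as the interaction term only).
#' @param snp_index SNP index for G-containing kinds.
#' @param exposure_name exposure name for E-containing kinds.
#' @export
effect_spec <- function(cmr_index, kind, delta_beta, snp_index = NULL,
                        exposure_name = NULL) {
  kind <- match.arg(kind, c("PD", "G", "E", "G_plus_E", "GxE", "LED"))
  if (!all(is.finite(delta_beta))) stop_field("delta_beta", "must be finite")
  needs_g <- kind %in% c("G", "G_plus_E", "GxE")
  needs_e <- kind %in% c("E", "G_plus_E", "GxE")
  if (needs_g && is.null(snp_index)) stop_field("snp_index", paste("required for kind", kind))
  if (needs_e && is.null(exposure_name)) stop_field("exposure_name", paste("required for kind", kind))
  delta <- switch(kind,
    G_plus_E = rep_len(delta_beta, 2L),
    GxE = if (length(delta_beta) == 1L) c(0, 0, delta_beta) else rep_len(delta_beta, 3L),
    delta_beta[1L])
  structure(list(cmr_index = as.integer(cmr_index), kind = kind,
                 delta_beta = delta,
                 snp_index = if (is.null(snp_index)) NULL else as.integer(snp_index),
                 exposure_name = exposure_name),
            class = "effect_spec")
}

rdirichlet_one <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# Whole-blood-like composition: neutrophil-dominant 12-type mixture.
blood_cell_alphas <- function() {
  c(Neu = 50, Eos = 2.5, Bas = 0.6, Mono = 7, Bnv = 3, Bmem = 2,
    CD4nv = 7, CD4mem = 8, CD8nv = 4, CD8mem = 5, Treg = 2, NK = 6)
}

#' Simulate a synthetic cohort bundle
#'
#' Generates methylation beta values with CMR-structured correlation (a shared
#' per-CMR latent Gaussian factor, mapped through a logistic squash), HWE SNP
#' dosages placed in cis of CMRs, binary exposures with lag times and
#' imputation uncertainty, covariates, batch shifts, and the planted effects
#' from the config, then clips beta to \[0.001, 0.999\]. Identical
#' config + seed reproduces the bundle exactly.
#'
#' @param config a [sim_config()].
#' @return a list of class `cohort_bundle` with elements `beta` (probes x
#'   samples), `manifest` (probe_id, chrom, pos), `samples` (covariate table),
#'   `cell_props` (samples x 12), `genotypes` (SNPs x samples dosages),
#'   `snp_manifest`, `exposures` (an `exposure_panel`), `cmr_set` (the
#'   generating CMR definitions, usable as a reference CMR set), `truth`
#'   (ground-truth effect table), and `config`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config object")
  n <- config$n_samples
  layout <- config$cmr_layout
  n_cmrs <- nrow(layout)

  ## ---- probe manifest & CMR placement -------------------------------------
  set.seed(derive_seed(config$seed, "manifest"))
  probe_counts <- layout$probe_count
  n_in_cmrs <- sum(probe_counts)
  n_single <- config$n_probes - n_in_cmrs
  chroms <- paste0("chr", 1:22)
  cmr_chrom <- chroms[((seq_len(n_cmrs) - 1L) %% 22L) + 1L]
  pos <- integer(config$n_probes)
  chrom <- character(config$n_probes)
  probe_cmr <- integer(config$n_probes)  # 0 = singleton
  cursor <- stats::setNames(rep(1e6, 22), chroms)
  idx <- 1L
  cmr_rows <- vector("list", n_cmrs)
  for (c_i in seq_len(n_cmrs)) {
    ch <- cmr_chrom[c_i]
    k <- probe_counts[c_i]
    p0 <- cursor[[ch]]
    pp <- p0 + layout$gap_bp[c_i] * (seq_len(k) - 1L)
    rows <- idx:(idx + k - 1L)
    pos[rows] <- pp
    chrom[rows] <- ch
    probe_cmr[rows] <- c_i
    cmr_rows[[c_i]] <- rows
    cursor[[ch]] <- pp[k] + 2e5  # well beyond any linking distance
    idx <- idx + k
  }
  if (n_single > 0) {
    for (s_i in seq_len(n_single)) {
      ch <- chroms[((s_i - 1L) %% 22L) + 1L]
      pos[idx] <- cursor[[ch]]
      chrom[idx] <- ch
      cursor[[ch]] <- cursor[[ch]] + 2e5
      idx <- idx + 1L
    }
  }
  probe_id <- sprintf("cg%07d", seq_len(config$n_probes))
  manifest <- data.frame(probe_id = probe_id, chrom = chrom, pos = as.integer(pos),
                         stringsAsFactors = FALSE)
  cmr_ids <- sprintf("CMR%05d", seq_len(n_cmrs))
  regions <- data.frame(
    cmr_id = cmr_ids, chrom = cmr_chrom,
    start = vapply(cmr_rows, function(r) pos[r[1L]], 0),
    end = vapply(cmr_rows, function(r) pos[r[length(r)]], 0),
    n_probes = probe_counts, stringsAsFactors = FALSE)
  cmr_set <- new_cmr_set(regions,
                         stats::setNames(lapply(cmr_rows, function(r) probe_id[r]), cmr_ids))

  ## ---- covariates ----------------------------------------------------------
  set.seed(derive_seed(config$seed, "covariates"))
  sample_id <- sprintf("S%04d", seq_len(n))
  n_f <- round(config$female_fraction * n)
  sex <- sample(c(rep("F", n_f), rep("M", n - n_f)))
  age <- round(stats::rnorm(n, 65, 7), 1)
  smoking <- stats::rbinom(n, 1, 0.30)
  alcohol <- stats::rbinom(n, 1, 0.50)
  head_trauma <- stats::rbinom(n, 1, 0.15)
  plate <- factor(sample(seq_len(config$n_plates), n, replace = TRUE))
  row <- factor(sample(seq_len(config$n_rows), n, replace = TRUE))
  gpc <- matrix(stats::rnorm(3 * n), ncol = 3,
                dimnames = list(NULL, paste0("gpc", 1:3)))
  cell_props <- t(vapply(seq_len(n), function(i) rdirichlet_one(blood_cell_alphas()),
                         numeric(12)))
  colnames(cell_props) <- names(blood_cell_alphas())
  rownames(cell_props) <- sample_id

  ## ---- exposures -----------------------------------------------------------
  set.seed(derive_seed(config$seed, "exposures"))
  exp_list <- list()
  for (e in config$exposures) {
    truth_e <- stats::rbinom(n, 1, e$prevalence)
    lag <- rep(NA_real_, n)
    lag[truth_e == 1] <- round(stats::rlnorm(sum(truth_e), e$lag_meanlog, e$lag_sdlog), 1)
    panel <- simulate_imputations(truth_e, config$missing_rate,
                                  config$imputation_flip_rate, config$m_imputations,
                                  seed = derive_seed(config$seed, paste0("imp_", e$name)))
    # imputation can mark additional samples exposed, so any sample subject to
    # imputation also carries a lag time
    need_lag <- attr(panel, "missing") & is.na(lag)
    lag[need_lag] <- round(stats::rlnorm(sum(need_lag), e$lag_meanlog,
                                         e$lag_sdlog), 1)
    exp_list[[e$name]] <- list(name = e$name, truth = truth_e, lag = lag,
                               imputations = panel)
  }
  exposures <- structure(list(exposures = exp_list, sample_id = sample_id,
                              m = config$m_imputations), class = "exposure_panel")

  ## ---- genotypes -----------------------------------------------------------
  set.seed(derive_seed(config$seed, "genotypes"))
  if (config$n_snps > 0) {
    maf <- stats::runif(config$n_snps, config$maf_range[1], config$maf_range[2])
    geno <- matrix(stats::rbinom(config$n_snps * n, 2, rep(maf, each = n)),
                   nrow = config$n_snps, byrow = TRUE)
    host <- ((seq_len(config$n_snps) - 1L) %% n_cmrs) + 1L
    mid <- (regions$start + regions$end) / 2
    snp_pos <- as.integer(round(mid[host] + stats::runif(config$n_snps, -3e4, 3e4)))
    snp_manifest <- data.frame(snp_id = sprintf("rs%06d", seq_len(config$n_snps)),
                               chrom = regions$chrom[host], pos = pmax(1L, snp_pos),
                               maf = maf, stringsAsFactors = FALSE)
    rownames(geno) <- snp_manifest$snp_id
    colnames(geno) <- sample_id
  } else {
    geno <- matrix(numeric(0), nrow = 0, ncol = n, dimnames = list(NULL, sample_id))
    snp_manifest <- data.frame(snp_id = character(), chrom = character(),
                               pos = integer(), maf = numeric())
  }

  ## ---- case status ---------------------------------------------------------
  set.seed(derive_seed(config$seed, "case"))
  if (is.null(config$case_logit)) {
    n_cases <- round(config$case_fraction * n)
    case <- integer(n)
    case[sample.int(n, n_cases)] <- 1L
  } else {
    lp <- numeric(n)
    cov_tab <- list(age = scale(age)[, 1], smoking = smoking, alcohol = alcohol,
                    head_trauma = head_trauma)
    for (nm in names(config$case_logit)) {
      v <- if (nm %in% names(cov_tab)) cov_tab[[nm]]
           else if (nm %in% names(exp_list)) exp_list[[nm]]$truth
           else if (grepl("^snp[0-9]+$", nm))
             scale(geno[as.integer(sub("snp", "", nm)), ])[, 1]
           else stop_field("case_logit", sprintf("unknown variable '%s'", nm))
      lp <- lp + config$case_logit[[nm]] * v
    }
    pr <- stats::plogis(stats::qlogis(config$case_fraction) + lp - mean(lp))
    case <- stats::rbinom(n, 1, pr)
    if (sum(case) < 2 || sum(case) > n - 2)
      stop("degenerate case draw under case_logit; adjust loadings")
  }
  led <- rep(NA_real_, n)
  led[case == 1] <- pmax(50, round(stats::rnorm(sum(case), 600, 150)))

  samples <- data.frame(sample_id = sample_id, case = case, sex = sex, age = age,
                        smoking = smoking, alcohol = alcohol,
                        head_trauma = head_trauma, plate = plate, row = row,
                        gpc, led = led, stringsAsFactors = FALSE)

  ## ---- methylation ---------------------------------------------------------
  set.seed(derive_seed(config$seed, "beta"))
  mu_probe <- numeric(config$n_probes)
  latent <- matrix(0, config$n_probes, n)
  for (c_i in seq_len(n_cmrs)) {
    rows <- cmr_rows[[c_i]]
    k <- length(rows)
    mu_c <- stats::runif(1, -1.5, 1.5)
    mu_probe[rows] <- mu_c + stats::rnorm(k, 0, 0.15)
    rho <- layout$corr[c_i]
    # compensate the latent correlation for independent probe noise so the
    # configured value is the *observed* within-CMR correlation (delta-method
    # signal SD on the beta scale; capped at 1 where not attainable)
    if (rho > 0 && config$noise_sd > 0) {
      p_c <- stats::plogis(mu_c)
      s2 <- (config$latent_sd * p_c * (1 - p_c))^2
      rho <- min(1, rho * (s2 + config$noise_sd^2) / s2)
    }
    f <- stats::rnorm(n)
    eps <- matrix(stats::rnorm(k * n), k, n)
    latent[rows, ] <- config$latent_sd *
      (sqrt(rho) * matrix(f, k, n, byrow = TRUE) + sqrt(1 - rho) * eps)
  }
  singles <- which(probe_cmr == 0L)
  if (length(singles)) {
    mu_probe[singles] <- stats::runif(length(singles), -2.5, 2.5)
    latent[singles, ] <- config$latent_sd * stats::rnorm(length(singles) * n)
  }
  beta <- stats::plogis(mu_probe + latent)

  # batch: additive per-level mean shifts
  if (config$batch_sd > 0) {
    plate_shift <- stats::rnorm(config$n_plates, 0, config$batch_sd)
    row_shift <- stats::rnorm(config$n_rows, 0, config$batch_sd)
    beta <- beta + rep(plate_shift[as.integer(plate)] + row_shift[as.integer(row)],
                       each = config$n_probes)
  }

  # planted effects, all on the beta scale
  truth_rows <- list()
  for (ef in config$effects) {
    rows <- cmr_rows[[ef$cmr_index]]
    cid <- cmr_ids[ef$cmr_index]
    add <- switch(ef$kind,
      PD = ef$delta_beta * case,
      G = ef$delta_beta * geno[ef$snp_index, ],
      E = ef$delta_beta * exp_list[[ef$exposure_name]]$truth,
      LED = ef$delta_beta * ifelse(is.na(led), 0, led),
      G_plus_E = ef$delta_beta[1] * geno[ef$snp_index, ] +
                 ef$delta_beta[2] * exp_list[[ef$exposure_name]]$truth,
      GxE = {
        g <- geno[ef$snp_index, ]; ev <- exp_list[[ef$exposure_name]]$truth
        ef$delta_beta[1] * g + ef$delta_beta[2] * ev + ef$delta_beta[3] * g * ev
      })
    beta[rows, ] <- beta[rows, ] + rep(add, each = length(rows))
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      cmr_id = cid, kind = ef$kind,
      delta_beta = paste(ef$delta_beta, collapse = ","),
      snp_id = if (is.null(ef$snp_index)) NA_character_ else snp_manifest$snp_id[ef$snp_index],
      exposure = ef$exposure_name %||% NA_character_,
      stringsAsFactors = FALSE)
  }
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(cmr_id = character(), kind = character(), delta_beta = character(),
               snp_id = character(), exposure = character())

  if (config$noise_sd > 0)
    beta <- beta + stats::rnorm(length(beta), 0, config$noise_sd)
  beta <- pmin(pmax(beta, 0.001), 0.999)
  dimnames(beta) <- list(probe_id, sample_id)

  structure(list(beta = beta, manifest = manifest, samples = samples,
                 cell_props = cell_props, genotypes = geno,
                 snp_manifest = snp_manifest, exposures = exposures,
                 cmr_set = cmr_set, truth = truth, config = config),
            class = "cohort_bundle")
}

#' Simulate multiply-imputed copies of a binary exposure
#'
#' Entries selected as missing are re-drawn independently in each of the `m`
#' copies, disagreeing with the underlying truth at `flip_rate`; non-missing
#' entries are identical across copies.
#'
#' @param exposure_truth binary 0/1 vector.
#' @param missing_rate fraction of entries subject to imputation.
#' @param flip_rate per-copy disagreement probability for missing entries.
#' @param m number of imputed copies (default 10).
#' @param seed integer seed.
#' @return integer matrix, `length(exposure_truth)` x `m`, with a logical
#'   attribute `"missing"` marking the imputed entries.
#' @export
simulate_imputations <- function(exposure_truth, missing_rate, flip_rate,
                                 m = 10L, seed = 1L) {
  if (!all(exposure_truth %in% c(0, 1))) stop("exposure_truth must be binary 0/1")
  check_number(missing_rate, "missing_rate", lo = 0, hi = 1)
  check_number(flip_rate, "flip_rate", lo = 0, hi = 1)
  if (m < 1) stop("m must be >= 1")
  set.seed(seed)
  n <- length(exposure_truth)
  miss <- stats::runif(n) < missing_rate
  out <- matrix(rep(as.integer(exposure_truth), m), nrow = n)
  if (any(miss)) {
    k <- sum(miss)
    flips <- matrix(stats::runif(k * m) < flip_rate, k, m)
    truth_block <- matrix(exposure_truth[miss], k, m)
    out[miss, ] <- as.integer(ifelse(flips, 1 - truth_block, truth_block))
  }
  colnames(out) <- paste0("imp", seq_len(m))
  attr(out, "missing") <- miss
  out
}

#' Empirical power of the region-based EWAS by simulation
#'
#' Runs the full per-stratum analysis (cell-type PCs, propensity full matching,
#' variability filter, weighted Huber EWAS, hit calling) on repeated synthetic
#' cohorts and reports the fraction of planted disease-effect CMRs detected at
#' the given FDR and effect-size thresholds.
#'
#' @param config a [sim_config()] containing at least one `PD`-kind effect with
#'   nonzero `delta_beta`.
#' @param n_runs number of simulated cohorts.
#' @param fdr BH-adjusted p-value threshold (default 0.05).
#' @param detection_delta minimum absolute adjusted effect (default 0.03).
#' @param seed integer seed governing all runs.
#' @return list with `power`, `ci` (normal-approximation 95% interval from
#'   the binomial variance over runs), and per-run detection fractions.
#' @export
power_by_simulation <- function(config, n_runs, fdr = 0.05,
                                detection_delta = 0.03, seed = 1L) {
  if (n_runs < 1) stop("n_runs must be >= 1")
  pd <- Filter(function(e) e$kind == "PD" && any(e$delta_beta != 0), config$effects)
  if (!length(pd)) stop("power undefined: config plants no nonzero PD effects")
  planted <- sprintf("CMR%05d", vapply(pd, `[[`, 0L, "cmr_index"))
  fractions <- vapply(seq_len(n_runs), function(r) {
    cfg <- config
    cfg$seed <- derive_seed(seed, paste0("power_run_", r))
    bundle <- simulate_cohort(cfg)
    ew <- run_stratum_ewas(bundle, p_thr = fdr, effect_thr = detection_delta)
    hits <- ew$hits
    mean(planted %in% hits)
  }, 0)
  power <- mean(fractions)
  se <- sqrt(max(stats::var(fractions) / n_runs, power * (1 - power) /
                   (n_runs * length(planted))))
  list(power = power,
       ci = c(max(0, power - 1.96 * se), min(1, power + 1.96 * se)),
       runs = fractions)
}
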