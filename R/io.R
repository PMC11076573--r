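#' Read / write tab-separated tables
#'
#' Thin wrappers around base TSV I/O guaranteeing byte-identical round trips
#' for the pipeline's report tables.
#'
#' @param df data frame.
#' @param path file path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a CMR set as BED plus a probe sidecar
#'
#' Internal coordinates are 1-based inclusive; the BED export is 0-based
#' half-open (start = internal start - 1, end = internal end). The sidecar TSV
#' lists the ordered member probe ids per CMR.
#'
#' @param cmrset a `cmr_set`.
#' @param bed_path BED output path.
#' @param probes_path sidecar TSV path (default `<bed_path>.probes.tsv`).
#' @export
write_cmr_bed <- function(cmrset, bed_path,
                          probes_path = paste0(bed_path, ".probes.tsv")) {
  r <- cmrset$regions
  bed <- data.frame(chrom = r$chrom, start = r$start - 1L, end = r$end,
                    name = r$cmr_id)
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  side <- data.frame(cmr_id = r$cmr_id,
                     probes = vapply(cmrset$probes[r$cmr_id], paste,
                                     "", collapse = ","))
  write_tsv(side, probes_path)
  invisible(bed_path)
}

#' @rdname write_cmr_bed
#' @param bed_path,probes_path paths written by [write_cmr_bed()].
#' @export
read_cmr_bed <- function(bed_path,
                         probes_path = paste0(bed_path, ".probes.tsv")) {
  bed <- utils::read.table(bed_path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name"))
  side <- read_tsv(probes_path)
  probes <- strsplit(side$probes, ",", fixed = TRUE)
  names(probes) <- side$cmr_id
  regions <- data.frame(cmr_id = bed$name, chrom = bed$chrom,
                        start = bed$start + 1L, end = bed$end,
                        n_probes = lengths(probes)[bed$name],
                        stringsAsFactors = FALSE)
  new_cmr_set(regions, probes)
}

#' Serialize a cohort bundle to plain-text files
#'
#' Writes the beta matrix, probe manifest, genotype dosages and SNP manifest,
#' the exposure panel in long format (sample_id, exposure, imputation, value,
#' lag_time), the covariate table, cell proportions, the CMR set (BED +
#' sidecar) and the ground-truth table.
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if absent).
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_tsv(data.frame(probe_id = rownames(bundle$beta),
                       as.data.frame(bundle$beta), check.names = FALSE),
            fp("beta.tsv"))
  write_tsv(bundle$manifest, fp("probes.tsv"))
  if (nrow(bundle$genotypes)) {
    write_tsv(data.frame(snp_id = rownames(bundle$genotypes),
                         as.data.frame(bundle$genotypes), check.names = FALSE),
              fp("dosages.tsv"))
  }
  write_tsv(bundle$snp_manifest, fp("snps.tsv"))
  long <- list()
  for (nm in names(bundle$exposures$exposures)) {
    e <- bundle$exposures$exposures[[nm]]
    m <- ncol(e$imputations)
    for (i in seq_len(m)) {
      long[[length(long) + 1L]] <- data.frame(
        sample_id = bundle$exposures$sample_id, exposure = nm,
        imputation = i, value = e$imputations[, i],
        lag_time = e$lag, stringsAsFactors = FALSE)
    }
  }
  write_tsv(do.call(rbind, long), fp("exposures.tsv"))
  write_tsv(bundle$samples, fp("samples.tsv"))
  write_tsv(data.frame(sample_id = rownames(bundle$cell_props),
                       as.data.frame(bundle$cell_props), check.names = FALSE),
            fp("cell_props.tsv"))
  write_cmr_bed(bundle$cmr_set, fp("cmrs.bed"))
  write_tsv(bundle$truth, fp("truth.tsv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @param dir directory written by [write_cohort()].
#' @export
read_cohort <- function(dir) {
  fp <- function(x) file.path(dir, x)
  beta_df <- read_tsv(fp("beta.tsv"))
  beta <- as.matrix(beta_df[, -1, drop = FALSE])
  rownames(beta) <- beta_df$probe_id
  manifest <- read_tsv(fp("probes.tsv"))
  snp_manifest <- read_tsv(fp("snps.tsv"))
  genotypes <- if (file.exists(fp("dosages.tsv"))) {
    g <- read_tsv(fp("dosages.tsv"))
    m <- as.matrix(g[, -1, drop = FALSE]); rownames(m) <- g$snp_id; m
  } else matrix(numeric(0), 0, ncol(beta), dimnames = list(NULL, colnames(beta)))
  samples <- utils::read.delim(fp("samples.tsv"), sep = "\t",
                               stringsAsFactors = FALSE, check.names = FALSE,
                               colClasses = c(sex = "character"))
  samples$plate <- factor(samples$plate)
  samples$row <- factor(samples$row)
  cp <- read_tsv(fp("cell_props.tsv"))
  cell_props <- as.matrix(cp[, -1, drop = FALSE])
  rownames(cell_props) <- cp$sample_id
  long <- read_tsv(fp("exposures.tsv"))
  exp_list <- list()
  for (nm in unique(long$exposure)) {
    sub <- long[long$exposure == nm, ]
    m <- max(sub$imputation)
    first <- sub[sub$imputation == 1, ]
    o <- match(samples$sample_id, first$sample_id)
    imp <- vapply(seq_len(m), function(i) {
      si <- sub[sub$imputation == i, ]
      as.integer(si$value[match(samples$sample_id, si$sample_id)])
    }, integer(nrow(samples)))
    colnames(imp) <- paste0("imp", seq_len(m))
    exp_list[[nm]] <- list(name = nm, truth = NULL, lag = first$lag_time[o],
                           imputations = imp)
  }
  exposures <- structure(list(exposures = exp_list,
                              sample_id = samples$sample_id,
                              m = if (length(exp_list)) ncol(exp_list[[1]]$imputations) else 0L),
                         class = "exposure_panel")
  structure(list(beta = beta, manifest = manifest, samples = samples,
                 cell_props = cell_props, genotypes = genotypes,
                 snp_manifest = snp_manifest, exposures = exposures,
                 cmr_set = read_cmr_bed(fp("cmrs.bed")),
                 truth = read_tsv(fp("truth.tsv")), config = NULL),
            class = "cohort_bundle")
}

#' Validate a cohort bundle against the pipeline's input contract
#'
#' Checks beta range, manifest completeness, dosage range \[0,2\], exposure
#' binariness per imputation, and covariate completeness for the EWAS formula.
#' Violations are reported as structured messages naming the offending file
#' component, row, and column.
#'
#' @param bundle a `cohort_bundle`.
#' @param fail stop on the first violation (default TRUE); otherwise return
#'   all messages.
#' @return (invisibly) a character vector of violations; empty when clean.
#' @export
validate_inputs <- function(bundle, fail = TRUE) {
  problems <- character(0)
  note <- function(fmt, ...) problems <<- c(problems, sprintf(fmt, ...))

  bad <- which(bundle$beta < 0 | bundle$beta > 1, arr.ind = TRUE)
  if (nrow(bad))
    note("beta: value %.4g out of [0,1] at probe %s, sample %s",
         bundle$beta[bad[1, 1], bad[1, 2]],
         rownames(bundle$beta)[bad[1, 1]], colnames(bundle$beta)[bad[1, 2]])
  uncovered <- setdiff(rownames(bundle$beta), bundle$manifest$probe_id)
  if (length(uncovered))
    note("manifest: probe %s missing from probe manifest", uncovered[1])
  if (nrow(bundle$genotypes)) {
    badg <- which(bundle$genotypes < 0 | bundle$genotypes > 2, arr.ind = TRUE)
    if (nrow(badg))
      note("dosages: value out of [0,2] at SNP %s, sample %s",
           rownames(bundle$genotypes)[badg[1, 1]],
           colnames(bundle$genotypes)[badg[1, 2]])
  }
  for (nm in names(bundle$exposures$exposures)) {
    im <- bundle$exposures$exposures[[nm]]$imputations
    if (!all(im %in% c(0L, 1L)))
      note("exposures: non-binary value for exposure %s", nm)
  }
  needed <- c("sample_id", "case", "sex", "age", "smoking", "alcohol",
              "head_trauma", "plate", "row", "gpc1", "gpc2", "gpc3")
  for (col in needed) {
    if (!col %in% names(bundle$samples)) {
      note("samples: required column %s absent", col)
    } else if (anyNA(bundle$samples[[col]])) {
      i <- which(is.na(bundle$samples[[col]]))[1]
      note("samples: missing %s for sample %s", col,
           bundle$samples$sample_id[i])
    }
  }
  if (fail && length(problems)) stop(paste(problems, collapse = "\n"), call. = FALSE)
  invisible(problems)
}
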