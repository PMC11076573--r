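#' Co-methylated region (CMR) sets
#'
#' A `cmr_set` couples a region table (`cmr_id`, `chrom`, `start`, `end`,
#' `n_probes`; 1-based inclusive coordinates of the first and last member
#' probe) with the ordered member probe ids of each region.
#'
#' @param regions data frame with columns `cmr_id`, `chrom`, `start`, `end`,
#'   `n_probes`.
#' @param probes named list (by `cmr_id`) of probe-id character vectors,
#'   ordered by position.
#' @return object of class `cmr_set`.
#' @export
new_cmr_set <- function(regions, probes) {
  stopifnot(is.data.frame(regions),
            all(c("cmr_id", "chrom", "start", "end", "n_probes") %in% names(regions)),
            identical(sort(as.character(regions$cmr_id)),
                      sort(as.character(names(probes) %||% character(0)))))
  structure(list(regions = regions[, c("cmr_id", "chrom", "start", "end", "n_probes")],
                 probes = if (nrow(regions)) probes[regions$cmr_id] else list()),
            class = "cmr_set")
}

#' @export
print.cmr_set <- function(x, ...) {
  cat(sprintf("cmr_set: %d regions, %d probes\n",
              nrow(x$regions), sum(lengths(x$probes))))
  print(utils::head(x$regions))
  invisible(x)
}

#' Call co-methylated regions from probe-level beta values
#'
#' Probes are sorted by (chromosome, position). An adjacent pair is linked iff
#' it lies on the same chromosome, the gap is at most `max_gap` bp, and the
#' pairwise Spearman correlation across samples is at least `min_corr`.
#' Maximal linked runs of two or more probes become CMRs. A constant probe has
#' undefined correlation with its neighbours: the link is broken (and counted
#' in the `n_undefined_pairs` attribute), never an error.
#'
#' @param beta probes x samples matrix of beta values, rownames = probe ids.
#' @param manifest data frame (`probe_id`, `chrom`, `pos`) covering every row
#'   of `beta`.
#' @param min_corr minimum Spearman correlation (default 0.3).
#' @param max_gap maximum inter-probe distance in bp (default 1000).
#' @return a [new_cmr_set()] object.
#' @export
call_cmrs <- function(beta, manifest, min_corr = 0.3, max_gap = 1000) {
  beta <- as.matrix(beta)
  if (ncol(beta) < 3) stop("need at least 3 samples to estimate correlations")
  if (!all(rownames(beta) %in% manifest$probe_id))
    stop("manifest does not cover all probes in beta")
  m <- manifest[match(rownames(beta), manifest$probe_id), ]
  o <- order(m$chrom, m$pos)
  m <- m[o, ]
  beta <- beta[o, , drop = FALSE]
  np <- nrow(beta)
  linked <- logical(max(np - 1L, 0L))
  n_undef <- 0L
  if (np >= 2L) {
    ranks <- t(apply(beta, 1L, rank, ties.method = "average"))
    sds <- apply(ranks, 1L, stats::sd)
    for (i in seq_len(np - 1L)) {
      if (m$chrom[i] != m$chrom[i + 1L]) next
      if (m$pos[i + 1L] - m$pos[i] > max_gap) next
      if (sds[i] == 0 || sds[i + 1L] == 0) { n_undef <- n_undef + 1L; next }
      rho <- stats::cor(ranks[i, ], ranks[i + 1L, ])
      if (is.finite(rho) && rho >= min_corr) linked[i] <- TRUE
    }
  }
  # maximal runs of linked adjacencies
  regions <- list(); probes <- list()
  i <- 1L
  cid <- 0L
  while (i < np) {
    if (linked[i]) {
      j <- i
      while (j < np && linked[j]) j <- j + 1L
      cid <- cid + 1L
      id <- sprintf("CMR%05d", cid)
      rows <- i:j
      regions[[cid]] <- data.frame(cmr_id = id, chrom = m$chrom[i],
                                   start = m$pos[i], end = m$pos[j],
                                   n_probes = length(rows),
                                   stringsAsFactors = FALSE)
      probes[[id]] <- m$probe_id[rows]
      i <- j + 1L
    } else i <- i + 1L
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(cmr_id = character(), chrom = character(), start = integer(),
               end = integer(), n_probes = integer())
  out <- new_cmr_set(regions, probes)
  attr(out, "n_undefined_pairs") <- n_undef
  out
}

#' Summarize beta values per CMR as the per-sample median
#'
#' @param beta probes x samples beta matrix.
#' @param cmrset a `cmr_set`; every member probe must be present in `beta`.
#' @return CMRs x samples matrix of median beta values.
#' @export
summarize_cmr_beta <- function(beta, cmrset) {
  beta <- as.matrix(beta)
  ids <- cmrset$regions$cmr_id
  out <- matrix(NA_real_, length(ids), ncol(beta),
                dimnames = list(ids, colnames(beta)))
  ridx <- stats::setNames(seq_len(nrow(beta)), rownames(beta))
  ks <- lengths(cmrset$probes[ids])
  for (k in sort(unique(ks))) {
    sel <- which(ks == k)
    pid <- unlist(cmrset$probes[ids[sel]], use.names = FALSE)
    ii <- unname(ridx[pid])
    if (anyNA(ii)) {
      bad <- which(is.na(ii))[1L]
      stop(sprintf("CMR %s: probe %s missing from beta matrix",
                   ids[sel[ceiling(bad / k)]], pid[bad]))
    }
    im <- matrix(ii, nrow = k)
    if (k == 1L) {
      out[sel, ] <- beta[im[1L, ], , drop = FALSE]
    } else if (k == 2L) {
      out[sel, ] <- (beta[im[1L, ], , drop = FALSE] +
                       beta[im[2L, ], , drop = FALSE]) / 2
    } else if (k == 3L) {
      a <- beta[im[1L, ], , drop = FALSE]
      b <- beta[im[2L, ], , drop = FALSE]
      d <- beta[im[3L, ], , drop = FALSE]
      out[sel, ] <- pmin(pmax(a, b), pmax(pmin(a, b), d))
    } else {
      for (j in seq_along(sel))
        out[sel[j], ] <- col_medians(beta[im[, j], , drop = FALSE])
    }
  }
  out
}

#' Variability filter on CMR median beta
#'
#' Retains CMRs whose spread between the `lo` and `hi` quantiles of per-sample
#' median beta strictly exceeds `min_range`. Quantiles use linear
#' interpolation (type 7).
#'
#' @param cmr_matrix CMRs x samples matrix from [summarize_cmr_beta()].
#' @param lo,hi quantile bounds (defaults 0.10 and 0.90).
#' @param min_range minimum (exclusive) spread (default 0.05).
#' @return character vector of retained CMR ids.
#' @export
variability_filter <- function(cmr_matrix, lo = 0.10, hi = 0.90, min_range = 0.05) {
  if (ncol(cmr_matrix) < 2) stop("need at least 2 samples")
  q <- apply(cmr_matrix, 1L, stats::quantile, probs = c(lo, hi), names = FALSE,
             type = 7)
  rng <- q[2L, ] - q[1L, ]
  rownames(cmr_matrix)[rng > min_range]
}

#' CMR length in bp
#'
#' The printed length convention is `end - start` (the span between the first
#' and last member probe), not `end - start + 1`.
#'
#' @param cmr either a `cmr_set` (returns a vector) or a list/row with `start`
#'   and `end`.
#' @return integer bp length(s).
#' @export
cmr_length <- function(cmr) {
  if (inherits(cmr, "cmr_set"))
    return(stats::setNames(cmr$regions$end - cmr$regions$start, cmr$regions$cmr_id))
  as.integer(cmr$end - cmr$start)
}

#' Fraction of reference CMRs sharing a probe with a query set
#'
#' @param query,reference `cmr_set` objects (both nonempty).
#' @return list with `fraction` (of reference CMRs having >= 1 probe in any
#'   query CMR) and `count`.
#' @export
reference_overlap <- function(query, reference) {
  if (!nrow(query$regions) || !nrow(reference$regions))
    stop("both CMR sets must be nonempty")
  qp <- unique(unlist(query$probes, use.names = FALSE))
  hit <- vapply(reference$probes, function(p) any(p %in% qp), TRUE)
  list(fraction = mean(hit), count = sum(hit))
}

# Subset a cmr_set to the given ids, preserving order of `ids`.
subset_cmr_set <- function(cmrset, ids) {
  keep <- match(ids, cmrset$regions$cmr_id)
  if (anyNA(keep)) stop("unknown CMR id(s)")
  new_cmr_set(cmrset$regions[keep, , drop = FALSE], cmrset$probes[ids])
}
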