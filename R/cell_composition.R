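#' Centered log-ratio transform of cell-type proportions
#'
#' Rows are samples, columns cell types; each row must be a composition
#' (non-negative, summing to 1 within 1e-6). Zeros are replaced
#' multiplicatively by `zero_replacement` and the row renormalized before the
#' transform, so every output row sums to zero.
#'
#' @param props samples x k matrix or data frame of proportions.
#' @param zero_replacement small positive value substituted for zeros.
#' @return numeric matrix of clr coordinates (rows sum to 0).
#' @export
clr_transform <- function(props, zero_replacement = 1e-5) {
  props <- as.matrix(props)
  if (any(props < 0)) stop("proportions must be non-negative")
  if (zero_replacement <= 0) stop("zero_replacement must be > 0")
  rs <- rowSums(props)
  if (any(abs(rs - 1) > 1e-6)) stop("each row must sum to 1 (within 1e-6)")
  zero <- props == 0
  if (any(zero)) {
    props[zero] <- zero_replacement
    props <- props / rowSums(props)
  }
  lp <- log(props)
  lp - rowMeans(lp)
}

# Orthonormal basis of the zero-sum (clr) subspace: normalized Helmert
# contrasts, so ilr = clr %*% V and clr back-maps as ilr %*% t(V).
ilr_basis <- function(k) {
  H <- stats::contr.helmert(k)
  sweep(H, 2, sqrt(colSums(H^2)), "/")
}

#' Robust principal components of cell-type composition
#'
#' Computes principal components of clr-transformed proportions using a
#' minimum-covariance-determinant (MCD) estimate of location and scatter, so a
#' handful of atypical compositions cannot dominate the PCs used as EWAS
#' covariates. Falls back to the classical covariance when the sample is too
#' small for MCD or when `robust = FALSE` (in which case the result equals
#' standard PCA on the clr data).
#'
#' The clr covariance has rank at most k - 1; requesting more PCs than the
#' data's rank is an error. Each loading vector's largest-magnitude entry is
#' made positive for reproducibility.
#'
#' @param props samples x k proportions (rows sum to 1).
#' @param n_pcs number of components to retain (default 6, the number used as
#'   EWAS covariates).
#' @param robust use the MCD scatter estimate (default TRUE).
#' @param zero_replacement passed to [clr_transform()].
#' @return list of class `composition_pcs`: `scores` (samples x n_pcs,
#'   centered), `loadings`, `var_explained` (fractions, non-increasing),
#'   `center`, and `cov` (the clr-scale scatter estimate the PCs decompose).
#' @export
robust_compositional_pcs <- function(props, n_pcs = 6L, robust = TRUE,
                                     zero_replacement = 1e-5) {
  props <- as.matrix(props)
  k <- ncol(props)
  n <- nrow(props)
  if (n_pcs >= k) stop("n_pcs must be smaller than the number of cell types")
  if (n < n_pcs + 1) stop("need at least n_pcs + 1 samples")
  z <- clr_transform(props, zero_replacement)

  total_var <- sum(apply(z, 2, stats::var))
  if (total_var < 1e-24) {
    # identical compositions: nothing to explain
    scores <- matrix(0, n, n_pcs, dimnames = list(rownames(props), paste0("PC", seq_len(n_pcs))))
    return(structure(list(scores = scores,
                          loadings = matrix(0, k, n_pcs),
                          var_explained = rep(0, n_pcs),
                          center = colMeans(z)), class = "composition_pcs"))
  }

  use_mcd <- robust && n >= 2 * k
  if (use_mcd) {
    # the clr covariance is singular (rows sum to 0); estimate the MCD scatter
    # in orthonormal ilr coordinates and map back to the clr simplex. The MCD
    # search subsamples, so the RNG is localized and fixed to keep the
    # pipeline reproducible without disturbing the caller's stream.
    V <- ilr_basis(k)
    rob <- with_preserved_seed(20200105, MASS::cov.rob(z %*% V, method = "mcd"))
    S <- V %*% rob$cov %*% t(V)
    center <- drop(V %*% rob$center)
  } else {
    S <- stats::cov(z)
    center <- colMeans(z)
  }
  eg <- eigen(S, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  rank <- sum(ev > max(ev) * 1e-10)
  if (n_pcs > rank) stop(sprintf("input has rank %d; cannot extract %d PCs", rank, n_pcs))
  load <- eg$vectors[, seq_len(n_pcs), drop = FALSE]
  # sign convention: largest-magnitude loading entry positive
  for (j in seq_len(n_pcs)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  scores <- sweep(z, 2, center) %*% load
  scores <- sweep(scores, 2, colMeans(scores))  # centered scores
  dimnames(scores) <- list(rownames(props), paste0("PC", seq_len(n_pcs)))
  dimnames(load) <- list(colnames(props), paste0("PC", seq_len(n_pcs)))
  structure(list(scores = scores, loadings = load,
                 var_explained = ev[seq_len(n_pcs)] / sum(ev),
                 center = center, cov = S, robust = use_mcd),
            class = "composition_pcs")
}
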