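#' Principal component niche space
#'
#' Eigen-decomposition of the sample covariance matrix of an
#' (already standardized) environmental matrix, keeping the leading
#' components as the low-dimensional niche plane. Because the input is
#' z-scored this is equivalent to a correlation PCA of the raw predictors.
#' Eigenvector signs are fixed deterministically: in each loading vector
#' the element of largest magnitude is made positive, so scores are stable
#' across runs and platforms.
#'
#' @param env Numeric matrix, records x variables (standardized).
#' @param n_components Number of components to retain (default 2).
#' @return A list of class `niche_pca`: `scores` (records x n_components),
#'   `loadings` (variables x n_components, orthonormal columns),
#'   `var_explained` (fraction of total variance per retained component),
#'   `sdev` (all singular values / sqrt(n-1)), `center` (column means
#'   removed before projection).
#' @export
pca_fit <- function(env, n_components = 2) {
  if (nrow(env) < 3) stop("need at least 3 records")
  p <- stats::prcomp(env, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  if (sum(ev > 1e-12 * ev[1]) < n_components)
    stop("fewer than ", n_components, " non-degenerate dimensions")
  flip <- vapply(seq_len(n_components), function(k) {
    v <- p$rotation[, k]
    sign(v[which.max(abs(v))])
  }, 0)
  loadings <- sweep(p$rotation[, seq_len(n_components), drop = FALSE],
                    2, flip, "*")
  scores <- sweep(p$x[, seq_len(n_components), drop = FALSE], 2, flip, "*")
  structure(list(scores = scores, loadings = loadings,
                 var_explained = ev[seq_len(n_components)] / sum(ev),
                 sdev = p$sdev, center = p$center),
            class = "niche_pca")
}

#' @export
print.niche_pca <- function(x, ...) {
  cat(sprintf("niche_pca: %d records, %d components (%s of variance)\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = " + ")))
  invisible(x)
}
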