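# z-transformation and PCA of the significant-protein SI_GI matrix.
# Observations are the band-replicate samples; variables are proteins, so
# loadings read as per-protein contributions to each component.

#' z-transform a proteins-by-samples matrix
#'
#' Standardizes each protein (row) across samples: subtract the mean and
#' divide by the sample standard deviation (n - 1 denominator).
#' Zero-variance proteins cannot be standardized; they are dropped and
#' reported.
#'
#' @param mat numeric matrix, proteins as rows, samples as columns (a
#'   `quant_matrix` is also accepted).
#' @return list of class `z_matrix` with `values` (standardized matrix)
#'   and `dropped_proteins` (character vector).
#' @export
z_transform <- function(mat) {
  if (inherits(mat, "quant_matrix")) mat <- mat$si_gi
  if (ncol(mat) < 2L)
    abort("z_transform needs at least two samples", "apms_value_error")
  sds <- apply(mat, 1L, sd)
  drop <- sds == 0 | is.na(sds)
  values <- (mat[!drop, , drop = FALSE] - rowMeans(mat[!drop, , drop = FALSE])) /
    sds[!drop]
  out <- list(values = values,
              dropped_proteins = rownames(mat)[drop] %||% character())
  class(out) <- "z_matrix"
  out
}

#' PCA of samples over standardized protein profiles
#'
#' Singular value decomposition of the samples-by-proteins matrix (rows of
#' the z-matrix are already centered across samples, so no further
#' centering is applied). Scores place the samples, loadings give each
#' protein's contribution per component, and variance explained is
#' reported in percent. A deterministic sign convention - the
#' largest-magnitude loading of each component is made positive - makes
#' the output bit-stable across runs.
#'
#' @param z a `z_matrix` (from [z_transform()]) or an equivalent
#'   proteins-by-samples matrix with standardized rows.
#' @return object of class `pca_result`: list with `scores` (samples x
#'   components), `loadings` (proteins x components), `variance_explained`
#'   (percent per component, non-increasing, summing to 100), and
#'   `dropped_proteins`.
#' @export
pca_samples <- function(z) {
  dropped <- character()
  if (inherits(z, "z_matrix")) {
    dropped <- z$dropped_proteins
    z <- z$values
  }
  if (!nrow(z))
    abort("no proteins retained for PCA", "apms_value_error")
  X <- t(z)                                  # samples x proteins
  if (all(X == 0))
    abort("degenerate all-zero matrix", "apms_value_error")
  sv <- svd(X)
  k <- min(dim(X))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], nrow = k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  comp <- paste0("PC", seq_len(k))
  dimnames(scores) <- list(rownames(X), comp)
  dimnames(loadings) <- list(colnames(X), comp)
  ve <- 100 * sv$d[seq_len(k)]^2 / sum(sv$d^2)
  out <- list(scores = scores, loadings = loadings,
              variance_explained = setNames(ve, comp),
              dropped_proteins = dropped)
  class(out) <- "pca_result"
  out
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples, %d proteins, PC1 %.2f%% / PC2 %.2f%%\n",
              nrow(x$scores), nrow(x$loadings),
              x$variance_explained[1],
              if (length(x$variance_explained) > 1)
                x$variance_explained[2] else NA_real_))
  invisible(x)
}
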