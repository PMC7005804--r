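# PCA-based discriminatory scoring of genes from the individuals x genes
# methylation-signal-density matrix. The first principal component's
# absolute loadings rank genes by how much each contributes to the
# direction of maximal between-individual variance (which, when the
# patient/control split drives that variance, is discriminatory power).

#' PCA of the individuals x genes signal matrix
#'
#' Columns are always centered; scaling to unit variance is optional
#' (off by default: signal densities share units). Eigenvalues are the
#' variances of the principal components (descending); loadings are the
#' orthonormal eigenvectors of the sample covariance matrix.
#'
#' @param matrix Numeric matrix, individuals x genes (>= 2 rows).
#' @param center Always-on centering flag (kept for the record).
#' @param scale Scale columns to unit variance? Default `FALSE`.
#' @return A list of class `pca_signal`: `eigenvalues`, `loadings`
#'   (genes x components), `scores` (individuals x components),
#'   `variance_fraction`.
#' @export
pca_signal <- function(matrix, center = TRUE, scale = FALSE) {
  if (nrow(matrix) < 2) stop("need at least 2 individuals")
  if (scale) {
    keep <- apply(matrix, 2, stats::sd) > 0
    matrix <- matrix[, keep, drop = FALSE]
  }
  pc <- stats::prcomp(matrix, center = center, scale. = scale)
  ev <- pc$sdev^2
  structure(list(eigenvalues = ev, loadings = pc$rotation,
                 scores = pc$x,
                 variance_fraction = ev / sum(ev)),
            class = "pca_signal")
}

#' Guttman-Kaiser component retention
#'
#' Retains components with eigenvalue > 1 and reports each component's
#' variance fraction.
#'
#' @param eigenvalues Numeric vector sorted descending.
#' @return A list with `indices` and `variance_fraction`.
#' @export
retain_components <- function(eigenvalues) {
  idx <- which(eigenvalues > 1)
  if (!length(idx)) {
    warning("no eigenvalue exceeds 1; no component retained")
  }
  list(indices = idx,
       variance_fraction = eigenvalues / sum(eigenvalues))
}

#' Gene PC-scores from PC1 loadings
#'
#' The PC-score of a gene is the absolute value of its PC1 loading times a
#' display scale (default 100). Because loadings are orthonormal, the sum
#' of squared (score / display_scale) equals 1; the ranking is invariant
#' to the scale constant. Each row optionally carries the gene's group
#' mean signal-density variation.
#'
#' @param loadings_pc1 Named numeric vector of PC1 loadings (names are
#'   genes), e.g. `pca$loadings[, 1]`.
#' @param densities Optional named numeric vector of per-gene signal
#'   density variation to attach.
#' @param display_scale Multiplier applied to |loading| (default 100).
#' @return `data.frame` of class `pc_score_table` sorted by descending
#'   `pc_score`.
#' @export
gene_pc_scores <- function(loadings_pc1, densities = NULL,
                           display_scale = 100) {
  stopifnot(!is.null(names(loadings_pc1)))
  out <- data.frame(gene = names(loadings_pc1),
                    pc_score = abs(loadings_pc1) * display_scale,
                    stringsAsFactors = FALSE)
  out$signal_density_variation <- if (!is.null(densities)) {
    as.numeric(densities[out$gene])
  } else NA_real_
  out <- out[order(-out$pc_score), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pc_score_table", "data.frame")
  out
}
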