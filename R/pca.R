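#' Transposed principal component analysis
#'
#' PCA in which genes are the statistical units (observations) and samples
#' are the variables — the reverse of the usual transcriptomics convention.
#' With many more genes than samples this is the better-conditioned
#' direction.  The decomposition is an eigendecomposition of the samples x
#' samples covariance (optionally correlation) matrix of the genes x samples
#' matrix after per-variable (per-sample) mean centering.  Because every
#' sample shares the same gene-abundance profile, the first component
#' typically absorbs nearly all variance (the "tissue type attractor");
#' group differences live in the minor components.
#'
#' Gene scores are the projections of the (centered) gene rows onto each
#' component; factor loadings are the Pearson correlations between each
#' original sample column and each component's score vector.  Components are
#' ordered by decreasing eigenvalue and each is oriented so that its
#' largest-magnitude gene score is positive, making signs deterministic.
#'
#' @param matrix genes x samples expression matrix (>= 2 genes, >= 2 samples).
#' @param center per-sample mean centering (default `TRUE`).
#' @param scale if `TRUE`, per-sample unit-variance scaling (correlation
#'   PCA); covariance PCA is the default.
#' @return Object of class `transpose_pca`: `eigenvalues`, `variance_fraction`
#'   (sums to 1), `scores` (genes x components), `loadings` (samples x
#'   components, the factor loadings), `center`, `scale`.
#' @export
transpose_pca <- function(matrix, center = TRUE, scale = FALSE) {
  assert_expression_matrix(matrix)
  if (nrow(matrix) < 2L || ncol(matrix) < 2L) {
    stopf("transposed PCA needs at least 2 genes and 2 samples")
  }
  sds <- apply(matrix, 2L, sd)
  if (all(sds == 0)) stopf("degenerate matrix: all samples are constant")
  if (scale && any(sds == 0)) {
    stopf("correlation PCA undefined: constant sample column present")
  }
  xc <- scale(matrix, center = center, scale = scale)
  cv <- crossprod(xc) / (nrow(matrix) - 1L)
  eig <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  scores <- xc %*% vecs
  # deterministic orientation: dominant gene score positive per component
  for (k in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, k]))
    if (scores[i, k] < 0) {
      scores[, k] <- -scores[, k]
      vecs[, k] <- -vecs[, k]
    }
  }
  score_sd <- apply(scores, 2L, sd)
  loadings <- base::matrix(0, ncol(matrix), ncol(scores))
  nz <- score_sd > 0
  loadings[, nz] <- cor(matrix, scores[, nz, drop = FALSE])
  dimnames(scores) <- list(rownames(matrix),
                           paste0("PC", seq_len(ncol(scores))))
  dimnames(loadings) <- list(colnames(matrix), colnames(scores))
  out <- list(eigenvalues = vals,
              variance_fraction = if (sum(vals) > 0) vals / sum(vals) else vals,
              scores = scores, loadings = loadings,
              rotation = vecs, center = center, scale = scale,
              n_genes = nrow(matrix), sample_ids = colnames(matrix))
  class(out) <- "transpose_pca"
  out
}

#' @export
print.transpose_pca <- function(x, ...) {
  cat(sprintf("Transposed PCA: %d genes as units, %d samples as variables\n",
              x$n_genes, length(x$sample_ids)))
  vf <- x$variance_fraction
  cat(sprintf("  variance fractions: PC1 %.1f%%, PC2 %.1f%%, PC3 %.1f%%\n",
              100 * vf[1], 100 * vf[min(2, length(vf))],
              100 * vf[min(3, length(vf))]))
  invisible(x)
}

#' @export
summary.transpose_pca <- function(object, ...) {
  data.frame(component = seq_along(object$eigenvalues),
             eigenvalue = object$eigenvalues,
             variance_fraction = object$variance_fraction,
             cumulative = cumsum(object$variance_fraction))
}

#' Select the component whose factor loadings best separate the groups
#'
#' Realises "linear discriminant analysis on the factor loadings" in its
#' one-dimensional form: for each eligible component the Fisher discriminant
#' ratio of its loadings — squared between-group mean difference over pooled
#' within-group variance — is computed, and the maximising component is
#' returned.  The first component is excluded by default because it carries
#' the shared tissue profile, not group differences.
#'
#' @param decomp a [transpose_pca()] decomposition.
#' @param annotation sample annotation over the same samples.
#' @param exclude_first drop component 1 from consideration (default `TRUE`).
#' @param floor separation values at or below this floor flag the selection
#'   as non-discriminating (default 0).
#' @return Object of class `discriminant_selection`: `component` (index of
#'   the best component), `separation` (named vector of Fisher ratios over
#'   eligible components), `discriminating` (logical).
#' @export
select_discriminant_component <- function(decomp, annotation,
                                          exclude_first = TRUE, floor = 0) {
  if (!inherits(decomp, "transpose_pca")) stopf("'decomp' must be a transpose_pca object")
  assert_annotation(annotation, decomp$sample_ids)
  grp <- annotation$group[match(decomp$sample_ids, annotation$sample_id)]
  labs <- unique(grp)
  n1 <- sum(grp == labs[1]); n2 <- sum(grp == labs[2])
  if (n1 < 2L || n2 < 2L) stopf("each group needs >= 2 samples for discriminant selection")
  eligible <- seq_len(ncol(decomp$loadings))
  if (exclude_first) eligible <- eligible[-1L]
  sep <- vapply(eligible, function(k) {
    fl <- decomp$loadings[, k]
    a <- fl[grp == labs[1]]; b <- fl[grp == labs[2]]
    pooled <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
    d2 <- (mean(a) - mean(b))^2
    if (pooled == 0) {
      if (d2 == 0) 0 else Inf
    } else d2 / pooled
  }, numeric(1))
  names(sep) <- paste0("PC", eligible)
  best <- eligible[which.max(sep)]
  out <- list(component = best, separation = sep,
              discriminating = max(sep) > floor, floor = floor,
              groups = labs)
  class(out) <- "discriminant_selection"
  out
}

#' @export
print.discriminant_selection <- function(x, ...) {
  cat(sprintf("Discriminant component: PC%d (Fisher ratio %.3g)%s\n",
              x$component, max(x$separation),
              if (x$discriminating) "" else " [below floor: non-discriminating]"))
  invisible(x)
}

#' Rank genes by absolute component score
#'
#' @param decomp a [transpose_pca()] decomposition.
#' @param component component index whose scores to rank on.
#' @param k list length (default 100); if larger than the gene count the
#'   full ranking is returned.
#' @return data.frame `rank`, `gene_id`, `score`, sorted by `|score|`
#'   descending, ties broken by gene ID lexicographic order.
#' @export
rank_genes_by_score <- function(decomp, component, k = 100) {
  if (!inherits(decomp, "transpose_pca")) stopf("'decomp' must be a transpose_pca object")
  if (!is_count(component) || component < 1 ||
      component > ncol(decomp$scores)) {
    stopf("invalid component index: %s", format(component))
  }
  if (!is_count(k) || k < 1) stopf("'k' must be a positive count")
  s <- decomp$scores[, component]
  ord <- order(-abs(s), names(s), method = "radix")
  n <- min(k, length(s))
  data.frame(rank = seq_len(n), gene_id = names(s)[ord][seq_len(n)],
             score = s[ord][seq_len(n)],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classical multidimensional scaling of samples
#'
#' Classical (Torgerson) scaling of the pairwise Euclidean distances between
#' sample expression vectors, via `stats::cmdscale`; equivalent up to sign
#' and rotation to the leading principal coordinates.  Used as an
#' unsupervised quality-control view of sample segregation.
#'
#' @param matrix genes x samples expression matrix.
#' @param n_dims embedding dimension (default 3); must be below the sample
#'   count.
#' @return samples x `n_dims` coordinate matrix.
#' @export
classical_mds <- function(matrix, n_dims = 3) {
  assert_expression_matrix(matrix)
  if (!is_count(n_dims) || n_dims < 1) stopf("'n_dims' must be a positive count")
  if (n_dims >= ncol(matrix)) {
    stopf("'n_dims' (%d) must be smaller than the sample count (%d)",
          n_dims, ncol(matrix))
  }
  d <- dist(t(matrix))
  coords <- cmdscale(d, k = n_dims)
  # cmdscale may drop trailing zero-eigenvalue axes (e.g. duplicated points)
  if (ncol(coords) < n_dims) {
    coords <- cbind(coords, base::matrix(0, nrow(coords), n_dims - ncol(coords)))
  }
  rownames(coords) <- colnames(matrix)
  colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
  coords
}
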