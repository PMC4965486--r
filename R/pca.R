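#' Principal component analysis of a genotype matrix
#'
#' Centers marker columns (covariance PCA; unit-scaling optional) and takes
#' the singular value decomposition.  Components are oriented so that each
#' loading vector's largest-magnitude entry is positive, making the output
#' deterministic.
#'
#' @param g an imputed [geno_matrix].
#' @param k number of components to keep (default `min(n, p)`).
#' @param scale if `TRUE`, scale marker columns to unit variance.
#' @return Object of class `geno_pca`: `scores` (`n x k`), `prop_var`
#'   (proportion of total variance per kept component), `k`.
#' @export
geno_pca <- function(g, k = NULL, scale = FALSE) {
  X <- g$dosages
  if (anyNA(X)) stop("PCA requires an imputed genotype matrix")
  sds <- apply(X, 2, stats::sd)
  if (all(sds == 0)) stop("constant genotype matrix")
  if (scale) {
    keep <- sds > 0
    X <- X[, keep, drop = FALSE]
    sds <- sds[keep]
  }
  Xc <- scale(X, center = TRUE, scale = if (scale) sds else FALSE)
  full <- min(dim(Xc))
  if (is.null(k)) k <- full
  if (k > full) stop("k exceeds min(n_lines, n_snps)")
  sv <- svd(Xc, nu = k, nv = k)
  ## deterministic sign: largest-|loading| entry positive
  for (j in seq_len(k)) {
    piv <- which.max(abs(sv$v[, j]))
    if (sv$v[piv, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  dimnames(scores) <- list(g$line_ids, paste0("PC", seq_len(k)))
  structure(list(scores = scores,
                 prop_var = sv$d[seq_len(k)]^2 / sum(sv$d^2),
                 k = k),
            class = "geno_pca")
}

#' @export
print.geno_pca <- function(x, ...) {
  cat(sprintf("genotype PCA: %d components; PC1+PC2 explain %.1f%% of variance\n",
              x$k, 100 * sum(x$prop_var[seq_len(min(2, x$k))])))
  invisible(x)
}

#' Split lines into two subpopulations along PC1
#'
#' Deterministic one-dimensional 2-means on the PC1 scores, initialized at
#' the two extreme scores; the cluster with the lower center is labelled 1.
#'
#' @param pca a [geno_pca()] result with `k >= 1`.
#' @return Integer vector of group labels (1 or 2), named by line.
#' @export
assign_subpops <- function(pca) {
  s <- pca$scores[, 1]
  if (length(unique(s)) < 2) stop("fewer than 2 distinct PC1 scores")
  centers <- c(min(s), max(s))
  for (iter in 1:100) {
    lab <- ifelse(abs(s - centers[1]) <= abs(s - centers[2]), 1L, 2L)
    new_centers <- c(mean(s[lab == 1L]), mean(s[lab == 2L]))
    if (anyNA(new_centers)) break
    if (isTRUE(all.equal(new_centers, centers))) break
    centers <- new_centers
  }
  if (min(table(lab)) == 1) warning("singleton subpopulation")
  stats::setNames(lab, rownames(pca$scores))
}
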