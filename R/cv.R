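#' Cross-validated genomic prediction accuracy
#'
#' Five-fold cross-validation of the RR-BLUP model with replicate
#' resampling.  Per replicate, lines are partitioned at random into
#' `n_folds` near-equal folds; marker effects are fitted on the training
#' folds and used to predict the held-out fold; `r_MP` is the Pearson
#' correlation between predicted and observed values, computed per fold and
#' averaged over folds (`pooling = "per_fold_mean"`, default) or computed
#' once over all held-out predictions (`"pooled"`).  The prediction accuracy
#' `r_GS = r_MP / sqrt(H2)` standardizes `r_MP` by the square root of the
#' broad-sense heritability of the trait.  `r_GS` is not truncated at 1;
#' chance values above 1 are kept and flagged.
#'
#' Replicate `r` draws from the substream `(seed, r)`, so results are
#' reproducible independently of `n_replicates`.
#'
#' @param y named vector of line BLUEs aligned to the rows of `X`.
#' @param X a [geno_matrix] (imputed) or dosage matrix.
#' @param vc a [fit_varcomp()] result (supplies `lambda` and `H2`).
#' @param n_folds folds per replicate, default 5.
#' @param n_replicates replicates, default 500.
#' @param seed integer seed governing fold draws and marker draws.
#' @param marker_subset optional fixed marker subset (column indices or snp
#'   ids) used in every replicate.
#' @param subset_fn optional function of a replicate seed returning the
#'   marker subset for that replicate (used by random-sampling sweeps);
#'   overrides `marker_subset`.
#' @param pooling `"per_fold_mean"` or `"pooled"`.
#' @param truth optional vector of true genetic values aligned to `y`; when
#'   given, the correlation between held-out predictions and `truth` is
#'   computed on the same folds (calibration of the `sqrt(H2)`
#'   standardization) and returned as `mean_r_truth`.
#' @return Object of class `cv_result`: data frame `replicates`
#'   (`replicate`, `r_MP`, `r_GS`), `mean_r_GS`, `sd_r_GS`, `mean_r_MP`,
#'   `H2`, fold/replicate counts, and `n_above_1` (replicates with
#'   `r_GS > 1`).
#' @export
run_cv <- function(y, X, vc, n_folds = 5, n_replicates = 500, seed = 1,
                   marker_subset = NULL, subset_fn = NULL,
                   pooling = c("per_fold_mean", "pooled"), truth = NULL) {
  pooling <- match.arg(pooling)
  Xm <- if (inherits(X, "geno_matrix")) X$dosages else as.matrix(X)
  n <- nrow(Xm)
  if (length(y) != n) stop("y and X are not aligned")
  if (is.na(vc$H2) || vc$H2 <= 0) stop("H2 must be positive to standardize r_MP")
  if (n_folds < 2) stop("need at least 2 folds")
  if (floor(n / n_folds) < 3) stop("fold size below 3 lines")
  if (is.character(marker_subset)) marker_subset <- match(marker_subset, colnames(Xm))
  fixed_idx <- marker_subset %||% seq_len(ncol(Xm))
  K_fixed <- if (is.null(subset_fn)) tcrossprod(Xm[, fixed_idx, drop = FALSE]) else NULL
  res <- matrix(NA_real_, n_replicates, 2)
  r_truth <- if (is.null(truth)) NULL else numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    rs <- substream_seed(seed, paste0("rep", r))
    rep_out <- with_seed(rs, {
      idx <- if (is.null(subset_fn)) fixed_idx else subset_fn(rs)
      if (is.character(idx)) idx <- match(idx, colnames(Xm))
      K <- if (is.null(subset_fn)) K_fixed else tcrossprod(Xm[, idx, drop = FALSE])
      lambda <- (vc$sigma2_e / vc$l) / (vc$sigma2_G / length(idx))
      if (lambda == 0) lambda <- 1e-10
      cv_one_replicate(y, K, lambda, n_folds, pooling, truth = truth)
    })
    res[r, ] <- c(rep_out[1], rep_out[1] / sqrt(vc$H2))
    if (!is.null(truth)) r_truth[r] <- rep_out[2]
  }
  replicates <- data.frame(replicate = seq_len(n_replicates),
                           r_MP = res[, 1], r_GS = res[, 2])
  if (!is.null(truth)) replicates$r_truth <- r_truth
  structure(list(replicates = replicates,
                 mean_r_MP = mean(res[, 1]),
                 mean_r_GS = mean(res[, 2]),
                 sd_r_GS = stats::sd(res[, 2]),
                 H2 = vc$H2, n_folds = n_folds, n_replicates = n_replicates,
                 pooling = pooling,
                 mean_r_truth = if (is.null(truth)) NA_real_ else mean(r_truth),
                 n_above_1 = sum(res[, 2] > 1)),
            class = "cv_result")
}

## one CV replicate on a precomputed kernel; RNG state supplied by caller
cv_one_replicate <- function(y, K, lambda, n_folds, pooling, lines = NULL,
                             truth = NULL) {
  if (is.null(lines)) lines <- seq_len(nrow(K))
  n <- length(lines)
  fold <- sample(rep(seq_len(n_folds), length.out = n))
  preds <- obs <- tru <- numeric(0)
  fold_r <- fold_rt <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    te <- lines[fold == f]
    tr <- lines[fold != f]
    V <- K[tr, tr] + lambda * diag(length(tr))
    R <- chol(V)
    solveV <- function(b) backsolve(R, backsolve(R, b, transpose = TRUE))
    Vi1 <- solveV(rep(1, length(tr)))
    mu <- sum(Vi1 * y[tr]) / sum(Vi1)
    w <- solveV(y[tr] - mu)
    pred <- mu + as.vector(K[te, tr, drop = FALSE] %*% w)
    fold_r[f] <- stats::cor(pred, y[te])
    if (!is.null(truth)) {
      fold_rt[f] <- stats::cor(pred, truth[te])
      tru <- c(tru, truth[te])
    }
    preds <- c(preds, pred); obs <- c(obs, y[te])
  }
  r_mp <- if (pooling == "per_fold_mean") mean(fold_r) else stats::cor(preds, obs)
  if (is.null(truth)) return(r_mp)
  r_tr <- if (pooling == "per_fold_mean") mean(fold_rt) else stats::cor(preds, tru)
  c(r_mp, r_tr)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV, %d replicates (%s pooling)\n",
              x$n_folds, x$n_replicates, x$pooling))
  cat(sprintf("  mean r_MP = %.4f; mean r_GS = %.4f (sd %.4f), H2 = %.4f\n",
              x$mean_r_MP, x$mean_r_GS, x$sd_r_GS, x$H2))
  if (x$n_above_1 > 0) cat("  note:", x$n_above_1, "replicate(s) with r_GS > 1\n")
  invisible(x)
}

#' Within-subpopulation accuracy contrast
#'
#' Contrasts the cross-validated accuracy within one subpopulation against
#' the accuracy of a size-matched random subset of the full panel (re-drawn
#' every replicate), reporting both and the percent decrease
#' `100 * (r_full - r_group) / r_full`.
#'
#' @inheritParams run_cv
#' @param groups per-line group labels aligned to `y`.
#' @param target_group the label of the subpopulation of interest; needs at
#'   least `2 * n_folds` lines.
#' @return List of class `cv_contrast`: `cv_group`, `cv_matched` (each a
#'   replicate-level data frame plus mean), and `pct_decrease`.
#' @export
cv_subpop_contrast <- function(y, X, vc, groups, target_group, n_folds = 5,
                               n_replicates = 100, seed = 1,
                               pooling = c("per_fold_mean", "pooled")) {
  pooling <- match.arg(pooling)
  Xm <- if (inherits(X, "geno_matrix")) X$dosages else as.matrix(X)
  in_group <- which(as.character(groups) == as.character(target_group))
  m <- length(in_group)
  if (m < 2 * n_folds) stop("target group too small for ", n_folds, "-fold CV")
  if (is.na(vc$H2) || vc$H2 <= 0) stop("H2 must be positive")
  K <- tcrossprod(Xm)
  lambda <- (vc$sigma2_e / vc$l) / (vc$sigma2_G / ncol(Xm))
  if (lambda == 0) lambda <- 1e-10
  rg <- rm_ <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    rs <- substream_seed(seed, paste0("contrast", r))
    vals <- with_seed(rs, {
      a <- cv_one_replicate(y, K, lambda, n_folds, pooling, lines = in_group)
      matched <- sort(sample(nrow(Xm), m))
      b <- cv_one_replicate(y, K, lambda, n_folds, pooling, lines = matched)
      c(a, b)
    })
    rg[r] <- vals[1]; rm_[r] <- vals[2]
  }
  h <- sqrt(vc$H2)
  out <- list(group = target_group, n_group = m,
              r_GS_group = mean(rg) / h,
              r_GS_matched = mean(rm_) / h,
              pct_decrease = 100 * (mean(rm_) - mean(rg)) / mean(rm_),
              replicates = data.frame(replicate = seq_len(n_replicates),
                                      r_GS_group = rg / h,
                                      r_GS_matched = rm_ / h))
  class(out) <- "cv_contrast"
  out
}

#' @export
print.cv_contrast <- function(x, ...) {
  cat(sprintf("CV accuracy within group '%s' (n = %d): r_GS = %.4f\n",
              x$group, x$n_group, x$r_GS_group))
  cat(sprintf("  size-matched random subset of the panel: r_GS = %.4f\n",
              x$r_GS_matched))
  cat(sprintf("  percent decrease: %.2f%%\n", x$pct_decrease))
  invisible(x)
}
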