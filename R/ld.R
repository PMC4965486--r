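#' Pairwise linkage disequilibrium within chromosomes
#'
#' Treats each inbred line as one haplotype (no phasing): alleles are
#' `dosage / 2`.  For every within-chromosome marker pair (optionally capped
#' by physical distance) it reports `r2`, the squared Pearson correlation of
#' the allele vectors, and `dprime = |D| / Dmax` from the 2x2 haplotype
#' frequencies.  Residual heterozygous or fractional calls are dropped
#' pairwise with a warning; monomorphic markers are skipped.
#'
#' @param g an imputed [geno_matrix].
#' @param max_distance optional bp cap on pair distance.
#' @param maf_min minimum per-marker minor allele frequency for a marker to
#'   enter pairs (default 0: all polymorphic markers).
#' @return Data frame with columns `chrom`, `i`, `j` (global marker column
#'   indices), `snp_i`, `snp_j`, `distance` (bp), `r2`, `dprime`.
#' @export
pairwise_ld <- function(g, max_distance = NULL, maf_min = 0) {
  d <- g$dosages
  frac <- !is.na(d) & d != 0 & d != 2
  if (any(frac)) {
    warning(sum(frac), " heterozygous/fractional calls dropped pairwise")
    d[frac] <- NA
  }
  out <- vector("list", length(unique(g$map$chrom)))
  names(out) <- unique(g$map$chrom)
  for (ch in unique(g$map$chrom)) {
    cols <- which(g$map$chrom == ch)
    if (length(cols) < 2) next
    X <- d[, cols, drop = FALSE] / 2
    pos <- g$map$pos[cols]
    pA <- colMeans(X, na.rm = TRUE)
    poly <- is.finite(pA) & pA > 0 & pA < 1 & pmin(pA, 1 - pA) >= maf_min
    if (sum(poly) < 2) next
    X <- X[, poly, drop = FALSE]; pos <- pos[poly]; cols <- cols[poly]
    m <- ncol(X)
    pr <- utils::combn(m, 2)
    a <- pr[1, ]; b <- pr[2, ]
    dist <- pos[b] - pos[a]
    if (!is.null(max_distance)) {
      keep <- dist <= max_distance
      a <- a[keep]; b <- b[keep]; dist <- dist[keep]
    }
    if (!length(a)) next
    stat <- ld_pair_stats(X, a, b)
    out[[ch]] <- data.frame(chrom = ch, i = cols[a], j = cols[b],
                            snp_i = g$map$snp_id[cols[a]],
                            snp_j = g$map$snp_id[cols[b]],
                            distance = dist, r2 = stat$r2, dprime = stat$dprime)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(chrom = character(), i = integer(), j = integer(),
                      snp_i = character(), snp_j = character(),
                      distance = numeric(), r2 = numeric(), dprime = numeric())
  }
  rownames(res) <- NULL
  res
}

## r2 and |D'| for marker pairs given an allele matrix (entries 0/1/NA) and
## paired column indices; pairwise-complete over lines
ld_pair_stats <- function(X, a, b) {
  n_pair <- length(a)
  r2 <- dprime <- numeric(n_pair)
  cc <- !is.na(X)
  if (all(cc)) {
    n <- nrow(X)
    P <- colMeans(X)
    J <- crossprod(X) / n
    for (k in seq_len(n_pair)) {
      st <- dpair_from_freqs(J[a[k], b[k]], P[a[k]], P[b[k]])
      r2[k] <- st[1]; dprime[k] <- st[2]
    }
  } else {
    for (k in seq_len(n_pair)) {
      ok <- cc[, a[k]] & cc[, b[k]]
      x <- X[ok, a[k]]; y <- X[ok, b[k]]
      st <- dpair_from_freqs(mean(x * y), mean(x), mean(y))
      r2[k] <- st[1]; dprime[k] <- st[2]
    }
  }
  list(r2 = r2, dprime = dprime)
}

dpair_from_freqs <- function(pAB, pA, pB) {
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) return(c(NA_real_, NA_real_))
  D <- pAB - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else min(pA * pB, (1 - pA) * (1 - pB))
  c(D^2 / (pA * (1 - pA) * pB * (1 - pB)),
    if (dmax > 0) abs(D) / dmax else 0)
}

#' One-sided 90% confidence bounds on |D'|
#'
#' Computes the likelihood of the four observed haplotype counts on a grid of
#' |D'| in `{0, 0.001, ..., 1}` with allele frequencies fixed at their
#' observed values and D carrying the observed sign, normalizes it to a
#' discrete distribution, and returns `ci_low` = the smallest grid value with
#' cumulative mass >= 0.05 and `ci_high` = the smallest with cumulative mass
#' >= 0.95 (the interval used by the Gabriel block definition).
#'
#' @param counts haplotype counts, length 4 in the order `AB, Ab, aB, ab`.
#' @param grid_step grid resolution on |D'|, default 0.001.
#' @return Numeric vector `c(ci_low, ci_high)`.
#' @export
dprime_ci <- function(counts, grid_step = 0.001) {
  stopifnot(length(counts) == 4, all(counts >= 0))
  n <- sum(counts)
  pA <- (counts[1] + counts[2]) / n
  pB <- (counts[1] + counts[3]) / n
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) {
    stop("degenerate haplotype table: a marginal allele count is zero")
  }
  D <- counts[1] / n - pA * pB
  sgn <- if (D >= 0) 1 else -1
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else min(pA * pB, (1 - pA) * (1 - pB))
  grid <- seq(0, 1, by = grid_step)
  Dg <- sgn * grid * dmax
  f11 <- pmax(pA * pB + Dg, 0)
  f12 <- pmax(pA * (1 - pB) - Dg, 0)
  f21 <- pmax((1 - pA) * pB - Dg, 0)
  f22 <- pmax((1 - pA) * (1 - pB) + Dg, 0)
  xlog <- function(cnt, f) {
    if (cnt == 0) return(rep(0, length(f)))
    out <- rep(-Inf, length(f))
    out[f > 0] <- cnt * log(f[f > 0])
    out
  }
  ll <- xlog(counts[1], f11) + xlog(counts[2], f12) +
    xlog(counts[3], f21) + xlog(counts[4], f22)
  lik <- exp(ll - max(ll))
  cum <- cumsum(lik) / sum(lik)
  c(ci_low = grid[which(cum >= 0.05)[1]],
    ci_high = grid[which(cum >= 0.95)[1]])
}

#' LD-decay curve by locally weighted regression
#'
#' Fits r2 against physical distance with local linear regression (tricube
#' weights, via [stats::loess()] with `degree = 1`) and evaluates the fit on
#' a log-spaced distance grid, clipped to `[0, 1]`.
#'
#' @param pairs data frame from [pairwise_ld()] (needs `distance`, `r2`).
#' @param span loess smoothing span, default 0.3.
#' @param grid_n number of grid points.
#' @return Object of class `ld_decay`: data frame `grid` with `distance` and
#'   fitted `r2`, plus the span.  Use [decay_distance()] to read off where
#'   the curve crosses a threshold.
#' @export
ld_decay <- function(pairs, span = 0.3, grid_n = 200) {
  pairs <- pairs[is.finite(pairs$r2) & is.finite(pairs$distance), ]
  if (nrow(pairs) < 100) stop("need at least 100 LD pairs to fit a decay curve")
  if (length(unique(pairs$distance)) == 1) stop("all pair distances identical")
  fit <- stats::loess(r2 ~ distance, data = pairs, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  dmin <- max(min(pairs$distance), 1)
  dmax <- max(pairs$distance)
  grid <- exp(seq(log(dmin), log(dmax), length.out = grid_n))
  fitted <- pmin(pmax(stats::predict(fit, data.frame(distance = grid)), 0), 1)
  structure(list(grid = data.frame(distance = grid, r2 = fitted), span = span),
            class = "ld_decay")
}

#' @export
print.ld_decay <- function(x, ...) {
  d01 <- decay_distance(x, 0.1)
  cat(sprintf("LD-decay curve (span %.2f), %d grid points; r2 < 0.1 beyond %s\n",
              x$span, nrow(x$grid),
              if (is.na(d01)) "the fitted range (never)" else sprintf("%.0f bp", d01)))
  invisible(x)
}

#' @rdname ld_decay
#' @param curve an `ld_decay` object.
#' @param threshold r2 threshold, default 0.1.
#' @return `decay_distance()`: the smallest grid distance where the fitted
#'   curve drops below `threshold`, or `NA` if it never does.
#' @export
decay_distance <- function(curve, threshold = 0.1) {
  below <- which(curve$grid$r2 < threshold)
  if (!length(below)) return(NA_real_)
  curve$grid$distance[below[1]]
}
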