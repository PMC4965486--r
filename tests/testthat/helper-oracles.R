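## Independent oracles used by the unit and acceptance tests.  Each is coded
## as a direct, brute-force transcription of the definition, deliberately
## avoiding the package's own computational shortcuts.

## GLS estimate of fixed line effects with random locations: builds the full
## N x N covariance V = s2L * Zl Zl' + s2e * I and inverts it explicitly.
gls_blues_oracle <- function(pheno, s2L, s2e) {
  line <- factor(pheno$line_id)
  loc <- factor(pheno$location_id)
  X <- stats::model.matrix(~ line - 1)
  Zl <- stats::model.matrix(~ loc - 1)
  V <- s2L * tcrossprod(Zl) + s2e * diag(nrow(X))
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% pheno$value)
  stats::setNames(as.vector(b), levels(line))
}

## Ridge solution by one dense solve of the full (p+1) x (p+1) Henderson
## system, no kernel tricks.
ridge_oracle <- function(y, X, lambda) {
  n <- nrow(X); p <- ncol(X)
  A <- matrix(0, p + 1, p + 1)
  A[1, 1] <- n
  A[1, -1] <- colSums(X)
  A[-1, 1] <- colSums(X)
  A[-1, -1] <- crossprod(X) + lambda * diag(p)
  sol <- solve(A, c(sum(y), as.vector(crossprod(X, y))))
  list(mu = sol[1], alpha = sol[-1])
}

## Brute-force grid likelihood for the |D'| confidence bounds: explicit loop
## over the grid, multinomial likelihood via dmultinom.
dprime_ci_oracle <- function(counts, grid_step = 0.001) {
  n <- sum(counts)
  pA <- (counts[1] + counts[2]) / n
  pB <- (counts[1] + counts[3]) / n
  D <- counts[1] / n - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else min(pA * pB, (1 - pA) * (1 - pB))
  sgn <- if (D >= 0) 1 else -1
  grid <- seq(0, 1, by = grid_step)
  lik <- numeric(length(grid))
  for (k in seq_along(grid)) {
    Dg <- sgn * grid[k] * dmax
    f <- c(pA * pB + Dg, pA * (1 - pB) - Dg, (1 - pA) * pB - Dg, (1 - pA) * (1 - pB) + Dg)
    f <- pmax(f, 0)
    lik[k] <- if (any(f == 0 & counts > 0)) 0 else stats::dmultinom(counts, prob = f)
  }
  cum <- cumsum(lik) / sum(lik)
  c(grid[which(cum >= 0.05)[1]], grid[which(cum >= 0.95)[1]])
}

## Balanced two-way ANOVA variance-component estimators.
anova_vc_oracle <- function(pheno) {
  line <- factor(pheno$line_id)
  loc <- factor(pheno$location_id)
  n <- nlevels(line); l <- nlevels(loc)
  tab <- stats::anova(stats::lm(value ~ line + loc, data = transform(pheno, line = line, loc = loc)))
  mse <- tab["Residuals", "Mean Sq"]
  list(sigma2_e = mse,
       sigma2_G = (tab["line", "Mean Sq"] - mse) / l,
       sigma2_L = (tab["loc", "Mean Sq"] - mse) / n)
}

## Planted-block truth trimmed to markers the Gabriel caller can see
## (MAF >= maf_min); segments reduced below 2 visible markers are dropped.
trim_truth_blocks <- function(truth, geno, maf_min = 0.05) {
  ms <- marker_stats(geno)
  common <- which(ms$maf >= maf_min)
  tb <- truth$block_boundaries
  keep <- logical(nrow(tb))
  for (k in seq_len(nrow(tb))) {
    vis <- common[common >= tb$first[k] & common <= tb$last[k]]
    if (length(vis) >= 2) {
      tb$first[k] <- min(vis); tb$last[k] <- max(vis); keep[k] <- TRUE
    }
  }
  tb[keep, , drop = FALSE]
}

## Fraction of truth blocks matched by a called block within +-1 marker at
## both ends.
block_recovery <- function(called, truth_blocks) {
  if (nrow(truth_blocks) == 0) return(NA_real_)
  hits <- vapply(seq_len(nrow(truth_blocks)), function(k) {
    any(abs(called$blocks$first - truth_blocks$first[k]) <= 1 &
          abs(called$blocks$last - truth_blocks$last[k]) <= 1)
  }, logical(1))
  mean(hits)
}

## Small reusable simulated panel for cross-module tests.
small_panel <- function(seed = 11, n_lines = 120, n_snps = 300, h2 = 0.63,
                        n_locations = 8, ...) {
  cfg <- sim_config(n_lines = n_lines, n_snps = n_snps, n_chromosomes = 4,
                    chrom_length_bp = 4e6, recomb_hotspot_rate = 2.5,
                    n_qtl = min(60, n_snps), target_h2 = h2,
                    n_locations = n_locations, master_seed = seed, ...)
  sg <- simulate_genotypes(cfg)
  sp <- simulate_phenotypes(sg$geno, sg$truth, cfg)
  list(cfg = cfg, geno = sg$geno, pheno = sp$pheno, truth = sp$truth)
}
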