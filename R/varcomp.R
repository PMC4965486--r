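#' REML variance components for the two-way random model
#'
#' Fits `y_ij = mu + L_i + G_j + e_ij` with random location and genotype
#' effects to long-format entry means, by EM on Henderson's mixed-model
#' equations followed by a direct REML profile-likelihood polish (L-BFGS-B on
#' log-variances).  Convergence: maximum relative change of the three
#' components below `tol` or `max_iter` EM iterations; negative estimates are
#' truncated at zero.  Broad-sense heritability is reported on the entry-mean
#' basis, `H2 = sigma2_G / (sigma2_G + sigma2_e / l)` with `l` the number of
#' distinct locations.
#'
#' @param pheno data frame with columns `line_id`, `location_id`, `value`
#'   (at most one record per line x location).
#' @param tol relative-change convergence tolerance for the EM stage.
#' @param max_iter maximum EM iterations.
#' @param trace if `TRUE`, keep the per-iteration REML log-likelihoods in the
#'   returned object (`$em_loglik`).
#' @return An object of class `varcomp`: `sigma2_G`, `sigma2_L`, `sigma2_e`,
#'   `mu`, `l`, `H2`, `loglik`, `converged`, `n_iterations`, and the data
#'   dimensions.
#' @export
fit_varcomp <- function(pheno, tol = 1e-8, max_iter = 500, trace = FALSE) {
  pheno <- check_pheno(pheno)
  line <- factor(pheno$line_id)
  loc <- factor(pheno$location_id)
  y <- pheno$value
  q <- nlevels(line)
  l <- nlevels(loc)
  if (q < 2) stop("need at least 2 lines")
  if (!design_connected(line, loc)) {
    stop("design is not connected: lines and locations form disjoint blocks")
  }
  if (l < 2) {
    warning("fewer than 2 locations: sigma2_L is inestimable; fitting the reduced model without a location term")
    return(fit_varcomp_one_way(y, line, trace))
  }
  N <- length(y)
  Zg <- stats::model.matrix(~ line - 1)
  Zl <- stats::model.matrix(~ loc - 1)
  W <- cbind(1, Zg, Zl)
  WtW <- crossprod(W)
  Wty <- crossprod(W, y)
  yty <- sum(y^2)
  vy <- stats::var(y)
  eps <- 1e-10 * vy
  ig <- 1 + seq_len(q)
  il <- 1 + q + seq_len(l)

  ess_and_logdet <- function(sg, sl, se) {
    A <- WtW
    diag(A)[ig] <- diag(WtW)[ig] + se / sg
    diag(A)[il] <- diag(WtW)[il] + se / sl
    R <- chol(A)
    s <- backsolve(R, backsolve(R, Wty, transpose = TRUE))
    list(s = s, ess = yty - sum(s * Wty), logdetA = 2 * sum(log(diag(R))), R = R)
  }
  reml_ll <- function(sg, sl, se) {
    h <- ess_and_logdet(sg, sl, se)
    -0.5 * ((N - 1 - q - l) * log(se) + q * log(sg) + l * log(sl) +
              h$logdetA + h$ess / se + (N - 1) * log(2 * pi))
  }

  ## interior starting values: an even split of the phenotypic variance.
  ## (method-of-moments starts can land a component on the zero boundary,
  ## where the EM update is a fixed point and the fit locks up)
  sg <- vy / 3; sl <- vy / 3; se <- vy / 3

  ll_trace <- numeric(0)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    h <- ess_and_logdet(sg, sl, se)
    Ainv <- chol2inv(h$R)
    ghat <- h$s[ig]; uhat <- h$s[il]
    se_new <- max(h$ess / (N - 1), eps)
    sg_new <- max((sum(ghat^2) + se * sum(diag(Ainv)[ig])) / q, eps)
    sl_new <- max((sum(uhat^2) + se * sum(diag(Ainv)[il])) / l, eps)
    if (trace) ll_trace <- c(ll_trace, reml_ll(sg, sl, se))
    delta <- max(abs(c(sg_new - sg, sl_new - sl, se_new - se)) /
                   pmax(abs(c(sg, sl, se)), eps))
    sg <- sg_new; sl <- sl_new; se <- se_new
    if (delta < tol) { converged <- TRUE; break }
  }
  ## direct profile-likelihood refinement near the EM solution
  opt <- stats::optim(log(c(sg, sl, se)),
                      function(par) -reml_ll(exp(par[1]), exp(par[2]), exp(par[3])),
                      method = "L-BFGS-B",
                      lower = log(eps), upper = log(1e8 * max(vy, eps)),
                      control = list(factr = 10))
  v <- exp(opt$par)
  sg <- v[1]; sl <- v[2]; se <- v[3]
  ## boundary truncation: estimates pinned at the floor are reported as 0
  floor_cut <- 10 * eps
  if (sg <= floor_cut) sg <- 0
  if (sl <= floor_cut) sl <- 0
  if (se <= floor_cut) se <- 0
  h2 <- if (sg + se / l > 0) sg / (sg + se / l) else NA_real_
  out <- list(sigma2_G = unname(sg), sigma2_L = unname(sl), sigma2_e = unname(se),
              mu = mean(y), l = l, n_lines = q, n_obs = N,
              H2 = unname(h2),
              loglik = reml_ll(max(sg, eps), max(sl, eps), max(se, eps)),
              converged = converged || opt$convergence == 0,
              n_iterations = it)
  if (trace) out$em_loglik <- ll_trace
  class(out) <- "varcomp"
  out
}

fit_varcomp_one_way <- function(y, line, trace) {
  q <- nlevels(line)
  reps <- table(line)
  if (all(reps == 1)) {
    warning("one observation per line: residual variance inestimable; attributing all variance to genotype")
    sg <- stats::var(y); se <- 0
  } else {
    fit <- stats::anova(stats::lm(y ~ line))
    mse <- fit["Residuals", "Mean Sq"]
    r0 <- (length(y) - sum(reps^2) / length(y)) / (q - 1)
    sg <- max((fit["line", "Mean Sq"] - mse) / r0, 0)
    se <- mse
  }
  out <- list(sigma2_G = sg, sigma2_L = NA_real_, sigma2_e = se,
              mu = mean(y), l = 1L, n_lines = q, n_obs = length(y),
              H2 = if (sg + se > 0) sg / (sg + se) else NA_real_,
              loglik = NA_real_, converged = TRUE, n_iterations = 0L)
  if (trace) out$em_loglik <- numeric(0)
  class(out) <- "varcomp"
  out
}

#' @export
print.varcomp <- function(x, ...) {
  cat("Two-way random model REML fit\n")
  cat(sprintf("  sigma2_G = %.6g  sigma2_L = %.6g  sigma2_e = %.6g\n",
              x$sigma2_G, x$sigma2_L, x$sigma2_e))
  cat(sprintf("  grand mean = %.6g, %d lines x %d locations (%d records)\n",
              x$mu, x$n_lines, x$l, x$n_obs))
  cat(sprintf("  entry-mean heritability H2 = %.4f\n", x$H2))
  if (!x$converged) cat("  WARNING: not converged\n")
  invisible(x)
}

check_pheno <- function(pheno) {
  need <- c("line_id", "location_id", "value")
  if (!all(need %in% names(pheno))) {
    stop("phenotype table must have columns line_id, location_id, value")
  }
  if (any(!is.finite(pheno$value))) stop("phenotype values must be finite")
  if (anyDuplicated(pheno[, c("line_id", "location_id")])) {
    stop("at most one record per line x location")
  }
  pheno
}

design_connected <- function(line, loc) {
  ## union-find over the bipartite line/location incidence
  nl <- nlevels(line); nc <- nlevels(loc)
  parent <- seq_len(nl + nc)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_along(line)) {
    a <- find(as.integer(line[k])); b <- find(nl + as.integer(loc[k]))
    if (a != b) parent[b] <- a
  }
  length(unique(vapply(seq_len(nl + nc), find, integer(1)))) == 1L
}

#' Best linear unbiased estimates of line means
#'
#' Solves the mixed-model equations with genotype fixed (cell-means
#' parameterization, so each BLUE estimates `mu + G_j`) and location random
#' with variance ratio `sigma2_L / sigma2_e` taken from a [fit_varcomp()]
#' result.  On balanced complete data the BLUE equals the line's arithmetic
#' mean across locations.
#'
#' @param pheno phenotype data frame (`line_id`, `location_id`, `value`).
#' @param vc a [fit_varcomp()] result on the same data.
#' @return Named numeric vector of per-line BLUEs (trait units), in the order
#'   of `sort(unique(line_id))` as produced by `factor()`.
#' @export
compute_blues <- function(pheno, vc) {
  pheno <- check_pheno(pheno)
  line <- factor(pheno$line_id)
  loc <- factor(pheno$location_id)
  y <- pheno$value
  q <- nlevels(line); l <- nlevels(loc)
  if (l == 1 || is.na(vc$sigma2_L) || vc$sigma2_L <= 0 || vc$sigma2_e <= 0) {
    ## zero location variance (or a single location): locations drop out
    m <- tapply(y, line, mean)
    return(stats::setNames(as.vector(m), names(m))[levels(line)])
  }
  k <- vc$sigma2_e / vc$sigma2_L
  Xg <- stats::model.matrix(~ line - 1)
  Zl <- stats::model.matrix(~ loc - 1)
  A <- rbind(cbind(crossprod(Xg), crossprod(Xg, Zl)),
             cbind(crossprod(Zl, Xg), crossprod(Zl) + k * diag(l)))
  rhs <- c(crossprod(Xg, y), crossprod(Zl, y))
  s <- solve(A, rhs)
  stats::setNames(s[seq_len(q)], levels(line))
}

#' Welch t contrast between two line groups
#'
#' Compares the BLUEs of two subpopulations with an unequal-variance
#' (Welch) two-sample t test.
#'
#' @param blues named vector of line BLUEs.
#' @param groups per-line group labels (same order/length as `blues`);
#'   exactly two distinct labels, each with at least two lines.
#' @return List of class `subpop_contrast`: per-group `means`, `se`, `n`,
#'   the `t` statistic, `df`, and `p_value`.
#' @export
contrast_subpopulations <- function(blues, groups) {
  groups <- as.character(groups)
  stopifnot(length(groups) == length(blues))
  gl <- unique(groups)
  if (length(gl) != 2) stop("exactly two groups required")
  a <- blues[groups == gl[1]]; b <- blues[groups == gl[2]]
  if (length(a) < 2 || length(b) < 2) stop("each group needs at least 2 lines")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("zero within-group variance in both groups: t statistic undefined")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  out <- list(groups = gl,
              means = stats::setNames(c(mean(a), mean(b)), gl),
              se = stats::setNames(c(stats::sd(a) / sqrt(length(a)),
                                     stats::sd(b) / sqrt(length(b))), gl),
              n = stats::setNames(c(length(a), length(b)), gl),
              t = unname(tt$statistic), df = unname(tt$parameter),
              p_value = tt$p.value)
  class(out) <- "subpop_contrast"
  out
}

#' @export
print.subpop_contrast <- function(x, ...) {
  cat("Welch two-sample t contrast of line BLUEs\n")
  for (g in x$groups) {
    cat(sprintf("  %s: n = %d, mean = %.4f +/- %.4f (SE)\n",
                g, x$n[g], x$means[g], x$se[g]))
  }
  cat(sprintf("  t = %.3f, df = %.1f, p = %.3g\n", x$t, x$df, x$p_value))
  invisible(x)
}
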