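#' Ridge-regression BLUP of marker effects
#'
#' Fits the genomic prediction model `y = mu + X alpha + e` with
#' `alpha ~ N(0, I_p sigma2_alpha)`, `sigma2_alpha = sigma2_G / p`, and
#' residual variance `sigma2_e / l` (the BLUEs are means over `l`
#' locations).  The ridge parameter is therefore fixed from the phenotypic
#' variance components, not re-estimated:
#' `lambda = (sigma2_e / l) / (sigma2_G / p)`.
#'
#' `(mu, alpha)` solve Henderson's equations
#' `[[n, 1'X], [X'1, X'X + lambda I]] (mu, alpha) = (1'y, X'y)`.
#' When `p > n` the identical solution is obtained through the n x n kernel
#' system: with `V = X X' + lambda I`,
#' `mu = (1' V^-1 1)^-1 1' V^-1 y` and `alpha = X' V^-1 (y - mu)`.
#'
#' @param y named vector of line BLUEs, aligned to the rows of `X`.
#' @param X a [geno_matrix] of the training lines (imputed; fractional
#'   dosages allowed), or a plain numeric matrix.
#' @param vc a [fit_varcomp()] result supplying `sigma2_G`, `sigma2_e`, `l`;
#'   alternatively pass `lambda` directly.
#' @param lambda optional explicit ridge parameter (overrides `vc`).
#' @param route `"auto"` picks marker-space when `p <= n`, kernel-space
#'   otherwise; `"marker"` or `"kernel"` force a route (they agree to
#'   numerical precision).
#' @return Object of class `rrblup`: `mu_hat`, `alpha_hat` (named per
#'   marker), `lambda`, `sigma2_alpha`, `sigma2_resid`, `marker_ids`,
#'   `fitted`, `route`.
#' @export
rrblup <- function(y, X, vc = NULL, lambda = NULL,
                   route = c("auto", "marker", "kernel")) {
  route <- match.arg(route)
  Xm <- if (inherits(X, "geno_matrix")) X$dosages else as.matrix(X)
  n <- nrow(Xm); p <- ncol(Xm)
  if (length(y) != n) stop("y and X are not aligned: ", length(y), " vs ", n, " lines")
  if (anyNA(Xm)) stop("X contains missing dosages; impute first")
  s2a <- s2r <- NA_real_
  if (is.null(lambda)) {
    if (is.null(vc)) stop("supply either vc or lambda")
    if (vc$sigma2_G <= 0) {
      stop("sigma2_G = 0: lambda = (sigma2_e/l)/(sigma2_G/p) is undefined")
    }
    s2a <- vc$sigma2_G / p
    s2r <- vc$sigma2_e / vc$l
    lambda <- s2r / s2a
    if (lambda == 0) lambda <- 1e-10   # guard exact zero residual variance
  }
  if (lambda <= 0) stop("lambda must be positive")
  if (all(Xm == 0) || max(abs(Xm)) == 0) stop("rank-0 marker matrix")
  if (route == "auto") route <- if (p <= n) "marker" else "kernel"
  cn <- colnames(Xm) %||% paste0("m", seq_len(p))
  if (route == "marker") {
    A <- rbind(cbind(n, t(colSums(Xm))),
               cbind(colSums(Xm), crossprod(Xm) + lambda * diag(p)))
    rhs <- c(sum(y), crossprod(Xm, y))
    sol <- solve(A, rhs)
    mu <- sol[1]
    alpha <- sol[-1]
  } else {
    V <- tcrossprod(Xm) + lambda * diag(n)
    Vi1 <- solve(V, rep(1, n))
    Viy <- solve(V, y)
    mu <- sum(Vi1 * y) / sum(Vi1)
    alpha <- as.vector(crossprod(Xm, Viy - Vi1 * mu))
  }
  fitted <- as.vector(mu + Xm %*% alpha)
  structure(list(mu_hat = unname(mu),
                 alpha_hat = stats::setNames(as.vector(alpha), cn),
                 lambda = lambda,
                 sigma2_alpha = s2a, sigma2_resid = s2r,
                 marker_ids = cn,
                 fitted = stats::setNames(fitted, names(y)),
                 y = y, route = route, n = n, p = p),
            class = "rrblup")
}

#' @export
print.rrblup <- function(x, ...) {
  cat(sprintf("RR-BLUP fit: %d lines x %d markers (%s route)\n", x$n, x$p, x$route))
  cat(sprintf("  mu_hat = %.4f, lambda = %.4g\n", x$mu_hat, x$lambda))
  cat(sprintf("  marker effects: mean |alpha| = %.4g, max |alpha| = %.4g\n",
              mean(abs(x$alpha_hat)), max(abs(x$alpha_hat))))
  invisible(x)
}

#' @export
summary.rrblup <- function(object, ...) {
  r <- object$y - object$fitted
  out <- list(n = object$n, p = object$p, lambda = object$lambda,
              mu_hat = object$mu_hat,
              effect_quantiles = stats::quantile(object$alpha_hat),
              train_cor = stats::cor(object$fitted, object$y),
              resid_sd = stats::sd(r))
  class(out) <- "summary.rrblup"
  out
}

#' @export
print.summary.rrblup <- function(x, ...) {
  cat(sprintf("RR-BLUP: n = %d, p = %d, lambda = %.4g, mu = %.4f\n",
              x$n, x$p, x$lambda, x$mu_hat))
  cat(sprintf("  training correlation %.4f, residual sd %.4g\n",
              x$train_cor, x$resid_sd))
  cat("  marker-effect quantiles:\n")
  print(x$effect_quantiles)
  invisible(x)
}

#' @export
coef.rrblup <- function(object, ...) {
  c("(Intercept)" = object$mu_hat, object$alpha_hat)
}

#' @export
residuals.rrblup <- function(object, ...) object$y - object$fitted

#' Predict genotypic values for new lines
#'
#' @param object an [rrblup] fit.
#' @param newdata a [geno_matrix] or dosage matrix whose markers match the
#'   model's markers (same ids, same coding).
#' @param ... unused.
#' @return Named vector of predicted genotypic values `mu + X alpha`.
#' @export
predict.rrblup <- function(object, newdata, ...) {
  Xm <- if (inherits(newdata, "geno_matrix")) newdata$dosages else as.matrix(newdata)
  ids <- colnames(Xm)
  if (!is.null(ids)) {
    missing <- setdiff(object$marker_ids, ids)
    extra <- setdiff(ids, object$marker_ids)
    if (length(missing) || length(extra)) {
      stop("marker mismatch; missing: ",
           paste(utils::head(missing, 3), collapse = ","),
           " extra: ", paste(utils::head(extra, 3), collapse = ","))
    }
    Xm <- Xm[, object$marker_ids, drop = FALSE]
  } else if (ncol(Xm) != object$p) {
    stop("newdata has ", ncol(Xm), " markers; model has ", object$p)
  }
  stats::setNames(as.vector(object$mu_hat + Xm %*% object$alpha_hat),
                  rownames(Xm))
}
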