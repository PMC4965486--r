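#' Filter markers by missing rate
#'
#' Removes SNPs whose fraction of missing calls strictly exceeds
#' `max_missing` (a SNP at exactly the threshold is retained).
#'
#' @param g a [geno_matrix].
#' @param max_missing maximum tolerated missing fraction, default 0.10.
#' @return The filtered [geno_matrix]; the number of removed SNPs is attached
#'   as attribute `n_removed` and reported via `message()`.
#' @export
filter_missing <- function(g, max_missing = 0.10) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  rate <- colMeans(is.na(g$dosages))
  keep <- rate <= max_missing
  if (!any(keep)) stop("all markers exceed the missing-rate threshold")
  message(sum(!keep), " of ", length(keep),
          " SNPs removed (missing rate > ", max_missing, ")")
  out <- subset_markers(g, which(keep))
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Impute missing dosages by the marker mean
#'
#' Each missing call is replaced by the mean dosage of the marker over
#' non-missing lines; values become fractional.  Deterministic and idempotent.
#'
#' @param g a [geno_matrix], typically after [filter_missing()].
#' @param method imputation method; only `"marker_mean"` is implemented.
#' @return The imputed [geno_matrix] (no missing values).
#' @export
impute_missing <- function(g, method = c("marker_mean")) {
  method <- match.arg(method)
  d <- g$dosages
  nm <- colSums(!is.na(d))
  if (any(nm == 0)) {
    stop("marker(s) entirely missing (should have been filtered): ",
         paste(utils::head(g$map$snp_id[nm == 0], 5), collapse = ", "))
  }
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx)) d[idx] <- mu[idx[, 2]]
  g$dosages <- d
  g
}

#' Per-marker allele frequency statistics
#'
#' Computes, on non-missing calls, the minor allele frequency
#' `MAF = min(p, 1 - p)` with `p` the mean dosage / 2, the biallelic
#' polymorphism information content `PIC = 1 - (p^2 + q^2) - 2 p^2 q^2`
#' (Botstein's formula), and the missing rate.
#'
#' @param g a [geno_matrix].
#' @return Data frame with columns `snp_id`, `maf`, `pic`, `missing_rate`.
#' @export
marker_stats <- function(g) {
  d <- g$dosages
  p <- colMeans(d, na.rm = TRUE) / 2
  q <- 1 - p
  data.frame(snp_id = g$map$snp_id,
             maf = pmin(p, q),
             pic = 1 - (p^2 + q^2) - 2 * p^2 * q^2,
             missing_rate = colMeans(is.na(d)),
             row.names = NULL)
}
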