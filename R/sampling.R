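#' Marker-density grid for random sampling (RSM)
#'
#' Subset sizes are rounded fractions 5%, 10%, ..., 100% of the marker
#' panel (20 levels; duplicates collapsed), and the pool is the full QC'd
#' panel.
#'
#' @param n_markers number of markers in the panel (>= 20).
#' @param step_fraction grid step as a fraction; must divide 1 evenly.
#' @return List of class `sampling_scheme` with `label = "RSM"`, `sizes`,
#'   `pool` (all marker indices).
#' @export
rsm_grid <- function(n_markers, step_fraction = 0.05) {
  if (n_markers < 20) stop("need at least 20 markers")
  k <- 1 / step_fraction
  if (abs(k - round(k)) > 1e-9) stop("step_fraction must divide 1 evenly")
  sizes <- unique(round(seq(step_fraction, 1, by = step_fraction) * n_markers))
  sizes <- sizes[sizes >= 1]
  structure(list(label = "RSM", sizes = sizes, pool = seq_len(n_markers)),
            class = "sampling_scheme")
}

#' Draw a random marker subset
#'
#' Uniform sampling without replacement from the scheme's pool;
#' deterministic given the seed.
#'
#' @param scheme a `sampling_scheme`.
#' @param size subset size (must not exceed the pool).
#' @param seed integer seed.
#' @return Sorted vector of marker indices.
#' @export
rsm_draw <- function(scheme, size, seed) {
  if (size > length(scheme$pool)) stop("size exceeds pool")
  with_seed(seed, sort(sample(scheme$pool, size)))
}

#' Haplotype-block-based marker pool and grid (HBA)
#'
#' The pool is one uniformly chosen SNP per haplotype block plus all
#' non-block SNPs, so `|pool| = n_blocks + n_nonblock_snps`.  The size grid
#' has 20 near-equal steps ending at the full pool:
#' `sizes = |pool| - step * (19:0)` with `step = round(|pool| / 20)` (which
#' reproduces a 172...3554 grid in steps of 178 for a pool of 3554).
#'
#' @param blocks a [call_blocks()] result covering the panel.
#' @param g the matching [geno_matrix].
#' @param seed seed for the per-block representative draw (fixed per run).
#' @return List of class `sampling_scheme` with `label = "HBA"`, `sizes`,
#'   `pool` (marker indices).
#' @export
hba_pool <- function(blocks, g, seed = 1) {
  member <- block_membership(blocks, g)
  nonblock <- which(is.na(member))
  if (blocks$n_blocks == 0) {
    warning("empty block set: HBA pool falls back to all markers")
    pool <- seq_len(nrow(g$map))
  } else {
    reps <- with_seed(seed, vapply(seq_len(blocks$n_blocks), function(k) {
      idx <- which(member == k)
      if (length(idx) == 1) idx else sample(idx, 1)
    }, integer(1)))
    pool <- sort(c(reps, nonblock))
  }
  np <- length(pool)
  step <- round(np / 20)
  sizes <- np - step * (19:0)
  sizes <- unique(sizes[sizes >= 1])
  structure(list(label = "HBA", sizes = sizes, pool = pool),
            class = "sampling_scheme")
}

#' Evenly-spaced marker selection (ESM)
#'
#' Allocates the subset size to chromosomes proportionally to their marker
#' counts (largest-remainder rounding), then picks, within each chromosome,
#' the marker nearest to each of `k` equally spaced physical targets
#' `(j - 0.5) / k` of the chromosome span (measured from 0 to the last
#' marker position); ties go to the lower index.  Deterministic: no
#' randomness.
#'
#' @param map marker map data frame (`snp_id`, `chrom`, `pos`), sorted as in
#'   a [geno_matrix].
#' @param size total number of markers to select (>= number of chromosomes).
#' @return Sorted vector of marker row indices into `map`.
#' @export
esm_select <- function(map, size) {
  chroms <- unique(map$chrom)
  if (size < length(chroms)) stop("size below the number of chromosomes: cannot cover the genome")
  if (size > nrow(map)) stop("size exceeds the marker panel")
  counts <- table(factor(map$chrom, levels = chroms))
  quota <- size * as.numeric(counts) / nrow(map)
  alloc <- floor(quota)
  rem <- size - sum(alloc)
  if (rem > 0) {
    o <- order(quota - alloc, decreasing = TRUE)
    alloc[o[seq_len(rem)]] <- alloc[o[seq_len(rem)]] + 1
  }
  ## keep every chromosome represented
  while (any(alloc == 0)) {
    give <- which(alloc == 0)[1]
    take <- which.max(alloc)
    alloc[give] <- 1; alloc[take] <- alloc[take] - 1
  }
  alloc <- pmin(alloc, as.numeric(counts))
  picked <- integer(0)
  for (c_i in seq_along(chroms)) {
    rows <- which(map$chrom == chroms[c_i])
    k <- alloc[c_i]
    if (k == 0) next
    pos <- map$pos[rows]
    targets <- (seq_len(k) - 0.5) / k * max(pos)
    sel <- integer(0)
    for (t in targets) {
      d <- abs(pos - t)
      d[match(sel, rows)] <- Inf     # already used within this chromosome
      sel <- c(sel, rows[which.min(d)])
    }
    picked <- c(picked, sel)
  }
  sort(unique(picked))
}

#' ESM as a sampling scheme over the HBA-style grid
#'
#' Convenience wrapper giving ESM the same size grid as an HBA scheme (the
#' two strategies are compared at matched densities).
#'
#' @param map marker map.
#' @param sizes size grid to use.
#' @return List of class `sampling_scheme` with `label = "ESM"`.
#' @export
esm_scheme <- function(map, sizes) {
  sizes <- sizes[sizes >= length(unique(map$chrom)) & sizes <= nrow(map)]
  structure(list(label = "ESM", sizes = sizes, pool = seq_len(nrow(map)),
                 map = map),
            class = "sampling_scheme")
}

#' @export
print.sampling_scheme <- function(x, ...) {
  cat(sprintf("%s sampling scheme: pool of %d markers, %d grid sizes (%d...%d)\n",
              x$label, length(x$pool), length(x$sizes), min(x$sizes), max(x$sizes)))
  invisible(x)
}

#' Cross-validated accuracy over marker-density grids
#'
#' Runs [run_cv()] for every scheme and grid size.  For the random schemes
#' (RSM, HBA) a fresh subset is drawn from the scheme pool every replicate;
#' for ESM the single deterministic subset is used and replicates vary only
#' the fold assignment.
#'
#' @inheritParams run_cv
#' @param schemes list of `sampling_scheme` objects.
#' @param map marker map (needed for ESM).
#' @return Long-format data frame: `scheme`, `size`, `mean_r_MP`,
#'   `mean_r_GS`, `sd_r_GS`, `se_r_GS`.
#' @export
density_sweep <- function(y, X, vc, schemes, map = NULL, n_folds = 5,
                          n_replicates = 100, seed = 1,
                          pooling = c("per_fold_mean", "pooled")) {
  pooling <- match.arg(pooling)
  rows <- list()
  for (sc in schemes) {
    for (sz in sc$sizes) {
      cv <- if (sc$label == "ESM") {
        m <- sc$map %||% map
        if (is.null(m)) stop("ESM requires a marker map")
        run_cv(y, X, vc, n_folds, n_replicates,
               seed = substream_seed(seed, paste0(sc$label, sz)),
               marker_subset = esm_select(m, sz), pooling = pooling)
      } else {
        pool <- sc$pool
        run_cv(y, X, vc, n_folds, n_replicates,
               seed = substream_seed(seed, paste0(sc$label, sz)),
               subset_fn = function(rs) with_seed(rs + 1, sort(sample(pool, sz))),
               pooling = pooling)
      }
      rows[[length(rows) + 1]] <-
        data.frame(scheme = sc$label, size = sz,
                   mean_r_MP = cv$mean_r_MP, mean_r_GS = cv$mean_r_GS,
                   sd_r_GS = cv$sd_r_GS,
                   se_r_GS = cv$sd_r_GS / sqrt(cv$n_replicates))
    }
  }
  do.call(rbind, rows)
}
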