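#' Parameters for Gabriel-style block calling
#'
#' Defaults follow the Haploview 4.2 implementation of the Gabriel
#' confidence-interval method: a pair is "strong LD" when the one-sided 90%
#' CI on |D'| has lower bound >= 0.70 and upper bound >= 0.98, "strong
#' recombination" when the upper bound < 0.90, otherwise uninformative; a
#' candidate interval is a block when its outermost pair is strong LD and at
#' least 95% of its informative pairs are strong LD; pairs with a marker
#' under 5% MAF are excluded and candidates are capped at a 500 kb span.
#'
#' @param ci_strong_low,ci_strong_high strong-LD bounds on (ci_low, ci_high).
#' @param ci_recomb_high strong-recombination bound on ci_high.
#' @param informative_frac minimum strong-LD fraction among informative pairs.
#' @param maf_min minimum MAF for a marker to enter the analysis.
#' @param max_span_bp maximum block span in bp.
#' @return List of class `gabriel_params`.
#' @export
gabriel_params <- function(ci_strong_low = 0.70, ci_strong_high = 0.98,
                           ci_recomb_high = 0.90, informative_frac = 0.95,
                           maf_min = 0.05, max_span_bp = 5e5) {
  structure(list(ci_strong_low = ci_strong_low, ci_strong_high = ci_strong_high,
                 ci_recomb_high = ci_recomb_high,
                 informative_frac = informative_frac,
                 maf_min = maf_min, max_span_bp = max_span_bp),
            class = "gabriel_params")
}

#' Detect Gabriel-style haplotype blocks
#'
#' Classifies within-chromosome marker pairs by their |D'| confidence
#' interval (see [dprime_ci()] and [gabriel_params()]), enumerates candidate
#' intervals whose outermost pair is strong LD and whose informative pairs
#' are at least 95% strong LD, and keeps a non-overlapping set greedily from
#' the widest bp span down.  Lines are treated as haplotypes (inbred panel).
#'
#' @param g an imputed [geno_matrix] with 0/2 dosages (fractional residues
#'   are rounded for haplotype counting).
#' @param params a [gabriel_params()] list.
#' @return Object of class `haplo_blocks`: data frame `blocks` with columns
#'   `chrom`, `first`, `last` (global marker column indices), `start_bp`,
#'   `end_bp`, `n_snps`; counts `n_blocks`, `n_block_snps`,
#'   `n_nonblock_snps` (these two partition the full marker panel).
#' @export
call_blocks <- function(g, params = gabriel_params()) {
  map <- g$map
  for (ch in unique(map$chrom)) {
    if (is.unsorted(map$pos[map$chrom == ch], strictly = TRUE)) {
      stop("marker map not sorted on chromosome ", ch)
    }
  }
  X_all <- round(g$dosages) / 2
  blocks <- list()
  for (ch in unique(map$chrom)) {
    cols <- which(map$chrom == ch)
    pA <- colMeans(X_all[, cols, drop = FALSE], na.rm = TRUE)
    use <- pmin(pA, 1 - pA) >= params$maf_min
    acols <- cols[use]
    m <- length(acols)
    if (m < 2) next
    X <- X_all[, acols, drop = FALSE]
    pos <- map$pos[acols]
    ## classify pairs within the span cap: 1 strong LD, -1 strong
    ## recombination, 0 uninformative
    cls <- matrix(NA_integer_, m, m)
    for (a in seq_len(m - 1)) {
      for (b in (a + 1):m) {
        if (pos[b] - pos[a] > params$max_span_bp) break
        n11 <- sum(X[, a] == 1 & X[, b] == 1)
        n12 <- sum(X[, a] == 1 & X[, b] == 0)
        n21 <- sum(X[, a] == 0 & X[, b] == 1)
        n22 <- sum(X[, a] == 0 & X[, b] == 0)
        ci <- dprime_ci(c(n11, n12, n21, n22))
        cls[a, b] <- if (ci[1] >= params$ci_strong_low &&
                           ci[2] >= params$ci_strong_high) 1L
        else if (ci[2] < params$ci_recomb_high) -1L else 0L
      }
    }
    ## candidates: outer pair strong, >= informative_frac of informative
    ## pairs inside (outer pair included) strong
    cand <- list()
    for (a in seq_len(m - 1)) {
      ns <- 0L; ni <- 0L
      for (b in (a + 1):m) {
        if (is.na(cls[a, b])) break
        add <- cls[a:(b - 1), b]
        ns <- ns + sum(add == 1L, na.rm = TRUE)
        ni <- ni + sum(add != 0L, na.rm = TRUE)
        if (cls[a, b] == 1L && ni > 0 && ns / ni >= params$informative_frac) {
          cand[[length(cand) + 1]] <- c(a, b)
        }
      }
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    span <- pos[cand[, 2]] - pos[cand[, 1]]
    nmark <- cand[, 2] - cand[, 1] + 1
    o <- order(-span, -nmark, cand[, 1])
    taken <- rep(FALSE, m)
    for (k in o) {
      rng <- cand[k, 1]:cand[k, 2]
      if (any(taken[rng])) next
      taken[rng] <- TRUE
      blocks[[length(blocks) + 1]] <-
        data.frame(chrom = ch, first = acols[cand[k, 1]], last = acols[cand[k, 2]],
                   start_bp = pos[cand[k, 1]], end_bp = pos[cand[k, 2]],
                   n_snps = acols[cand[k, 2]] - acols[cand[k, 1]] + 1L)
    }
  }
  blocks <- if (length(blocks)) do.call(rbind, blocks) else {
    data.frame(chrom = character(), first = integer(), last = integer(),
               start_bp = numeric(), end_bp = numeric(), n_snps = integer())
  }
  blocks <- blocks[order(match(blocks$chrom, unique(map$chrom)), blocks$first), ]
  rownames(blocks) <- NULL
  n_block_snps <- sum(blocks$n_snps)
  structure(list(blocks = blocks,
                 n_blocks = nrow(blocks),
                 n_block_snps = n_block_snps,
                 n_nonblock_snps = nrow(map) - n_block_snps,
                 n_markers = nrow(map),
                 params = params),
            class = "haplo_blocks")
}

#' @export
print.haplo_blocks <- function(x, ...) {
  cat(sprintf("haplo_blocks: %d blocks holding %d SNPs; %d SNPs outside blocks (of %d)\n",
              x$n_blocks, x$n_block_snps, x$n_nonblock_snps, x$n_markers))
  if (x$n_blocks > 0) {
    cat(sprintf("  block sizes %d-%d SNPs\n", min(x$blocks$n_snps), max(x$blocks$n_snps)))
  }
  invisible(x)
}

#' Block membership of each marker
#'
#' @param blocks a [call_blocks()] result.
#' @param g the [geno_matrix] the blocks were called on.
#' @return Integer vector, one entry per marker: the block number it falls
#'   in, or `NA` for non-block SNPs.
#' @export
block_membership <- function(blocks, g) {
  member <- rep(NA_integer_, nrow(g$map))
  if (blocks$n_blocks) {
    for (k in seq_len(nrow(blocks$blocks))) {
      member[blocks$blocks$first[k]:blocks$blocks$last[k]] <- k
    }
  }
  member
}

#' Write blocks to a BED-like table
#'
#' Columns: chrom, start bp, end bp, SNP count, comma-joined SNP ids.
#'
#' @param blocks a [call_blocks()] result.
#' @param g the matching [geno_matrix].
#' @param path output path (tab-separated, no header).
#' @return `path`, invisibly.
#' @export
write_blocks_bed <- function(blocks, g, path) {
  b <- blocks$blocks
  ids <- vapply(seq_len(nrow(b)), function(k) {
    paste(g$map$snp_id[b$first[k]:b$last[k]], collapse = ",")
  }, character(1))
  utils::write.table(data.frame(b$chrom, b$start_bp, b$end_bp, b$n_snps, ids),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
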