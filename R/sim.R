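#' Simulation configuration for a structured inbred SNP panel
#'
#' Describes the generative model used throughout the package's tests and
#' demos: fully homozygous lines built as recombinant mosaics of
#' subpopulation-specific ancestral haplotype pools, with recombination
#' restricted to sampled hotspot positions (so markers between consecutive
#' hotspots form high-D' blocks), two subpopulations diverged by a
#' Balding-Nichols drift parameter, and multi-location phenotypes generated
#' from additive QTL effects plus location and residual variance components
#' tuned to a target entry-mean heritability.
#'
#' Defaults emulate a soybean-style diversity panel: 235 lines in an 185/50
#' two-ecotype split, ~5000 mapped SNPs on 20 chromosomes, and 23 trial
#' locations.
#'
#' @param n_lines number of inbred lines.
#' @param n_snps total number of SNPs across the genome.
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_bp chromosome length in bp (all chromosomes equal).
#' @param n_subpops 1 or 2 subpopulations.
#' @param subpop_sizes line counts per subpopulation; must sum to `n_lines`.
#' @param divergence_fst Balding-Nichols drift parameter in `[0, 1)`;
#'   0 means the subpopulations share ancestral allele frequencies.
#' @param haplotype_pool_size ancestral haplotypes per subpopulation.
#' @param recomb_hotspot_rate expected recombination hotspots per Mb.
#' @param within_block_mutation per-SNP copy-error probability when a line
#'   copies a pool haplotype.
#' @param n_qtl number of additive QTL (drawn from genotyped SNPs); the
#'   default is capped at `n_snps` for small panels.
#' @param sigma2_G genetic variance of the simulated trait (trait units^2).
#' @param target_h2 target entry-mean heritability in `(0, 1]`; the residual
#'   variance is set to `sigma2_G * l * (1 - h2) / h2`.
#' @param n_locations number of trial locations `l`.
#' @param sigma2_L location variance.
#' @param master_seed integer master seed; named substreams are derived from
#'   it so that genotypes, QTL effects, location effects and residuals can be
#'   regenerated independently.
#' @param hotspots_bp optional list of fixed hotspot positions (bp), one
#'   numeric vector per chromosome; overrides the Poisson hotspot draw (used
#'   to plant blocks at known boundaries).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 235, n_snps = 5000, n_chromosomes = 20,
                       chrom_length_bp = 5e7, n_subpops = 2,
                       subpop_sizes = NULL, divergence_fst = 0.1,
                       haplotype_pool_size = 20, recomb_hotspot_rate = 2,
                       within_block_mutation = 0.01, n_qtl = 200,
                       sigma2_G = 1, target_h2 = 0.63, n_locations = 23,
                       sigma2_L = 2, master_seed = 1, hotspots_bp = NULL) {
  if (!n_subpops %in% c(1L, 2L)) stop("n_subpops must be 1 or 2")
  if (is.null(subpop_sizes)) {
    subpop_sizes <- if (n_subpops == 1) n_lines else {
      a <- round(n_lines * 185 / 235); c(a, n_lines - a)
    }
  }
  if (length(subpop_sizes) != n_subpops || sum(subpop_sizes) != n_lines) {
    stop("subpop_sizes must have length n_subpops and sum to n_lines")
  }
  if (divergence_fst < 0 || divergence_fst >= 1) stop("divergence_fst must be in [0, 1)")
  if (target_h2 <= 0 || target_h2 > 1) stop("target_h2 must be in (0, 1]")
  if (missing(n_qtl)) n_qtl <- min(n_qtl, n_snps)
  if (n_qtl > n_snps) stop("n_qtl must not exceed n_snps")
  cfg <- list(n_lines = n_lines, n_snps = n_snps, n_chromosomes = n_chromosomes,
              chrom_length_bp = chrom_length_bp, n_subpops = n_subpops,
              subpop_sizes = subpop_sizes, divergence_fst = divergence_fst,
              haplotype_pool_size = haplotype_pool_size,
              recomb_hotspot_rate = recomb_hotspot_rate,
              within_block_mutation = within_block_mutation,
              n_qtl = n_qtl, sigma2_G = sigma2_G, target_h2 = target_h2,
              n_locations = n_locations, sigma2_L = sigma2_L,
              master_seed = master_seed, hotspots_bp = hotspots_bp)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate an inbred genotype panel with block-structured LD
#'
#' Lines are recombinant mosaics of a subpopulation-specific ancestral
#' haplotype pool; recombination happens only at Poisson-sampled hotspot
#' positions, so the markers between consecutive hotspots descend from single
#' pool haplotypes and form high-D' blocks whose boundaries are recorded in
#' the returned truth record.  Subpopulation allele frequencies drift apart
#' from a common ancestral frequency by Balding-Nichols Beta sampling with
#' parameter `divergence_fst`.  Monomorphic markers are re-drawn so every
#' marker segregates.
#'
#' @param config a [sim_config].
#' @return A list with elements `geno` (a [geno_matrix], dosages in
#'   `{0, 2}`) and `truth` (list with `block_boundaries` — per-chromosome
#'   data frame of marker-index intervals between hotspots with >= 2 SNPs —
#'   plus `subpop` labels and `hotspots_bp`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(substream_seed(config$master_seed, "genotypes"), {
    n <- config$n_lines
    p <- config$n_snps
    H <- config$haplotype_pool_size
    ## marker map: near-equal SNP counts per chromosome, unique sorted positions
    per <- diff(round(seq(0, p, length.out = config$n_chromosomes + 1)))
    chrom <- rep(paste0("chr", seq_len(config$n_chromosomes)), per)
    pos <- unlist(lapply(per, function(k) sort(sample.int(config$chrom_length_bp, k))))
    ## ancestral and subpopulation allele frequencies
    p_anc <- stats::runif(p, 0.1, 0.9)
    Fst <- config$divergence_fst
    freq <- matrix(NA_real_, nrow = config$n_subpops, ncol = p)
    draw_freq <- function(pa) {
      if (Fst == 0) return(pa)
      stats::rbeta(length(pa), pa * (1 - Fst) / Fst, (1 - pa) * (1 - Fst) / Fst)
    }
    for (k in seq_len(config$n_subpops)) freq[k, ] <- draw_freq(p_anc)
    ## recombination hotspots partition each chromosome into copying segments
    seg_of <- integer(p)          # global segment index per SNP
    hotspots <- vector("list", config$n_chromosomes)
    seg_off <- 0L
    for (ch in seq_len(config$n_chromosomes)) {
      idx <- which(chrom == paste0("chr", ch))
      hs <- if (!is.null(config$hotspots_bp)) {
        sort(config$hotspots_bp[[ch]])
      } else {
        n_hs <- stats::rpois(1, config$recomb_hotspot_rate * config$chrom_length_bp / 1e6)
        sort(stats::runif(n_hs, 0, config$chrom_length_bp))
      }
      hotspots[[ch]] <- hs
      seg_of[idx] <- seg_off + findInterval(pos[idx], hs) + 1L
      seg_off <- seg_off + length(hs) + 1L
    }
    n_seg <- seg_off
    ## Ancestral pools: within a copying segment the pool haplotypes are
    ## comonotone -- haplotype h carries the minor allele at marker j iff its
    ## segment-level score u[h, seg] falls below the marker frequency.  Two
    ## markers of one segment therefore have nested allele sets in the pool
    ## (|D'| = 1 exactly in the infinite-pool limit), which is what makes
    ## hotspot-delimited segments behave as Gabriel-style blocks.
    U <- lapply(seq_len(config$n_subpops), function(k) {
      matrix(stats::runif(H * n_seg), nrow = H)
    })
    pool_col <- function(k, j) as.integer(U[[k]][, seg_of[j]] < freq[k, j])
    subpop <- rep(seq_len(config$n_subpops), config$subpop_sizes)
    Z <- matrix(sample.int(H, n * n_seg, replace = TRUE), nrow = n)
    mut_mask <- matrix(stats::runif(n * p) < config$within_block_mutation, nrow = n)
    build_col <- function(j) {
      hap <- pool_col(1, j)[Z[, seg_of[j]]]
      if (config$n_subpops == 2) {
        two <- subpop == 2
        hap[two] <- pool_col(2, j)[Z[two, seg_of[j]]]
      }
      hap[mut_mask[, j]] <- 1L - hap[mut_mask[, j]]
      hap
    }
    haplo <- vapply(seq_len(p), build_col, integer(n))
    ## re-draw monomorphic markers with a fresh allele frequency
    for (tries in 1:100) {
      mono <- which(apply(haplo, 2, function(x) all(x == x[1])))
      if (!length(mono)) break
      p_anc[mono] <- stats::runif(length(mono), 0.2, 0.8)
      for (k in seq_len(config$n_subpops)) {
        freq[k, mono] <- draw_freq(p_anc[mono])
      }
      haplo[, mono] <- vapply(mono, build_col, integer(n))
    }
    mono <- which(apply(haplo, 2, function(x) all(x == x[1])))
    ## last resort (tiny pools): flip one line's allele directly
    if (length(mono)) haplo[1, mono] <- 1L - haplo[1, mono]
    g <- geno_matrix(2 * haplo,
                     data.frame(snp_id = sprintf("snp%05d", seq_len(p)),
                                chrom = chrom, pos = pos),
                     line_ids = sprintf("line%04d", seq_len(n)))
    ## truth blocks: hotspot-delimited segments holding >= 2 markers
    blocks <- do.call(rbind, lapply(split(seq_len(p), seg_of), function(idx) {
      if (length(idx) < 2) return(NULL)
      data.frame(chrom = chrom[idx[1]], first = min(idx), last = max(idx))
    }))
    if (is.null(blocks)) {
      blocks <- data.frame(chrom = character(), first = integer(), last = integer())
    }
    blocks <- blocks[order(blocks$first), ]
    rownames(blocks) <- NULL
    list(geno = g,
         truth = list(block_boundaries = blocks,
                      subpop = subpop,
                      hotspots_bp = hotspots))
  })
}

#' Simulate multi-location entry-mean phenotypes
#'
#' Implements the generative inverse of the two-way model
#' `y_ij = mu + L_i + G_j + e_ij`: per-line genetic values are additive over
#' QTL drawn from the genotyped SNPs and rescaled to variance `sigma2_G`;
#' location effects are `N(0, sigma2_L)`; entry-mean residuals are
#' `N(0, sigma2_e)` with `sigma2_e = sigma2_G * l * (1 - h2) / h2`, so the
#' entry-mean heritability `sigma2_G / (sigma2_G + sigma2_e / l)` equals
#' `target_h2` by construction.
#'
#' @param geno a [geno_matrix] from [simulate_genotypes()].
#' @param truth the matching truth record (updated in the return value).
#' @param config the [sim_config] used to generate `geno`.
#' @return A list with `pheno` (long data frame `line_id`, `location_id`,
#'   `value`) and `truth` extended with `qtl_indices`, `qtl_effects`,
#'   `true_genetic_values`, `sigma2_e`, and `realized_h2` (from the realized
#'   variance components).
#' @export
simulate_phenotypes <- function(geno, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$target_h2 <= 0) stop("target_h2 = 0 is rejected: lambda undefined downstream")
  n <- nrow(geno$dosages)
  l <- config$n_locations
  qtl <- with_seed(substream_seed(config$master_seed, "effects"), {
    idx <- sort(sample.int(ncol(geno$dosages), config$n_qtl))
    list(idx = idx, eff = stats::rnorm(config$n_qtl))
  })
  g_raw <- as.vector(geno$dosages[, qtl$idx, drop = FALSE] %*% qtl$eff)
  if (stats::var(g_raw) == 0) stop("degenerate QTL draw: no genetic variance")
  g_val <- (g_raw - mean(g_raw)) * sqrt(config$sigma2_G / stats::var(g_raw))
  sigma2_e <- config$sigma2_G * l * (1 - config$target_h2) / config$target_h2
  L <- with_seed(substream_seed(config$master_seed, "locations"),
                 stats::rnorm(l, 0, sqrt(config$sigma2_L)))
  e <- with_seed(substream_seed(config$master_seed, "residuals"),
                 matrix(stats::rnorm(n * l, 0, sqrt(sigma2_e)), nrow = n))
  y <- outer(g_val, L, "+") + e
  pheno <- data.frame(line_id = rep(geno$line_ids, times = l),
                      location_id = rep(sprintf("loc%02d", seq_len(l)), each = n),
                      value = as.vector(y))
  var_e <- if (sigma2_e > 0) stats::var(as.vector(e)) else 0
  truth$qtl_indices <- qtl$idx
  truth$qtl_effects <- qtl$eff
  truth$true_genetic_values <- stats::setNames(g_val, geno$line_ids)
  truth$sigma2_e <- sigma2_e
  truth$realized_h2 <- stats::var(g_val) / (stats::var(g_val) + var_e / l)
  list(pheno = pheno, truth = truth)
}

#' Write a simulation truth record to JSON
#'
#' @param truth truth record from [simulate_phenotypes()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
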