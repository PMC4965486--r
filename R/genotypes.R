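#' Genotype matrix container
#'
#' Bundles an allele-dosage matrix (lines in rows, SNPs in columns) with its
#' marker map.  Dosages count copies of the alternate (second-listed) allele,
#' so inbred lines carry 0 or 2; heterozygous calls are 1 and missing calls
#' `NA`.  Markers are stored sorted by chromosome (order of first appearance)
#' and strictly increasing physical position.
#'
#' @param dosages numeric matrix, `n_lines x n_snps`, values in
#'   `{0, 1, 2, NA}` (fractional values are allowed after mean imputation).
#' @param map data frame with columns `snp_id`, `chrom`, `pos` (bp); one row
#'   per column of `dosages`, in column order.
#' @param line_ids character vector of unique line identifiers; defaults to
#'   rownames of `dosages`.
#' @return An object of class `geno_matrix`: a list with elements `dosages`,
#'   `map`, `line_ids`.
#' @export
geno_matrix <- function(dosages, map, line_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(line_ids)) line_ids <- paste0("L", seq_len(nrow(dosages)))
  line_ids <- as.character(line_ids)
  map <- as.data.frame(map)
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(map))) {
    stop("map must have columns snp_id, chrom, pos")
  }
  map <- map[, need]
  map$snp_id <- as.character(map$snp_id)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.numeric(map$pos)
  if (nrow(map) != ncol(dosages)) {
    stop("map has ", nrow(map), " rows but dosages has ", ncol(dosages), " columns")
  }
  if (anyDuplicated(map$snp_id)) {
    stop("duplicate snp ids: ", paste(unique(map$snp_id[duplicated(map$snp_id)]), collapse = ", "))
  }
  if (anyDuplicated(line_ids)) stop("duplicate line ids")
  if (any(!is.na(dosages) & (dosages < 0 | dosages > 2))) {
    stop("dosage values must lie in [0, 2] or be NA")
  }
  ## sort markers: chromosomes in order of first appearance, positions within
  chrom_order <- match(map$chrom, unique(map$chrom))
  o <- order(chrom_order, map$pos)
  map <- map[o, , drop = FALSE]
  dosages <- dosages[, o, drop = FALSE]
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0)) stop("positions not strictly increasing on chromosome ", ch)
  }
  rownames(map) <- NULL
  dimnames(dosages) <- list(line_ids, map$snp_id)
  structure(list(dosages = dosages, map = map, line_ids = line_ids),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  miss <- mean(is.na(x$dosages))
  cat(sprintf("geno_matrix: %d lines x %d SNPs on %d chromosome(s), %.2f%% missing\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$map$chrom)), 100 * miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

## marker-index subset, keeping container invariants
subset_markers <- function(g, idx) {
  if (is.character(idx)) idx <- match(idx, g$map$snp_id)
  if (anyNA(idx)) stop("unknown snp ids in subset")
  geno_matrix(g$dosages[, idx, drop = FALSE], g$map[idx, , drop = FALSE],
              g$line_ids)
}

subset_lines <- function(g, idx) {
  structure(list(dosages = g$dosages[idx, , drop = FALSE],
                 map = g$map,
                 line_ids = g$line_ids[idx]),
            class = "geno_matrix")
}
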