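#' Read genotypes from VCF, HapMap or matrix-CSV
#'
#' Supported formats:
#' \describe{
#'   \item{`vcf`}{VCF v4.x with a `GT` field; only biallelic SNPs are
#'     accepted.  Dosage = count of the ALT allele; `./.` is missing.}
#'   \item{`hapmap`}{Tab-delimited HapMap dialect: the 11 standard header
#'     columns (`rs#`, `alleles`, `chrom`, `pos`, ...) then one column per
#'     line with single-character genotype calls (inbred calls; `N` = missing).
#'     Dosage = count of the second-listed allele of the `alleles` field.}
#'   \item{`matrix-csv`}{First column `line_id`, remaining columns one per
#'     SNP with values 0/1/2/NA; requires `map` (a path to a CSV with columns
#'     `snp_id`, `chrom`, `pos_bp`, or an equivalent data frame).}
#' }
#' Markers are sorted by chromosome and position on load (dosage columns are
#' permuted consistently).  Multi-allelic records are rejected.
#'
#' @param path input file path.
#' @param format one of `"vcf"`, `"hapmap"`, `"matrix-csv"`.
#' @param map marker map for `matrix-csv` input (path or data frame).
#' @return A [geno_matrix].
#' @export
read_genotypes <- function(path, format = c("vcf", "hapmap", "matrix-csv"),
                           map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         "vcf" = read_genotypes_vcf(path),
         "hapmap" = read_genotypes_hapmap(path),
         "matrix-csv" = read_genotypes_matrix(path, map))
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  multi <- grepl(",", alt) | nchar(alt) != 1 | nchar(ref) != 1
  if (any(multi)) {
    stop("multi-allelic or non-SNP records rejected: ",
         paste(utils::head(fix[multi, "ID"], 5), collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  gt <- gsub("\\|", "/", gt)
  dos <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt))
  code <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2)
  for (i in seq_len(nrow(gt))) {
    g <- gt[i, ]
    d <- unname(code[g])
    unknown <- !is.na(g) & g != "./." & g != "." & is.na(d)
    if (any(unknown)) {
      stop("unparsable GT '", g[unknown][1], "' at record ", fix[i, "ID"])
    }
    dos[, i] <- d
  }
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  geno_matrix(dos,
              data.frame(snp_id = ids, chrom = fix[, "CHROM"],
                         pos = as.numeric(fix[, "POS"])),
              line_ids = colnames(gt))
}

read_genotypes_hapmap <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  if (ncol(tab) < 12) stop("hapmap file needs 11 header columns plus lines: ", path)
  std <- 11L
  line_ids <- names(tab)[-seq_len(std)]
  alleles <- strsplit(tab[[2]], "/", fixed = TRUE)
  bad <- vapply(alleles, function(a) length(a) != 2 || any(nchar(a) != 1), logical(1))
  if (any(bad)) stop("non-biallelic alleles field at record ", which(bad)[1])
  n_snp <- nrow(tab)
  dos <- matrix(NA_real_, nrow = length(line_ids), ncol = n_snp)
  calls <- as.matrix(tab[, -seq_len(std), drop = FALSE])
  for (j in seq_len(n_snp)) {
    a1 <- alleles[[j]][1]; a2 <- alleles[[j]][2]
    g <- calls[j, ]
    d <- ifelse(g == a2, 2, ifelse(g == a1, 0, NA))
    het <- iupac_het(a1, a2)
    if (!is.na(het)) d[g == het] <- 1
    unknown <- !(g %in% c(a1, a2, het, "N", "NN", "-", "")) & !is.na(g)
    if (any(unknown)) {
      stop("unparsable call '", g[unknown][1], "' at record ", tab[[1]][j])
    }
    dos[, j] <- d
  }
  geno_matrix(dos,
              data.frame(snp_id = tab[[1]], chrom = as.character(tab[[3]]),
                         pos = as.numeric(tab[[4]])),
              line_ids = line_ids)
}

iupac_het <- function(a1, a2) {
  pair <- paste(sort(c(a1, a2)), collapse = "")
  c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")[pair]
}

read_genotypes_matrix <- function(path, map) {
  if (is.null(map)) stop("matrix-csv input requires a marker map")
  if (is.character(map)) {
    if (!file.exists(map)) stop("map file not found: ", map)
    map <- utils::read.csv(map, stringsAsFactors = FALSE)
  }
  map <- as.data.frame(map)
  if ("pos_bp" %in% names(map) && !"pos" %in% names(map)) {
    names(map)[names(map) == "pos_bp"] <- "pos"
  }
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  line_ids <- as.character(tab[[1]])
  dos <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(dos) <- "double"
  m <- match(colnames(dos), map$snp_id)
  if (anyNA(m)) stop("map is missing snp ids: ",
                     paste(utils::head(colnames(dos)[is.na(m)], 5), collapse = ", "))
  geno_matrix(dos, map[m, , drop = FALSE], line_ids = line_ids)
}

#' Write genotypes
#'
#' `write_vcf()` writes a minimal VCF v4.2 (GT-only, one pseudo-sample per
#' line, homozygous calls for integer dosages).  `write_geno_csv()` writes
#' the matrix-CSV dialect plus a companion map CSV.
#'
#' @param g a [geno_matrix] with integer dosages (0/1/2/NA).
#' @param path output file path.
#' @param map_path where to write the marker map CSV.
#' @return The input, invisibly.
#' @export
write_vcf <- function(g, path) {
  d <- g$dosages
  if (any(!is.na(d) & d != round(d))) {
    stop("write_vcf requires integer dosages (write before imputation)")
  }
  gt <- matrix("./.", nrow = ncol(d), ncol = nrow(d))
  gt[t(d) == 0] <- "0/0"
  gt[t(d) == 1] <- "0/1"
  gt[t(d) == 2] <- "1/1"
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", g$line_ids), collapse = "\t"))
  body <- paste(g$map$chrom, format(g$map$pos, scientific = FALSE, trim = TRUE),
                g$map$snp_id, "A", "T", ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(g)
}

#' @rdname write_vcf
#' @export
write_geno_csv <- function(g, path, map_path = NULL) {
  tab <- data.frame(line_id = g$line_ids, check.names = FALSE)
  tab <- cbind(tab, as.data.frame(g$dosages, check.names = FALSE))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  if (!is.null(map_path)) {
    utils::write.csv(data.frame(snp_id = g$map$snp_id, chrom = g$map$chrom,
                                pos_bp = g$map$pos),
                     map_path, row.names = FALSE, quote = FALSE)
  }
  invisible(g)
}

#' Read / write long-format phenotypes
#'
#' Phenotype CSVs are long format with columns `line_id`, `location_id`,
#' `value` (one entry mean per line x location).
#'
#' @param path CSV path.
#' @param pheno data frame with the three columns above.
#' @return `read_pheno_csv()` returns the data frame; `write_pheno_csv()` its
#'   input, invisibly.
#' @export
read_pheno_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("line_id", "location_id", "value")
  if (!all(need %in% names(tab))) {
    stop("phenotype CSV must have columns line_id, location_id, value: ", path)
  }
  tab[, need]
}

#' @rdname read_pheno_csv
#' @export
write_pheno_csv <- function(pheno, path) {
  utils::write.csv(pheno[, c("line_id", "location_id", "value")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(pheno)
}
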