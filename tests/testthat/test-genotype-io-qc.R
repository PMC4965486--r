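make_tiny_geno <- function() {
  d <- rbind(L1 = c(0, 2, 0, NA),
             L2 = c(2, 2, NA, 0),
             L3 = c(0, 0, 2, 2))
  geno_matrix(d, data.frame(snp_id = paste0("s", 1:4),
                            chrom = c("1", "1", "2", "2"),
                            pos = c(100, 200, 50, 400)))
}

test_that("VCF records are coded as ALT-allele counts with missing preserved", {
  vcf <- file.path(tempdir(), "tiny.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "A", "B", "C", sep = "\t"),
    paste("1", "100", "s1", "A", "T", ".", "PASS", ".", "GT",
          "0/0", "1/1", "./.", sep = "\t")), vcf)
  g <- read_genotypes(vcf, "vcf")
  expect_equal(unname(g$dosages[, 1]), c(0, 2, NA))
  expect_equal(g$line_ids, c("A", "B", "C"))
})

test_that("multi-allelic VCF records are rejected", {
  vcf <- file.path(tempdir(), "multi.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "A", "B", sep = "\t"),
    paste("1", "100", "s1", "A", "T,G", ".", "PASS", ".", "GT",
          "0/0", "1/1", sep = "\t")), vcf)
  expect_error(read_genotypes(vcf, "vcf"), "multi-allelic")
})

test_that("matrix-CSV and VCF round-trips reproduce the dosage matrix", {
  pan <- small_panel(seed = 2, n_lines = 30, n_snps = 60)
  gpath <- file.path(tempdir(), "g.csv"); mpath <- file.path(tempdir(), "m.csv")
  write_geno_csv(pan$geno, gpath, mpath)
  g2 <- read_genotypes(gpath, "matrix-csv", map = mpath)
  expect_identical(g2$dosages, pan$geno$dosages)
  expect_identical(g2$map, pan$geno$map)
  vpath <- file.path(tempdir(), "g.vcf")
  write_vcf(pan$geno, vpath)
  g3 <- read_genotypes(vpath, "vcf")
  expect_equal(unname(g3$dosages), unname(pan$geno$dosages))
})

test_that("hapmap input with unsorted positions is sorted consistently", {
  hpath <- file.path(tempdir(), "h.hmp.txt")
  hdr <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#", "center",
           "protLSID", "assayLSID", "panelLSID", "QCcode", "L1", "L2")
  rows <- c(paste(c("s1", "A/G", "1", "500", "+", rep(".", 6), "A", "G"), collapse = "\t"),
            paste(c("s2", "C/T", "1", "100", "+", rep(".", 6), "T", "N"), collapse = "\t"),
            paste(c("s3", "A/C", "1", "300", "+", rep(".", 6), "M", "C"), collapse = "\t"))
  writeLines(c(paste(hdr, collapse = "\t"), rows), hpath)
  g <- read_genotypes(hpath, "hapmap")
  expect_equal(g$map$snp_id, c("s2", "s3", "s1"))       # sorted by position
  expect_equal(g$map$pos, c(100, 300, 500))
  expect_equal(unname(g$dosages["L1", ]), c(2, 1, 0))   # T/T, het, A/A
  expect_equal(unname(g$dosages["L2", ]), c(NA, 2, 2))
})

test_that("missing-rate filter uses a strict threshold", {
  d <- matrix(0, nrow = 10, ncol = 3,
              dimnames = list(paste0("L", 1:10), paste0("s", 1:3)))
  d[, 1] <- rep(c(0, 2), 5)
  d[1:2, 2] <- NA; d[3:10, 2] <- c(0, 2, 0, 2, 0, 2, 0, 2)  # 20% missing
  d[1, 3] <- NA; d[2:10, 3] <- rep(c(0, 2, 0), 3)           # 10% missing
  g <- geno_matrix(d, data.frame(snp_id = paste0("s", 1:3), chrom = "1",
                                 pos = c(1, 2, 3)))
  f <- suppressMessages(filter_missing(g, 0.10))
  expect_equal(f$map$snp_id, c("s1", "s3"))   # exactly 10% retained, 20% dropped
  expect_equal(attr(f, "n_removed"), 1L)
  ## every marker above the threshold: nothing survives
  g_all <- geno_matrix(matrix(c(NA, 0, 2, NA, 2, 0), nrow = 3),
                       data.frame(snp_id = c("a", "b"), chrom = "1", pos = 1:2),
                       line_ids = paste0("L", 1:3))
  expect_error(suppressMessages(filter_missing(g_all, 0.1)), "all markers")
})

test_that("mean imputation is exact, deterministic and idempotent", {
  g <- make_tiny_geno()
  gi <- impute_missing(g)
  expect_equal(unname(gi$dosages[, "s4"]), c(1, 0, 2))   # mean of 0 and 2
  expect_false(anyNA(gi$dosages))
  expect_identical(impute_missing(gi)$dosages, gi$dosages)
  ## filter + impute is idempotent on its own output
  g2 <- suppressMessages(filter_missing(gi, 0.10))
  expect_identical(impute_missing(g2)$dosages, gi$dosages)
})

test_that("imputation recovers marker means under MCAR missingness", {
  pan <- small_panel(seed = 14, n_lines = 200, n_snps = 150)
  d <- pan$geno$dosages
  pre_means <- colMeans(d)
  set.seed(99)
  mask <- matrix(runif(length(d)) < 0.05, nrow = nrow(d))
  d[mask] <- NA
  g <- geno_matrix(d, pan$geno$map)
  gi <- impute_missing(suppressMessages(filter_missing(g, 0.15)))
  kept <- match(gi$map$snp_id, pan$geno$map$snp_id)
  expect_lt(max(abs(colMeans(gi$dosages) - pre_means[kept])), 0.05 * 2)
})

test_that("MAF and PIC follow the biallelic closed forms", {
  ## p = 0.5: MAF 0.5, PIC 0.375; p = 0.25: PIC = 0.3046875; p = 0: both 0
  d <- cbind(s1 = c(0, 0, 2, 2), s2 = c(0, 0, 0, 2), s3 = c(0, 0, 0, 0))
  g <- geno_matrix(d, data.frame(snp_id = colnames(d), chrom = "1", pos = 1:3),
                   line_ids = paste0("L", 1:4))
  st <- marker_stats(g)
  expect_equal(st$maf, c(0.5, 0.25, 0))
  expect_equal(st$pic[1], 0.375)
  expect_equal(st$pic[2], 0.3046875)
  expect_equal(st$pic[3], 0)
})

test_that("PIC is bounded by expected heterozygosity on simulated panels", {
  pan <- small_panel(seed = 31, n_lines = 100, n_snps = 250)
  st <- marker_stats(pan$geno)
  eh <- 2 * st$maf * (1 - st$maf)
  expect_true(all(st$pic <= eh + 1e-12))
  expect_true(all(eh <= 0.5 + 1e-12))
  expect_true(all(st$maf >= 0 & st$maf <= 0.5))
})
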