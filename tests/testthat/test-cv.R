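fake_vc <- function(s2G = 1, s2e = 0, l = 1, H2 = 1) {
  structure(list(sigma2_G = s2G, sigma2_L = 0, sigma2_e = s2e, l = l, H2 = H2),
            class = "varcomp")
}

test_that("a noiseless linear signal is recovered almost perfectly", {
  set.seed(3)
  n <- 120; p <- 15
  X <- matrix(rbinom(n * p, 1, 0.5) * 2, n, p,
              dimnames = list(NULL, paste0("m", 1:p)))
  y <- as.vector(X %*% rnorm(p))
  cv <- run_cv(y, X, fake_vc(s2G = var(y), s2e = 1e-8 * var(y)),
               n_replicates = 5, seed = 2)
  expect_gte(cv$mean_r_GS, 0.99)
})

test_that("pure noise gives accuracy centered at zero", {
  ## fold-only replication converges to a dataset-specific constant, so the
  ## null must be checked across fresh datasets
  set.seed(4)
  n <- 100; p <- 50
  means <- sapply(1:30, function(k) {
    X <- matrix(rbinom(n * p, 1, 0.5) * 2, n, p)
    y <- rnorm(n)
    run_cv(y, X, fake_vc(s2G = 1, s2e = 1, l = 1),
           n_replicates = 3, seed = k)$mean_r_GS
  })
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 3 * se)
})

test_that("fold partitions are balanced, exhaustive and seed-reproducible", {
  pan <- small_panel(seed = 71, n_lines = 63, n_snps = 80)
  vc <- fit_varcomp(pan$pheno)
  b <- compute_blues(pan$pheno, vc)[pan$geno$line_ids]
  cv1 <- run_cv(b, pan$geno, vc, n_replicates = 3, seed = 9)
  cv2 <- run_cv(b, pan$geno, vc, n_replicates = 3, seed = 9)
  expect_identical(cv1$replicates, cv2$replicates)
  ## first replicates agree regardless of how many are run (substreams)
  cv3 <- run_cv(b, pan$geno, vc, n_replicates = 1, seed = 9)
  expect_equal(cv3$replicates$r_GS[1], cv1$replicates$r_GS[1])
  ## direct check of the partition invariant
  set.seed(1)
  fold <- sample(rep(1:5, length.out = 63))
  expect_equal(sort(unique(fold)), 1:5)
  expect_lte(diff(range(table(fold))), 1)
  ## guard rails
  expect_error(run_cv(b, pan$geno, vc, n_folds = 30), "fold size")
  vc0 <- vc; vc0$H2 <- 0
  expect_error(run_cv(b, pan$geno, vc0), "H2")
})

test_that("r_GS standardization divides r_MP by sqrt(H2)", {
  pan <- small_panel(seed = 72, n_lines = 60, n_snps = 80)
  vc <- fit_varcomp(pan$pheno)
  b <- compute_blues(pan$pheno, vc)[pan$geno$line_ids]
  cv <- run_cv(b, pan$geno, vc, n_replicates = 4, seed = 3)
  expect_equal(cv$replicates$r_GS, cv$replicates$r_MP / sqrt(vc$H2))
})

test_that("accuracy rises with heritability at fixed architecture", {
  means <- sapply(c(0.3, 0.63, 0.96), function(h2) {
    pan <- small_panel(seed = 73, h2 = h2, n_lines = 120, n_snps = 200)
    vc <- fit_varcomp(pan$pheno)
    b <- compute_blues(pan$pheno, vc)[pan$geno$line_ids]
    run_cv(b, pan$geno, vc, n_replicates = 20, seed = 4)$mean_r_MP
  })
  expect_true(all(diff(means) > -0.02))   # one MC-SE slack
})

test_that("subpop-differentiated trait architecture loses accuracy within one group", {
  cfg <- sim_config(n_lines = 200, n_snps = 800, n_chromosomes = 4,
                    chrom_length_bp = 8e6, subpop_sizes = c(120, 80),
                    divergence_fst = 0.25, n_qtl = 100, target_h2 = 0.8,
                    n_locations = 8, master_seed = 33)
  sg <- simulate_genotypes(cfg)
  ## causal loci on the most ecotype-differentiated markers: the mixed panel
  ## predicts the between-group component that within-group CV cannot use
  p1 <- colMeans(sg$geno$dosages[sg$truth$subpop == 1, ]) / 2
  p2 <- colMeans(sg$geno$dosages[sg$truth$subpop == 2, ]) / 2
  qtl <- order(-abs(p1 - p2))[1:80]
  set.seed(1)
  gval <- as.vector(sg$geno$dosages[, qtl] %*% rnorm(80))
  gval <- (gval - mean(gval)) / sd(gval)
  n <- 200; l <- 8; s2e <- l * (1 - 0.8) / 0.8
  ph <- data.frame(line_id = rep(sg$geno$line_ids, l),
                   location_id = rep(paste0("E", 1:l), each = n),
                   value = rep(gval, l) + rep(rnorm(l), each = n) +
                     rnorm(n * l, 0, sqrt(s2e)))
  vc <- fit_varcomp(ph)
  b <- compute_blues(ph, vc)[sg$geno$line_ids]
  ct <- cv_subpop_contrast(b, sg$geno, vc, sg$truth$subpop, 1,
                           n_replicates = 20, seed = 7)
  expect_gt(ct$pct_decrease, 0)
})

test_that("the subpopulation contrast is near zero for an arbitrary split", {
  pan <- small_panel(seed = 74, n_lines = 100, n_snps = 150,
                     n_subpops = 1, subpop_sizes = 100)
  vc <- fit_varcomp(pan$pheno)
  b <- compute_blues(pan$pheno, vc)[pan$geno$line_ids]
  groups <- rep(c("a", "b"), each = 50)
  ct <- cv_subpop_contrast(b, pan$geno, vc, groups, "a",
                           n_replicates = 40, seed = 6)
  ## the fixed "group" is one particular half of an exchangeable panel, so
  ## its accuracy can sit a little off the random-subset average; the check
  ## allows that finite-panel wobble on top of Monte-Carlo error
  diffs <- ct$replicates$r_GS_matched - ct$replicates$r_GS_group
  mc_se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * mc_se + 0.05)
  ## determinism
  ct2 <- cv_subpop_contrast(b, pan$geno, vc, groups, "a",
                            n_replicates = 1, seed = 6)
  expect_equal(ct2$replicates$r_GS_group, ct$replicates$r_GS_group[1])
  expect_error(cv_subpop_contrast(b, pan$geno, vc, groups, "a", n_folds = 40),
               "too small")
})
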