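balanced_pheno <- function(n = 15, l = 5, sg = 2, sl = 1, se = 0.5, seed = 7) {
  set.seed(seed)
  g <- rnorm(n, 0, sqrt(sg)); L <- rnorm(l, 0, sqrt(sl))
  data.frame(line_id = rep(sprintf("L%02d", 1:n), l),
             location_id = rep(sprintf("E%02d", 1:l), each = n),
             value = 10 + rep(g, l) + rep(L, each = n) + rnorm(n * l, 0, sqrt(se)))
}

test_that("REML matches the balanced ANOVA closed forms", {
  for (seed in c(7, 8, 9)) {
    ph <- balanced_pheno(seed = seed)
    vc <- fit_varcomp(ph)
    or <- anova_vc_oracle(ph)
    expect_equal(vc$sigma2_e, or$sigma2_e, tolerance = 1e-6)
    expect_equal(vc$sigma2_G, or$sigma2_G, tolerance = 1e-6)
    expect_equal(vc$sigma2_L, or$sigma2_L, tolerance = 1e-6)
    expect_equal(vc$H2, vc$sigma2_G / (vc$sigma2_G + vc$sigma2_e / vc$l))
  }
})

test_that("REML agrees with lme4 on unbalanced data", {
  skip_if_not_installed("lme4")
  ph <- balanced_pheno(n = 20, l = 6, seed = 12)
  set.seed(13)
  ph <- ph[-sample(nrow(ph), 15), ]   # 12.5% records deleted
  vc <- fit_varcomp(ph)
  fm <- lme4::lmer(value ~ (1 | line_id) + (1 | location_id), data = ph)
  v <- as.data.frame(lme4::VarCorr(fm))
  expect_equal(vc$sigma2_G, v$vcov[v$grp == "line_id"], tolerance = 1e-4)
  expect_equal(vc$sigma2_L, v$vcov[v$grp == "location_id"], tolerance = 1e-4)
  expect_equal(vc$sigma2_e, v$vcov[v$grp == "Residual"], tolerance = 1e-4)
})

test_that("noise-free data yields zero residual variance", {
  ph <- balanced_pheno(se = 0, seed = 3)
  vc <- fit_varcomp(ph)
  expect_lt(vc$sigma2_e, 1e-6)
  line_means <- tapply(ph$value, ph$line_id, mean)
  expect_equal(vc$sigma2_G, var(line_means), tolerance = 1e-3)
  expect_equal(vc$H2, 1, tolerance = 1e-6)
})

test_that("the EM iterations never decrease the REML log-likelihood", {
  ph <- balanced_pheno(n = 12, l = 4, seed = 5)
  set.seed(6)
  ph <- ph[-sample(nrow(ph), 5), ]
  vc <- fit_varcomp(ph, trace = TRUE)
  lls <- vc$em_loglik
  expect_gt(length(lls), 1)
  expect_true(all(diff(lls) > -1e-8))
})

test_that("heritability is invariant to affine trait rescaling", {
  ph <- balanced_pheno(seed = 17)
  vc1 <- fit_varcomp(ph)
  ph$value <- 3.7 * ph$value - 12
  vc2 <- fit_varcomp(ph)
  expect_equal(vc2$H2, vc1$H2, tolerance = 1e-6)
  expect_equal(vc2$sigma2_G, 3.7^2 * vc1$sigma2_G, tolerance = 1e-4)
})

test_that("disconnected designs and undersized inputs are rejected", {
  ph <- data.frame(line_id = c("A", "A", "B", "B"),
                   location_id = c("1", "2", "3", "4"),
                   value = 1:4)
  expect_error(fit_varcomp(ph), "not connected")
  expect_error(fit_varcomp(data.frame(line_id = "A", location_id = "1", value = 1)),
               "2 lines")
  ph2 <- data.frame(line_id = c("A", "A"), location_id = c("1", "1"), value = 1:2)
  expect_error(fit_varcomp(ph2), "one record per line")
})

test_that("BLUEs equal line means on balanced data, for any variance ratio", {
  ph <- balanced_pheno(seed = 19)
  vc <- fit_varcomp(ph)
  b <- compute_blues(ph, vc)
  means <- tapply(ph$value, factor(ph$line_id), mean)
  expect_equal(unname(b), as.vector(means[names(b)]), tolerance = 1e-10)
  ## invariance to the variance ratio on balanced data
  vc2 <- vc; vc2$sigma2_L <- 17 * vc$sigma2_L
  expect_equal(compute_blues(ph, vc2), b, tolerance = 1e-10)
  ## single location: BLUEs are the observed values
  ph1 <- ph[ph$location_id == "E01", ]
  vc1 <- suppressWarnings(fit_varcomp(ph1))
  b1 <- compute_blues(ph1, vc1)
  expect_equal(unname(b1), ph1$value[match(names(b1), ph1$line_id)])
})

test_that("BLUEs on unbalanced data match the explicit GLS oracle", {
  ph <- balanced_pheno(n = 30, l = 6, seed = 23)
  set.seed(24)
  ph <- ph[-sample(nrow(ph), 18), ]   # 10% records deleted
  vc <- fit_varcomp(ph)
  b <- compute_blues(ph, vc)
  oracle <- gls_blues_oracle(ph, vc$sigma2_L, vc$sigma2_e)
  expect_equal(b, oracle[names(b)], tolerance = 1e-8)
})

test_that("the subpopulation contrast behaves at the null and rejects degenerate input", {
  set.seed(31)
  b <- rnorm(60)
  groups <- rep(c("NS", "HH"), each = 30)
  ct <- contrast_subpopulations(b, groups)
  expect_equal(ct$t, unname(t.test(b[1:30], b[31:60])$statistic))
  ## identical groups => t exactly 0
  ct0 <- contrast_subpopulations(c(b[1:30], b[1:30]), groups)
  expect_equal(ct0$t, 0)
  ## degenerate: both groups constant
  expect_error(contrast_subpopulations(rep(c(0, 1), each = 5),
                                       rep(c("a", "b"), each = 5)),
               "zero within-group variance")
  expect_error(contrast_subpopulations(b, rep("NS", 60)), "two groups")
})

test_that("a one-SD shift between groups of 185/50 is detected with high power", {
  ## Monte-Carlo power at alpha = 0.01 for a 1-SD mean shift
  set.seed(41)
  hits <- 0; nrep <- 500
  for (r in seq_len(nrep)) {
    a <- rnorm(185); b <- rnorm(50, mean = 1)
    ct <- contrast_subpopulations(c(a, b), rep(c("A", "B"), c(185, 50)))
    if (ct$p_value < 0.01) hits <- hits + 1
  }
  expect_gt(hits / nrep, 0.99)
})
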