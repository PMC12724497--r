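test_that("Spearman correlation, CI and p behave as specified", {
  r1 <- spearman_with_ci(1:10, 1:10, B = 200, seed = 1)
  expect_equal(r1$rho, 1)
  expect_equal(c(r1$ci_low, r1$ci_high), c(1, 1))
  r2 <- spearman_with_ci(1:10, 10:1, B = 50, seed = 1)
  expect_equal(r2$rho, -1)
  r3 <- spearman_with_ci(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4), B = 50, seed = 1)
  expect_equal(r3$rho, 0.8)
  expect_true(r3$ci_low <= r3$rho && r3$rho <= r3$ci_high)
  expect_warning(rc <- spearman_with_ci(rep(1, 6), 1:6, B = 10, seed = 1),
                 "constant")
  expect_true(is.na(rc$rho))
  expect_error(spearman_with_ci(1:3, 1:3), "at least 4")
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  set.seed(5)
  base <- c(0.001, 0.008, 0.04, 0.04, 0.2, 0.9)
  for (i in 1:30) {
    p <- sample(base)
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_true(all(bh_fdr(base) >= base))
})

test_that("rank eta-squared reproduces the reference (H, n, k) triples", {
  expect_equal(round(eta2_from_h(167.15, 283, 5), 3), 0.587)
  expect_equal(round(eta2_from_h(121.50, 277, 5), 3), 0.432)
  expect_equal(round(eta2_from_h(170.68, 270, 5), 3), 0.629)
  expect_equal(round(eta2_from_h(165.25, 283, 5), 3), 0.580)
  expect_equal(round(eta2_from_h(127.11, 283, 4), 3), 0.445)
  # zero point: H = k - 1 maps to 0
  expect_equal(eta2_from_h(4, 100, 5), 0)
  expect_error(eta2_from_h(10, 5, 5), "n > k")
})

test_that("the Kruskal-Wallis wrapper agrees with the base test", {
  set.seed(6)
  x <- rnorm(60)
  g <- rep(1:3, each = 20)
  r <- kruskal_eta2(x, g)
  kt <- kruskal.test(x, factor(g))
  expect_equal(r$H, unname(kt$statistic))
  expect_equal(r$p, unname(kt$p.value))
  expect_equal(r$eta2, (r$H - 2) / (60 - 3))
  expect_error(kruskal_eta2(x, rep(1, 60)), "2 nonempty")
})

test_that("Cliff's delta matches exhaustive pair enumeration", {
  expect_equal(cliffs_delta(c(1, 2, 3), c(4, 5, 6), B = 0)$delta, -1)
  expect_equal(cliffs_delta(c(2, 5, 5, 9), c(2, 5, 5, 9), B = 0)$delta, 0)
  expect_equal(cliffs_delta(c(1, 3), c(2, 4), B = 0)$delta, -0.5)
  set.seed(7)
  for (i in 1:40) {
    a <- sample(1:8, sample(2:20, 1), replace = TRUE)
    b <- sample(1:8, sample(2:20, 1), replace = TRUE)
    expect_equal(cliffs_delta(a, b, B = 0)$delta, cliffs_oracle(a, b),
                 tolerance = 1e-12)
  }
  cd <- cliffs_delta(rnorm(30), rnorm(30) + 1, B = 200, seed = 2)
  expect_true(cd$ci_low <= cd$delta && cd$delta <= cd$ci_high)
  expect_true(cd$ci_low >= -1 && cd$ci_high <= 1)
})

test_that("Cramer's V matches hand computation", {
  expect_equal(cramers_v(matrix(c(10, 0, 0, 10), 2)), 1)
  marg <- outer(c(12, 8), c(6, 14)) / 20
  expect_equal(cramers_v(round(marg * 20)), 0, tolerance = 1e-12)
  expect_equal(cramers_v(matrix(c(6, 4, 4, 6), 2)), 0.2, tolerance = 1e-12)
  expect_error(cramers_v(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margins")
})

test_that("categorical cluster tests switch to Fisher on sparse tables", {
  dense <- matrix(c(30, 20, 25, 35), 2)
  sparse <- matrix(c(8, 1, 2, 9), 2)
  expect_equal(cluster_category_test(dense)$method, "chisq")
  expect_equal(cluster_category_test(sparse)$method, "fisher")
  expect_true(cluster_category_test(dense)$cramers_v >= 0)
})

test_that("adjusted regression recovers exact effects and flags collinearity", {
  set.seed(8)
  n <- 80
  df <- data.frame(mpis = rnorm(n), age = rnorm(n, 60, 8),
                   sex = sample(c("M", "F"), n, replace = TRUE))
  df$y <- 2 * df$mpis
  # exact fits make lm's inference summaries warn; the estimates are the point
  r <- suppressWarnings(adjusted_regression(df, "y", "mpis"))
  expect_equal(r$coefficients$estimate, 2, tolerance = 1e-10)
  expect_equal(r$r_squared, 1, tolerance = 1e-10)
  r2 <- suppressWarnings(adjusted_regression(df, "y", "mpis",
                                             c("age", "sex")))
  expect_equal(r2$coefficients$estimate[1], 2, tolerance = 1e-8)
  expect_gt(r2$partial_r2, 0.99)
  df$dup <- df$mpis
  expect_error(adjusted_regression(df, "y", c("mpis", "dup")),
               "collinear")
})

test_that("regression CIs achieve nominal coverage under a planted null", {
  set.seed(9)
  cover <- 0
  for (i in 1:500) {
    n <- 60
    x <- rnorm(n); y <- rnorm(n)  # predictor orthogonal to outcome
    r <- adjusted_regression(data.frame(x = x, y = y), "y", "x")
    cover <- cover + (r$coefficients$ci_low <= 0 & 0 <= r$coefficients$ci_high)
  }
  expect_gte(cover / 500, 0.94)
})

test_that("partition concordance permutation test behaves at both extremes", {
  a <- rep(1:5, each = 60)
  cp <- concordance_permutation(a, a, n_perm = 99, seed = 1)
  expect_equal(cp$nmi, 1); expect_equal(cp$ari, 1)
  expect_equal(cp$p_nmi, 1 / 100)
  # relabeled partition is still perfectly concordant
  b <- c(3, 4, 5, 1, 2)[a]
  cp2 <- concordance_permutation(a, b, n_perm = 99, seed = 1)
  expect_equal(cp2$ari, 1)
  # independent labelings: non-significant, and p never zero
  set.seed(10)
  x <- sample(1:5, 300, replace = TRUE)
  y <- sample(1:6, 300, replace = TRUE)
  cp3 <- concordance_permutation(x, y, n_perm = 199, seed = 2)
  expect_gt(cp3$p_nmi, 0.05)
  expect_gt(cp3$p_ari, 0)
  expect_error(concordance_permutation(1:4, 1:5), "length")
})

test_that("cluster composition summaries conserve counts", {
  cfg <- synthetic_config(n_per_group = c(PD = 60, HC = 25, SWEDD = 15),
                          seed = 11)
  co <- generate_cohort(cfg)
  labels <- co$truth$row_labels
  tab <- summarize_clusters(co$clinical, labels)
  expect_equal(sum(tab$n), 100)
  expect_equal(sum(tab$n_pd), 60)
  expect_equal(sum(tab$n_swedd), 15)
  # single cluster equals the whole-cohort summary
  tab1 <- summarize_clusters(co$clinical, rep(1, 100))
  expect_equal(tab1$n, 100)
  expect_equal(tab1$female_pct,
               round(100 * mean(co$clinical$sex == "F"), 1))
})

test_that("the association table mirrors its inputs and adjusts across the family", {
  cfg <- synthetic_config(
    n_per_group = c(PD = 150, HC = 60, SWEDD = 40),
    row_clusters = list(k = 1, prop = 1, shift = 0),
    pathway_effects = list(nigrostriatal = c(UPDRS3 = -0.5)),
    noise_sd = 0.05, seed = 12)
  co <- generate_cohort(cfg)
  fm <- zscore_columns(load_feature_table(co$features)$features)
  m <- compute_mpis(fm, assign_pathway_bins(fm$descriptors, cfg$bin_spec))
  tab <- mpis_association_table(m, co$clinical, B = 100, seed = 1)
  expect_equal(nrow(tab), 6 * 3)
  expect_true(all(tab$q >= tab$p))
  strongest <- tab[tab$pathway == "nigrostriatal" & tab$outcome == "UPDRS3", ]
  expect_lt(strongest$rho, -0.3)
  expect_lt(strongest$q, 0.05)
})
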