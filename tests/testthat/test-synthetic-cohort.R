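test_that("Gaussian-copula map between Spearman and Pearson is correct", {
  expect_identical(copula_pearson_from_spearman(0), 0)
  expect_equal(copula_pearson_from_spearman(1 - 1e-12), 1, tolerance = 1e-9)
  expect_equal(copula_pearson_from_spearman(0.5), 0.5176381, tolerance = 1e-6)
  expect_equal(copula_pearson_from_spearman(-0.3),
               -copula_pearson_from_spearman(0.3))
  expect_error(copula_pearson_from_spearman(1), "rho_s")
  expect_error(copula_pearson_from_spearman(-1.2), "rho_s")
})

test_that("copula planting induces the target Spearman in bivariate normals", {
  # oracle property: at large n the empirical Spearman matches the target
  set.seed(42)
  n <- 1e5
  for (rho_s in seq(-0.9, 0.9, by = 0.3)) {
    rho_p <- copula_pearson_from_spearman(rho_s)
    u <- rnorm(n)
    v <- rho_p * u + sqrt(1 - rho_p^2) * rnorm(n)
    expect_equal(cor(u, v, method = "spearman"), rho_s, tolerance = 0.01)
  }
})

test_that("cohort generation reproduces requested group composition", {
  cfg <- synthetic_config(n_per_group = c(PD = 185, HC = 72, SWEDD = 37),
                          seed = 3)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$clinical), 294)
  expect_equal(as.vector(table(co$clinical$diagnosis)[c("PD", "HC", "SWEDD")]),
               c(185, 72, 37))
  expect_equal(nrow(co$features), 294)
  # ground-truth invariants
  expect_true(all(co$truth$row_labels %in% seq_len(cfg$row_clusters$k)))
  expect_equal(colMeans(co$truth$pathway_latents),
               rep(0, ncol(co$truth$pathway_latents)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(apply(co$truth$pathway_latents, 2, sd),
               rep(1, ncol(co$truth$pathway_latents)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("null configuration leaves latents and outcomes uncorrelated", {
  cfg <- synthetic_config(
    n_per_group = c(PD = 300, HC = 120, SWEDD = 80),
    pathway_effects = list(), seed = 5)
  co <- generate_cohort(cfg)
  band <- 1.96 / sqrt(500 - 1)
  for (p in c("nigrostriatal", "sensory"))
    for (o in c("updrs3", "moca"))
      expect_lt(abs(cor(co$truth$pathway_latents[, p], co$clinical[[o]],
                        method = "spearman")), band)
})

test_that("planted rank effects are realized at their target magnitude", {
  # Monte-Carlo check of the copula oracle through the whole generator
  rhos <- numeric(10)
  for (s in 1:10) {
    cfg <- synthetic_config(
      n_per_group = c(PD = 3000, HC = 1200, SWEDD = 800),
      pathway_effects = list(nigrostriatal = c(UPDRS3 = -0.5)),
      seed = 100 + s)
    co <- generate_cohort(cfg)
    rhos[s] <- cor(co$truth$pathway_latents[, "nigrostriatal"],
                   co$clinical$updrs3, method = "spearman")
  }
  expect_equal(mean(rhos), -0.5, tolerance = 0.02)
})

test_that("monotone transforms leave the planted Spearman untouched", {
  cfg <- synthetic_config(seed = 9)
  co <- generate_cohort(cfg)
  u <- co$truth$pathway_latents[, "nigrostriatal"]
  y <- co$clinical$updrs3
  expect_identical(cor(u, y, method = "spearman"),
                   cor(u, exp(y / 10), method = "spearman"))
  expect_identical(cor(u, y, method = "spearman"),
                   cor(u, 3 * y + 7, method = "spearman"))
})

test_that("generation is deterministic given the seed", {
  cfg <- synthetic_config(seed = 17)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$features, b$features)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(synthetic_config(seed = 18))
  expect_false(identical(a$features, c2$features))
})

test_that("well-separated planted rows are k-means recoverable from raw features", {
  cfg <- two_cluster_config(n = 120, shift = 5, noise_sd = 1, seed = 2)
  co <- generate_cohort(cfg)
  lt <- load_feature_table(co$features)
  imaging <- lt$features$descriptors$modality %in% c("VOL", "FA", "MD", "SBR") &
    lt$features$descriptors$roi != "icv"
  km <- kmeans(lt$features$values[, imaging], 2, nstart = 10)
  expect_equal(ari(km$cluster, co$truth$row_labels), 1)
})

test_that("verify_planting flags nothing on a faithful cohort and stays well-formed at tiny n", {
  cfg <- synthetic_config(
    n_per_group = c(PD = 1500, HC = 300, SWEDD = 200),
    pathway_effects = list(nigrostriatal = c(UPDRS3 = -0.3),
                           sensory = c(MoCA = 0.25)),
    seed = 21)
  co <- generate_cohort(cfg)
  rep1 <- verify_planting(co$features, co$clinical, co$truth, B = 100)
  expect_equal(nrow(rep1), 2)
  expect_false(any(rep1$flagged))

  cfg2 <- synthetic_config(n_per_group = c(PD = 10, HC = 6, SWEDD = 4),
                           seed = 22)
  co2 <- generate_cohort(cfg2)
  rep2 <- verify_planting(co2$features, co2$clinical, co2$truth, B = 100)
  expect_true(all(is.finite(rep2$ci_low) & is.finite(rep2$ci_high)))
  expect_true(all(rep2$ci_low <= rep2$realized &
                    rep2$realized <= rep2$ci_high))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(seed = 1,
                                row_clusters = list(k = 2, prop = c(0.6, 0.6),
                                                    shift = 1)),
               "sum to 1")
  expect_error(synthetic_config(seed = 1, noise_sd = 0), "noise_sd")
  expect_error(synthetic_config(seed = 1,
                                pathway_effects = list(foo = c(UPDRS3 = 0.2))),
               "unknown pathway")
  expect_error(synthetic_config(seed = 1,
                                pathway_effects = list(
                                  nigrostriatal = c(UPDRS3 = 1))),
               "< 1")
  expect_error(synthetic_config(), "seed")
})

test_that("cohorts round-trip through the CSV dialect", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_per_group = c(PD = 20, HC = 8, SWEDD = 4),
                          seed = 30)
  co <- generate_cohort(cfg)
  write_cohort(co, dir)
  lt_mem <- load_feature_table(co$features, co$clinical)
  lt_csv <- load_feature_table(file.path(dir, "features.csv"),
                               file.path(dir, "clinical.csv"))
  expect_equal(lt_csv$features$values, lt_mem$features$values,
               tolerance = 1e-12)
  expect_identical(lt_csv$features$descriptors$name,
                   lt_mem$features$descriptors$name)
})
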