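std_fm <- function(df) {
  zscore_columns(load_feature_table(df)$features)
}

test_that("canonical bins realize the reference feature counts", {
  schema <- canonical_schema()
  bins <- assign_pathway_bins(schema, canonical_bin_spec())
  expect_equal(unname(attr(bins, "counts")),
               c(88L, 128L, 20L, 80L, 4L, 112L))
  # shared thalamic features appear in both striatal pathways
  thal <- schema$name[which(schema$roi == "thalamus" &
                              schema$modality == "FA")]
  expect_true(all(thal %in% bins$nigrostriatal$members$FA))
  expect_true(all(thal %in% bins$frontostriatal$members$FA))
  # member sets are modality-disjoint within each bin
  for (b in bins)
    expect_equal(anyDuplicated(unlist(b$members)), 0)
})

test_that("empty or partially matching bin specs degrade gracefully", {
  schema <- canonical_schema()
  empty <- assign_pathway_bins(schema, list())
  expect_length(empty, 0)
  spec <- list(toy = list(
    members = data.frame(roi = c("putamen", "not_a_region"),
                         modality = c("FA", "FA")),
    signs = c(FA = 1), weights = c(FA = 1)))
  expect_warning(bins <- assign_pathway_bins(schema, spec), "not_a_region")
  expect_equal(length(bins$toy$members$FA), 2)  # putamen L/R
})

test_that("single-feature bins reproduce the sign convention exactly", {
  df <- data.frame(subject_id = paste0("s", 1:4),
                   a_FA_L = c(1, 2, 3, 10), a_MD_L = c(4, 1, 0, 7))
  fm <- std_fm(df)
  spec <- list(fa_only = list(members = data.frame(roi = "a", modality = "FA"),
                              signs = c(FA = 1), weights = c(FA = 1)),
               md_only = list(members = data.frame(roi = "a", modality = "MD"),
                              signs = c(MD = -1), weights = c(MD = 1)))
  m <- compute_mpis(fm, assign_pathway_bins(fm$descriptors, spec))
  expect_equal(m$scores[, "fa_only"], fm$values[, "a_FA_L"],
               ignore_attr = TRUE)
  expect_equal(m$scores[, "md_only"], -fm$values[, "a_MD_L"],
               ignore_attr = TRUE)
})

test_that("a mixed FA/MD bin matches the hand-computed composite", {
  # z-scores (-1,0,1) and (1,0,-1); signed sum (-2,0,2); standardized (-1,0,1)
  df <- data.frame(subject_id = paste0("s", 1:3),
                   a_FA_L = c(1, 2, 3), a_MD_L = c(3, 2, 1))
  fm <- std_fm(df)
  expect_equal(fm$values[, "a_FA_L"], c(-1, 0, 1), ignore_attr = TRUE)
  spec <- list(mix = list(
    members = data.frame(roi = c("a", "a"), modality = c("FA", "MD")),
    signs = c(FA = 1, MD = -1), weights = c(FA = 1, MD = 1)))
  m <- compute_mpis(fm, assign_pathway_bins(fm$descriptors, spec))
  expect_equal(m$scores[, "mix"], c(-1, 0, 1), ignore_attr = TRUE)
})

test_that("MPIS columns are exactly standardized and equivariant", {
  cfg <- synthetic_config(n_per_group = c(PD = 40, HC = 15, SWEDD = 10),
                          seed = 4)
  co <- generate_cohort(cfg)
  fm <- zscore_columns(load_feature_table(co$features)$features)
  bins <- assign_pathway_bins(fm$descriptors, cfg$bin_spec)
  m <- compute_mpis(fm, bins)
  expect_true(all(abs(colMeans(m$scores)) < 1e-9))
  expect_true(all(abs(apply(m$scores, 2, sd) - 1) < 1e-9))

  # permuting subjects permutes rows identically
  perm <- sample(nrow(fm$values))
  fm_p <- pathwaycc:::new_feature_matrix(
    fm$values[perm, ], fm$subject_ids[perm], fm$descriptors,
    standardized = TRUE)
  m_p <- compute_mpis(fm_p, bins)
  expect_equal(m_p$scores, m$scores[perm, ], tolerance = 1e-12)

  # rescaling all weights in a bin leaves the standardized score unchanged
  spec2 <- cfg$bin_spec
  spec2$nigrostriatal$weights <- spec2$nigrostriatal$weights * 7
  m2 <- compute_mpis(fm, assign_pathway_bins(fm$descriptors, spec2))
  expect_equal(m2$scores[, "nigrostriatal"], m$scores[, "nigrostriatal"],
               tolerance = 1e-9)
})

test_that("MPIS recovers the planted pathway latent as noise vanishes", {
  cfg <- synthetic_config(
    n_per_group = c(PD = 120, HC = 50, SWEDD = 30),
    row_clusters = list(k = 1, prop = 1, shift = 0),
    pathway_effects = list(), noise_sd = 0.01, seed = 6)
  co <- generate_cohort(cfg)
  fm <- zscore_columns(load_feature_table(co$features)$features)
  m <- compute_mpis(fm, assign_pathway_bins(fm$descriptors, cfg$bin_spec))
  for (p in c("nigrostriatal", "sensory", "limbic"))
    expect_gt(cor(m$scores[, p], co$truth$pathway_latents[, p]), 0.999)
})

test_that("variant scores behave as specified", {
  cfg <- synthetic_config(n_per_group = c(PD = 60, HC = 25, SWEDD = 15),
                          seed = 8)
  co <- generate_cohort(cfg)
  lt <- load_feature_table(co$features)
  fm <- zscore_columns(lt$features)
  bins <- assign_pathway_bins(fm$descriptors, cfg$bin_spec)
  primary <- compute_mpis(fm, bins)

  # nonsigned MD is vacuous for a bin without MD members
  spec_noMD <- list(sbr_only = list(
    members = data.frame(roi = "putamen", modality = "SBR"),
    signs = c(SBR = 1), weights = c(SBR = 1)))
  bins_noMD <- assign_pathway_bins(fm$descriptors, spec_noMD)
  a <- compute_mpis(fm, bins_noMD)
  b <- compute_mpis(fm, bins_noMD, mpis_variant("nonsigned_md"))
  expect_equal(a$scores, b$scores, tolerance = 1e-12)

  # ICV-normalized variant with head size independent of the features
  # stays strongly concordant with the primary score
  icv <- compute_mpis(lt$features, bins, mpis_variant("icv_normalized"))
  conc <- mpis_variant_concordance(primary, list(icv = icv))
  expect_gte(conc$median_pearson[["icv"]], 0.9)

  # identical variant gives perfect concordance
  conc_id <- mpis_variant_concordance(primary, list(same = primary))
  expect_equal(conc_id$correlations$pearson, rep(1, 6), tolerance = 1e-12)
  expect_equal(conc_id$correlations$spearman, rep(1, 6), tolerance = 1e-12)

  # pathway-weighted differs only where the reweighting applies
  pw <- compute_mpis(fm, bins, mpis_variant("pathway_weighted"))
  expect_equal(pw$scores[, "sensory"], primary$scores[, "sensory"],
               tolerance = 1e-9)
  expect_gt(max(abs(pw$scores[, "nigrostriatal"] -
                      primary$scores[, "nigrostriatal"])), 1e-6)
})

test_that("variant preconditions are enforced", {
  cfg <- synthetic_config(n_per_group = c(PD = 10, HC = 4, SWEDD = 2),
                          seed = 2)
  co <- generate_cohort(cfg)
  lt <- load_feature_table(co$features)
  fm <- zscore_columns(lt$features)
  bins <- assign_pathway_bins(fm$descriptors, cfg$bin_spec)
  expect_error(compute_mpis(fm, bins, mpis_variant("icv_normalized")),
               "raw feature matrix")
  expect_error(compute_mpis(lt$features, bins), "standardized")
  spec <- list(ghost = list(
    members = data.frame(roi = "nothing_here", modality = "FA"),
    signs = c(FA = 1), weights = c(FA = 1)))
  bins_g <- suppressWarnings(assign_pathway_bins(fm$descriptors, spec))
  expect_warning(mg <- compute_mpis(fm, bins_g), "no member features")
  expect_true(all(is.na(mg$scores[, "ghost"])))
})
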