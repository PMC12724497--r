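#!/usr/bin/env Rscript
# Stage 4: stability of the selected co-clustering.
#
# Two complementary checks on the configuration adopted in stage 3:
# (i) 10 retrains from different seeds, all pairwise ARI/NMI between the
# hard subject partitions; (ii) a nonparametric subject bootstrap
# (resamples of 80% of subjects drawn with replacement, refit, compared
# to the full-sample solution on the unique subjects present).  The
# bootstrap uses 30 resamples here (desk scale; the full protocol uses
# 100).

suppressMessages(library(pathwaycc))

lt <- load_feature_table("results/cohort/features.csv",
                         "results/cohort/clinical.csv")
fm <- attach_views(zscore_columns(lt$features), canonical_schema())
fm_v4 <- select_view(fm, "V4")
keep <- fm_v4$descriptors$modality != "CLIN"
fm_clust <- pathwaycc:::new_feature_matrix(
  fm_v4$values[, keep, drop = FALSE], fm_v4$subject_ids,
  fm_v4$descriptors[keep, , drop = FALSE], standardized = TRUE)

sel <- read.csv("results/selection_cells.csv")
best <- sel[order(sel$kr + sel$kc, sel$kr), ]
kr <- read.csv("results/row_clusters.csv")
kr_n <- length(unique(kr$cluster))
kc_n <- length(unique(read.csv("results/col_clusters.csv")$cluster))
ctl <- srvcc_control(pretrain_epochs = 20, epochs = 50, warmup = 20,
                     lr = 3e-3, seed = 1)

st <- seed_stability(fm_clust, kr_n, kc_n, n_seeds = 10, control = ctl)
write.csv(data.frame(pair_ari = st$pairwise_ari,
                     pair_nmi = st$pairwise_nmi),
          "results/seed_stability.csv", row.names = FALSE)
cat(sprintf("seed stability (10 retrains, %d pairs): median ARI %.3f [IQR %.3f-%.3f], median NMI %.3f\n",
            length(st$pairwise_ari), st$ari_summary[["median"]],
            st$ari_summary[["iqr_low"]], st$ari_summary[["iqr_high"]],
            st$nmi_summary[["median"]]))

bs <- suppressWarnings(bootstrap_stability(fm_clust, kr_n, kc_n, B = 30,
                                           frac = 0.8, control = ctl))
write.csv(data.frame(boot_ari = bs$bootstrap_ari,
                     boot_nmi = bs$bootstrap_nmi),
          "results/bootstrap_stability.csv", row.names = FALSE)
cat(sprintf("bootstrap stability (%d resamples of 80%%): median ARI %.3f [IQR %.3f-%.3f], median NMI %.3f\n",
            length(bs$bootstrap_ari), bs$ari_summary[["median"]],
            bs$ari_summary[["iqr_low"]], bs$ari_summary[["iqr_high"]],
            bs$nmi_summary[["median"]]))
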