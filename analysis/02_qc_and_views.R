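#!/usr/bin/env Rscript
# Stage 2: ingestion, quality control, standardization and the view ledger.
#
# Reads the cohort CSVs exactly as a real metrics export would be read:
# drops non-numeric and "-std" nuisance columns, removes rows with
# non-finite values or a fully zeroed modality, z-scores every retained
# column (sample SD), and reports the nested feature views.

suppressMessages(library(pathwaycc))

lt <- load_feature_table("results/cohort/features.csv",
                         "results/cohort/clinical.csv")
fm <- zscore_columns(lt$features)
write.csv(fm$qc_ledger, "results/qc_ledger.csv", row.names = FALSE)
cat(sprintf("QC: %d subjects x %d features retained; %d columns dropped, %d rows dropped\n",
            nrow(fm$values), ncol(fm$values),
            sum(fm$qc_ledger$kind == "column"),
            sum(fm$qc_ledger$kind == "row")))

fm <- attach_views(fm, canonical_schema())
views <- data.frame(view = c("V1", "V2", "V3", "V4"))
views$n_features <- vapply(views$view, function(v)
  ncol(select_view(fm, v)$values), integer(1))
write.csv(views, "results/view_sizes.csv", row.names = FALSE)
cat("view ledger:", paste(sprintf("%s=%d", views$view, views$n_features),
                          collapse = ", "), "\n")

bins <- assign_pathway_bins(fm$descriptors, canonical_bin_spec())
counts <- data.frame(pathway = names(bins),
                     n_features = as.integer(attr(bins, "counts")))
write.csv(counts, "results/pathway_bin_sizes.csv", row.names = FALSE)
cat("pathway bins:", paste(sprintf("%s=%d", counts$pathway,
                                   counts$n_features), collapse = ", "), "\n")
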