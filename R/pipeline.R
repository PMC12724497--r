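#' End-to-end analysis pipeline
#'
#' Orchestrates the full analysis: cohort generation or ingestion, quality
#' control and standardization, view selection, co-clustering, optional
#' stability checks, pathway scoring with variants, and the pathway-aware
#' statistical evaluation.  Clustering consumes imaging features only:
#' clinical score columns are stripped from the clustering matrix by
#' default (they are linked post hoc), with an explicit override for the
#' clinical-only ablation.  A run manifest records the configuration, the
#' content hash and wall time of every written artifact, and all captured
#' warnings, so two runs with the same configuration and seed produce
#' identical numeric outputs.
#'
#' @name pipeline
NULL

#' Pipeline run configuration
#'
#' @param mode `"synthetic"` (generate a cohort) or `"csv"` (read paths).
#' @param features_path,clinical_path input CSVs in csv mode.
#' @param synthetic a [synthetic_config()] for synthetic mode (one with
#'   the run seed is built when omitted).
#' @param view feature view used for clustering (default `"V4"`).
#' @param schema optional descriptor schema supplying view tags in csv
#'   mode (synthetic mode uses the generator's own schema).
#' @param bin_spec pathway bins for scoring.
#' @param variants MPIS variants to compute beyond the primary.
#' @param kr,kc cluster counts; when `NULL`, a selection grid is scanned.
#' @param kr_grid,kc_grid selection grid (used when kr/kc are NULL).
#' @param control a [srvcc_control()] (its seed is overridden by `seed`).
#' @param stability list with `n_seeds` and `bootstrap_B` (either 0
#'   disables that stability stage).
#' @param stats list with `B` (bootstrap resamples), `n_perm`
#'   (permutations) and `q_level`.
#' @param allow_clinical_in_clustering keep CLIN columns in the clustering
#'   matrix (the literal clinical-only ablation).
#' @param seed global seed; stage seeds are derived from it at fixed
#'   offsets so stages are independently reproducible.
#' @param out_dir output directory for artifacts.
#' @export
run_config <- function(mode = c("synthetic", "csv"),
                       features_path = NULL, clinical_path = NULL,
                       synthetic = NULL, view = "V4", schema = NULL,
                       bin_spec = canonical_bin_spec(),
                       variants = c("icv_normalized", "pathway_weighted",
                                    "nonsigned_md"),
                       kr = 5, kc = 5, kr_grid = 3:7, kc_grid = 3:7,
                       control = srvcc_control(),
                       stability = list(n_seeds = 0, bootstrap_B = 0),
                       stats = list(B = 1000, n_perm = 1000,
                                    q_level = 0.05),
                       allow_clinical_in_clustering = FALSE,
                       seed = 1, out_dir = tempfile("pathwaycc_run_")) {
  mode <- match.arg(mode)
  if (mode == "csv" &&
      (is.null(features_path) || !file.exists(features_path)))
    stop("csv mode requires an existing features_path")
  if (mode == "csv" && !is.null(clinical_path) &&
      !file.exists(clinical_path))
    stop("clinical_path does not exist")
  list(mode = mode, features_path = features_path,
       clinical_path = clinical_path, synthetic = synthetic, view = view,
       schema = schema,
       bin_spec = bin_spec, variants = variants, kr = kr, kc = kc,
       kr_grid = kr_grid, kc_grid = kc_grid, control = control,
       stability = stability, stats = stats,
       allow_clinical_in_clustering = allow_clinical_in_clustering,
       seed = as.integer(seed), out_dir = out_dir)
}

strip_clinical <- function(fm) {
  keep <- fm$descriptors$modality != "CLIN"
  new_feature_matrix(fm$values[, keep, drop = FALSE], fm$subject_ids,
                     fm$descriptors[keep, , drop = FALSE],
                     standardized = fm$standardized, qc = fm$qc_ledger)
}

#' Run the full pipeline
#'
#' @param config a [run_config()].
#' @return the run manifest (invisibly also written as
#'   `manifest.json`): configuration snapshot, per-stage wall times,
#'   artifact hashes and collected warnings.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(
    utils::packageVersion("pathwaycc")),
    seed = config$seed, mode = config$mode, view = config$view,
    stages = list(), files = list(), warnings = character())
  note <- function(w) manifest$warnings <<- c(manifest$warnings, w)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- withCallingHandlers(expr, warning = function(w) {
      note(paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    val
  }
  emit <- function(df, file) {
    path <- file.path(config$out_dir, file)
    utils::write.csv(df, path, row.names = FALSE)
    path
  }

  # stage: input
  inputs <- stage("input", {
    if (config$mode == "synthetic") {
      syn <- config$synthetic %||%
        synthetic_config(seed = derive_seed(config$seed, 1L))
      cohort <- generate_cohort(syn)
      list(features = cohort$features, clinical = cohort$clinical,
           truth = cohort$truth, schema = syn$schema)
    } else {
      lt <- load_feature_table(config$features_path, config$clinical_path)
      list(features_loaded = lt, truth = NULL, schema = config$schema)
    }
  })

  # stage: QC + standardization
  fm_std <- stage("qc", {
    lt <- if (!is.null(inputs$features_loaded)) inputs$features_loaded
    else load_feature_table(inputs$features, inputs$clinical)
    inputs$clinical <- lt$clinical
    inputs$raw_fm <- lt$features
    fm <- zscore_columns(lt$features)
    if (!is.null(inputs$schema)) fm <- attach_views(fm, inputs$schema)
    fm
  })
  emit(fm_std$qc_ledger, "qc_ledger.csv")

  # stage: clustering matrix (view selection, clinical stripped)
  cluster_fm <- stage("view", {
    fm <- if (!is.null(fm_std$descriptors$views) &&
              any(fm_std$descriptors$views != "")) {
      select_view(fm_std, config$view)
    } else fm_std
    if (!config$allow_clinical_in_clustering) fm <- strip_clinical(fm)
    if (ncol(fm$values) < 2) stop("clustering matrix has fewer than 2 features")
    fm
  })
  manifest$clustering <- list(
    n_subjects = nrow(cluster_fm$values),
    n_features = ncol(cluster_fm$values),
    clinical_stripped = !config$allow_clinical_in_clustering,
    has_clin_columns = any(cluster_fm$descriptors$modality == "CLIN"))

  # stage: model selection (optional) + fit
  ctl <- config$control
  ctl$seed <- derive_seed(config$seed, 2L)
  sel <- NULL
  if (is.null(config$kr) || is.null(config$kc)) {
    sel <- stage("selection", model_selection_grid(
      cluster_fm, config$kr_grid, config$kc_grid, control = ctl))
    config$kr <- sel$selected[["kr"]]
    config$kc <- sel$selected[["kc"]]
    emit(sel$records, "selection_records.csv")
  }
  fit <- stage("cluster", train_srvcc(cluster_fm, config$kr, config$kc, ctl))
  emit(fit$log, "training_log.csv")
  emit(data.frame(subject_id = cluster_fm$subject_ids,
                  cluster = fit$assignments$row_labels), "row_clusters.csv")
  emit(data.frame(feature = cluster_fm$descriptors$name,
                  cluster = fit$assignments$col_labels), "col_clusters.csv")

  # stage: stability (optional)
  stab <- NULL
  if ((config$stability$n_seeds %||% 0) > 1) {
    stab <- stage("seed_stability", seed_stability(
      cluster_fm, config$kr, config$kc,
      n_seeds = config$stability$n_seeds, control = ctl))
    emit(data.frame(pair_ari = stab$pairwise_ari,
                    pair_nmi = stab$pairwise_nmi), "seed_stability.csv")
  }
  boot <- NULL
  if ((config$stability$bootstrap_B %||% 0) > 0) {
    boot <- stage("bootstrap_stability", bootstrap_stability(
      cluster_fm, config$kr, config$kc, B = config$stability$bootstrap_B,
      control = ctl, full = fit))
    emit(data.frame(boot_ari = boot$bootstrap_ari,
                    boot_nmi = boot$bootstrap_nmi), "bootstrap_stability.csv")
  }

  # stage: pathway scores and variants
  bins <- stage("bins", assign_pathway_bins(fm_std$descriptors,
                                            config$bin_spec))
  mpis <- stage("mpis", compute_mpis(fm_std, bins))
  emit(data.frame(subject_id = mpis$subject_ids, mpis$scores,
                  check.names = FALSE), "mpis_primary.csv")
  variants <- list()
  for (v in config$variants) {
    variants[[v]] <- stage(paste0("mpis_", v), {
      fm_in <- if (v == "icv_normalized") inputs$raw_fm else fm_std
      if (v == "icv_normalized" &&
          !"ICV" %in% colnames(inputs$raw_fm$values)) {
        warning("no ICV column; skipping icv_normalized variant")
        NULL
      } else compute_mpis(fm_in, bins, mpis_variant(v))
    })
  }
  variants <- Filter(Negate(is.null), variants)

  # stage: statistics
  stats_out <- stage("stats", {
    clin <- inputs$clinical
    assoc <- mpis_association_table(
      mpis, clin, B = config$stats$B, seed = derive_seed(config$seed, 3L))
    assoc_variants <- lapply(variants, function(v)
      mpis_association_table(v, clin, B = config$stats$B,
                             seed = derive_seed(config$seed, 3L)))
    conc <- mpis_variant_concordance(
      mpis, variants,
      assoc_results = c(list(primary = assoc), assoc_variants),
      q_level = config$stats$q_level)
    labels <- fit$assignments$row_labels
    kw <- do.call(rbind, lapply(colnames(mpis$scores), function(p) {
      if (all(!is.finite(mpis$scores[, p]))) return(NULL)
      r <- kruskal_eta2(mpis$scores[, p], labels)
      data.frame(pathway = p, H = r$H, k = r$k, n = r$n, eta2 = r$eta2,
                 p = r$p, stringsAsFactors = FALSE)
    }))
    kw$q <- bh_fdr(kw$p)
    comp <- summarize_clusters(clin, labels)
    contrast <- NULL
    tab_lab <- sort(unique(labels))
    if (length(tab_lab) >= 2) {
      a_lab <- tab_lab[1]; b_lab <- tab_lab[min(4, length(tab_lab))]
      contrast <- do.call(rbind, lapply(colnames(mpis$scores), function(p) {
        x <- mpis$scores[labels == a_lab, p]
        y <- mpis$scores[labels == b_lab, p]
        if (length(x) == 0 || length(y) == 0 || all(!is.finite(x))) return(NULL)
        cd <- cliffs_delta(x, y, B = config$stats$B,
                           seed = derive_seed(config$seed, 4L))
        data.frame(pathway = p, cluster_a = a_lab, cluster_b = b_lab,
                   delta = cd$delta, ci_low = cd$ci_low,
                   ci_high = cd$ci_high, stringsAsFactors = FALSE)
      }))
    }
    diag_tab <- table(labels, clin$diagnosis)
    cat_test <- cluster_category_test(diag_tab)
    regr <- do.call(rbind, lapply(colnames(mpis$scores), function(p) {
      if (all(!is.finite(mpis$scores[, p]))) return(NULL)
      df <- cbind(clin, mpis_score = mpis$scores[, p])
      r <- adjusted_regression(df, "updrs3", "mpis_score",
                               c("age", "sex", "education",
                                 "medication_status"))
      data.frame(pathway = p, outcome = "UPDRS3",
                 beta = r$coefficients$estimate[1],
                 ci_low = r$coefficients$ci_low[1],
                 ci_high = r$coefficients$ci_high[1],
                 p = r$coefficients$p[1], n = r$n,
                 stringsAsFactors = FALSE)
    }))
    regr$q <- bh_fdr(regr$p)
    list(assoc = assoc, kw = kw, composition = comp, contrast = contrast,
         category = cat_test, regressions = regr, concordance = conc)
  })
  emit(stats_out$assoc, "mpis_associations.csv")
  emit(stats_out$kw, "mpis_kruskal.csv")
  emit(stats_out$composition, "cluster_composition.csv")
  if (!is.null(stats_out$contrast)) emit(stats_out$contrast,
                                         "cluster_contrast.csv")
  emit(stats_out$regressions, "mpis_regressions.csv")
  emit(stats_out$concordance$correlations, "variant_concordance.csv")

  # stage: pathway-anchored concordance with the global partition
  conc_perm <- stage("concordance", {
    labels <- fit$assignments$row_labels
    out <- list()
    for (p in names(bins)) {
      members <- unlist(bins[[p]]$members)
      cols <- which(cluster_fm$descriptors$name %in% members)
      if (length(cols) < max(3, config$kc)) next
      sub_fm <- new_feature_matrix(
        cluster_fm$values[, cols, drop = FALSE], cluster_fm$subject_ids,
        cluster_fm$descriptors[cols, , drop = FALSE],
        standardized = cluster_fm$standardized)
      ctl_p <- ctl
      ctl_p$seed <- derive_seed(config$seed, 100L + match(p, names(bins)))
      sub_fit <- train_srvcc(sub_fm, config$kr,
                             min(config$kc, length(cols)), ctl_p)
      cp <- concordance_permutation(
        sub_fit$assignments$row_labels, labels,
        n_perm = config$stats$n_perm,
        seed = derive_seed(config$seed, 200L + match(p, names(bins))))
      out[[p]] <- data.frame(pathway = p, nmi = cp$nmi, ari = cp$ari,
                             p_nmi = cp$p_nmi, p_ari = cp$p_ari,
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  if (!is.null(conc_perm)) emit(conc_perm, "pathway_concordance.csv")

  # manifest: hash every artifact in the output directory
  files <- list.files(config$out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest$files <- lapply(files, function(f)
    list(file = basename(f), md5 = unname(tools::md5sum(f))))
  manifest$selected <- c(kr = config$kr, kc = config$kc)
  manifest$diagnosis_association <- stats_out$category
  manifest$final_loss <- fit$final_loss
  manifest$val_recon <- fit$val_recon
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(manifest)
}

#' Cross-view robustness of the subject partition
#'
#' Reruns the clustering stage on each requested feature view and reports
#' pairwise agreement (ARI/NMI) of the hard subject labelings across
#' views.  Views left without at least 2 features after the clinical
#' strip are skipped with a warning.
#'
#' @param fm_std a standardized `feature_matrix` with view tags.
#' @param views views to compare.
#' @param kr,kc cluster counts.
#' @param control a [srvcc_control()].
#' @param allow_clinical keep clinical columns (the literal V1 ablation).
#' @return list with `labelings` per view and a data.frame `agreement` of
#'   pairwise ARI/NMI.
#' @export
ablation_views <- function(fm_std, views = c("V2", "V3", "V4"), kr = 5,
                           kc = 5, control = srvcc_control(),
                           allow_clinical = FALSE) {
  labelings <- list()
  for (v in views) {
    fm_v <- select_view(fm_std, v)
    if (!allow_clinical) fm_v <- strip_clinical(fm_v)
    if (ncol(fm_v$values) < 2) {
      warning("view ", v, " has fewer than 2 features after the clinical ",
              "strip; skipped (set allow_clinical for the literal ablation)",
              call. = FALSE)
      next
    }
    fit <- train_srvcc(fm_v, kr, min(kc, ncol(fm_v$values)), control)
    labelings[[v]] <- fit$assignments$row_labels
  }
  vs <- names(labelings)
  agreement <- NULL
  if (length(vs) >= 2) {
    pairs <- utils::combn(vs, 2)
    agreement <- data.frame(
      view_a = pairs[1, ], view_b = pairs[2, ],
      ari = apply(pairs, 2L, function(p)
        ari(labelings[[p[1]]], labelings[[p[2]]])),
      nmi = apply(pairs, 2L, function(p)
        nmi(labelings[[p[1]]], labelings[[p[2]]])),
      stringsAsFactors = FALSE)
  }
  list(labelings = labelings, agreement = agreement)
}
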