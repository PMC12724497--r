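#' Synthetic multimodal cohorts with planted structure
#'
#' Real multimodal PD cohorts of this kind are held under data-use
#' agreements and cannot ship with the package, so every downstream stage
#' is exercised on synthetic cohorts with known truth.  The generative
#' model is deliberately minimal but jointly plantable and separately
#' switchable:
#'
#' * block structure: subject clusters x feature blocks shift the feature
#'   means (`x_ij = M[r_i, c_j] + ...`), giving the co-clustering model a
#'   recoverable checkerboard;
#' * pathway latents: each pathway p has a subject-level integrity factor
#'   `u_i(p)` (unit variance) loading on that pathway's features with
#'   modality sign `s(MD) = -1`, `s(FA) = s(VOL) = s(SBR) = +1`, so higher
#'   latent integrity lowers diffusivity;
#' * clinical links: outcome scores are drawn jointly Gaussian with the
#'   latents at the Pearson correlation that induces a requested Spearman
#'   correlation (the Gaussian-copula identity `rho_P = 2 sin(pi rho_S / 6)`),
#'   then pushed through a strictly monotone marginal transform
#'   (location/scale, integer rounding, range clipping), which preserves
#'   the planted rank correlation up to tie-induced attenuation.
#'
#' @name synthetic_cohort
NULL

OUTCOME_COLUMNS <- c(UPDRS3 = "updrs3", MoCA = "moca", QUIP_SUM = "quip_sum")
CLIN_FEATURE_FOR_OUTCOME <- c(UPDRS3 = "NP3TOT", MoCA = "MCATOT",
                              QUIP_SUM = "QUIP_SUM")

#' Bivariate-normal Pearson correlation inducing a target Spearman
#'
#' For a bivariate Gaussian copula, the population Spearman correlation
#' `rho_S` and Pearson correlation `rho_P` are linked by
#' `rho_S = (6 / pi) asin(rho_P / 2)`; this returns the inverse map
#' `rho_P = 2 sin(pi rho_S / 6)` used to plant rank effects.
#'
#' @param rho_s target Spearman correlation, strictly inside (-1, 1).
#' @export
copula_pearson_from_spearman <- function(rho_s) {
  if (any(!is.finite(rho_s)) || any(abs(rho_s) >= 1))
    stop("|rho_s| must be < 1")
  2 * sin(pi * rho_s / 6)
}

default_clinical_marginals <- function() {
  list(
    UPDRS3 = list(mean = 21.7, sd = 9.6, min = 0, max = 132, integer = TRUE),
    MoCA = list(mean = 27.3, sd = 2.1, min = 0, max = 30, integer = TRUE),
    QUIP_SUM = list(mean = 4.5, sd = 1.7, min = 0, max = 28, integer = TRUE)
  )
}

default_pathway_effects <- function() {
  list(
    nigrostriatal = c(UPDRS3 = -0.201, MoCA = 0.019, QUIP_SUM = 0.037),
    frontostriatal = c(UPDRS3 = -0.191, MoCA = 0.080, QUIP_SUM = 0.059),
    sensory = c(UPDRS3 = -0.097, MoCA = 0.163, QUIP_SUM = 0.096),
    limbic = c(UPDRS3 = -0.108, MoCA = 0.119, QUIP_SUM = 0.062),
    microvascular = c(UPDRS3 = -0.043, MoCA = -0.036, QUIP_SUM = 0.017)
  )
}

# Default checkerboard of mean shifts: amplitude `shift`, deterministic
# pattern with distinct rows.
default_shift_matrix <- function(k, n_blocks, shift) {
  outer(seq_len(k), seq_len(n_blocks), function(r, c) shift * sin(r * c))
}

#' Synthetic cohort configuration
#'
#' @param n_per_group named counts for the PD, HC and SWEDD groups.
#' @param schema descriptor data.frame (default [canonical_schema()]).
#' @param bin_spec pathway bin specification used for latent loading.
#' @param row_clusters list: `k` clusters, mixing `prop`, and either an
#'   explicit `k x n_blocks` mean-shift matrix `M` or a scalar `shift`
#'   amplitude for the default pattern.
#' @param col_block_map named integer vector modality -> feature-block id
#'   (defines the true column partition of imaging features).
#' @param pathway_effects list pathway -> named vector of target Spearman
#'   correlations per outcome (`UPDRS3`, `MoCA`, `QUIP_SUM`).
#' @param loadings per-modality loading of features on their pathway
#'   latent (`a_j`); default 1 for all modalities.
#' @param noise_sd residual feature noise standard deviation (> 0).
#' @param clinical_marginals per-outcome target mean/SD/range.
#' @param seed integer RNG seed (required; the generator is fully
#'   deterministic given the configuration).
#' @export
synthetic_config <- function(n_per_group = c(PD = 185, HC = 72, SWEDD = 37),
                             schema = canonical_schema(),
                             bin_spec = canonical_bin_spec(),
                             row_clusters = list(
                               k = 5,
                               prop = c(32, 28, 51, 44, 12) / 167,
                               shift = 2, M = NULL),
                             col_block_map = c(VOL = 1, FA = 2, MD = 2,
                                               SBR = 3),
                             pathway_effects = default_pathway_effects(),
                             loadings = c(VOL = 1, FA = 1, MD = 1, SBR = 1),
                             noise_sd = 1,
                             clinical_marginals = default_clinical_marginals(),
                             seed) {
  if (missing(seed)) stop("seed is required")
  n <- sum(n_per_group)
  stop_if_not(n >= 2, "total cohort size must be at least 2")
  stop_if_not(noise_sd > 0, "noise_sd must be > 0")
  stop_if_not(abs(sum(row_clusters$prop) - 1) < 1e-8,
              "mixing proportions must sum to 1")
  stop_if_not(length(row_clusters$prop) == row_clusters$k,
              "row_clusters$prop must have k entries")
  for (p in names(pathway_effects)) {
    if (!p %in% names(bin_spec))
      stop("pathway_effects references unknown pathway: ", p)
    if (any(abs(pathway_effects[[p]]) >= 1))
      stop("planted |rho| must be < 1 (pathway ", p, ")")
  }
  n_blocks <- length(unique(col_block_map))
  M <- row_clusters$M %||%
    default_shift_matrix(row_clusters$k, n_blocks,
                         row_clusters$shift %||% 2)
  stopifnot(nrow(M) == row_clusters$k, ncol(M) == n_blocks)
  structure(list(n_per_group = n_per_group, schema = schema,
                 bin_spec = bin_spec, row_clusters = row_clusters, M = M,
                 col_block_map = col_block_map,
                 pathway_effects = pathway_effects, loadings = loadings,
                 noise_sd = noise_sd,
                 clinical_marginals = clinical_marginals,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# First pathway (in bin-spec order) whose member pairs contain each
# feature; NA for features outside every bin.
primary_pathway <- function(schema, bin_spec) {
  prim <- rep(NA_character_, nrow(schema))
  for (p in rev(names(bin_spec))) {
    m <- bin_spec[[p]]$members
    key <- paste(m$roi, m$modality)
    hit <- paste(schema$roi, schema$modality) %in% key &
      schema$hemisphere %in% c("L", "R", "B")
    prim[hit] <- p
  }
  prim
}

apply_marginal <- function(g, marg) {
  y <- marg$mean + marg$sd * g
  if (isTRUE(marg$integer)) y <- round(y)
  pmin(pmax(y, marg$min), marg$max)
}

#' Generate a synthetic cohort
#'
#' @param config a [synthetic_config()].
#' @return list with `features` (data.frame in the feature-CSV dialect,
#'   including nuisance columns), `clinical` (data.frame of outcomes,
#'   covariates and diagnosis) and `truth` (row/column labels, pathway
#'   latents, planted effects).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  schema <- config$schema
  groups <- rep(names(config$n_per_group), times = config$n_per_group)
  n <- length(groups)
  ids <- sprintf("S%04d", seq_len(n))

  pathways <- names(config$bin_spec)
  prim <- primary_pathway(schema, config$bin_spec)
  for (p in names(config$pathway_effects)) {
    if (!any(prim == p, na.rm = TRUE))
      stop("no schema features in referenced pathway: ", p)
  }

  # pathway latents and jointly Gaussian outcome scores
  U <- matrix(stats::rnorm(n * length(pathways)), n, length(pathways),
              dimnames = list(ids, pathways))
  outcomes <- names(config$clinical_marginals)
  G <- matrix(0, n, length(outcomes), dimnames = list(ids, outcomes))
  for (o in outcomes) {
    b <- stats::setNames(numeric(length(pathways)), pathways)
    for (p in names(config$pathway_effects)) {
      rho <- config$pathway_effects[[p]]
      if (o %in% names(rho)) b[p] <- copula_pearson_from_spearman(rho[[o]])
    }
    ss <- sum(b^2)
    if (ss >= 1) stop("planted effects for ", o, " are jointly infeasible")
    G[, o] <- U %*% b + sqrt(1 - ss) * stats::rnorm(n)
  }
  # standardize latents to exact zero mean / unit sample variance (linear,
  # so planted correlations are untouched)
  U <- scale(U)
  attr(U, "scaled:center") <- attr(U, "scaled:scale") <- NULL

  # subject cluster labels and feature blocks
  r_lab <- sample(seq_len(config$row_clusters$k), n, replace = TRUE,
                  prob = config$row_clusters$prop)
  imaging <- !is.na(schema$modality) & schema$modality != "CLIN" &
    schema$hemisphere %in% c("L", "R", "B") & schema$roi != "icv"
  c_lab <- rep(NA_integer_, nrow(schema))
  c_lab[imaging] <- config$col_block_map[schema$modality[imaging]]

  baseline <- c(VOL = 20, FA = 10, MD = 10, SBR = 10)
  X <- matrix(NA_real_, n, nrow(schema),
              dimnames = list(ids, schema$name))
  im_idx <- which(imaging)
  mod_im <- schema$modality[im_idx]
  block_im <- c_lab[im_idx]
  prim_im <- prim[im_idx]
  noise <- matrix(stats::rnorm(n * length(im_idx), sd = config$noise_sd),
                  n, length(im_idx))
  latent_term <- matrix(0, n, length(im_idx))
  has_lat <- !is.na(prim_im)
  if (any(has_lat)) {
    s_mod <- ifelse(mod_im == "MD", -1, 1)
    a_mod <- config$loadings[mod_im]
    latent_term[, has_lat] <- U[, prim_im[has_lat], drop = FALSE] *
      rep(s_mod[has_lat] * a_mod[has_lat], each = n)
  }
  X[, im_idx] <- rep(baseline[mod_im], each = n) +
    config$M[r_lab, block_im, drop = FALSE] + latent_term + noise

  # clinical outcome scores (monotone marginal transforms of G)
  clin_scores <- lapply(outcomes, function(o)
    apply_marginal(G[, o], config$clinical_marginals[[o]]))
  names(clin_scores) <- outcomes

  # clinical-score feature columns mirror the clinical table
  for (o in outcomes) {
    feat <- CLIN_FEATURE_FOR_OUTCOME[[o]]
    if (feat %in% schema$name) X[, feat] <- clin_scores[[o]]
  }
  if ("NPTOT" %in% schema$name)
    X[, "NPTOT"] <- pmax(round(clin_scores[["UPDRS3"]] +
                                 stats::rnorm(n, 10, 4)), 0)
  if ("ICV" %in% schema$name)
    X[, "ICV"] <- stats::rnorm(n, 1.45e6, 5e4)

  # asymmetry summaries derived from their own L/R columns
  asym <- which(schema$hemisphere %in% "ASYM")
  for (j in asym) {
    rn <- paste(schema$roi[j], schema$modality[j], "R", sep = "_")
    ln <- paste(schema$roi[j], schema$modality[j], "L", sep = "_")
    if (rn %in% schema$name && ln %in% schema$name)
      X[, j] <- asymmetry_index(X[, rn], X[, ln])
  }
  # nuisance -std columns (acquisition dispersion; dropped at ingestion)
  std <- which(grepl("-std$", schema$name))
  if (length(std) > 0)
    X[, std] <- 1 + 0.05 * abs(stats::rnorm(n * length(std)))

  # covariates, independent of imaging by design
  tab1 <- list(
    PD = list(age = c(64.2, 9.1), female = 0.389, dur = c(1.9, 1.1),
              med_on = 0.524),
    HC = list(age = c(61.8, 8.7), female = 0.403, dur = NULL, med_on = 0),
    SWEDD = list(age = c(63.5, 8.9), female = 0.351, dur = c(1.8, 1.0),
                 med_on = 0.486))
  age <- sex <- education <- duration <- med <- numeric(n)
  for (g in names(tab1)) {
    idx <- which(groups == g)
    pars <- tab1[[g]]
    age[idx] <- stats::rnorm(length(idx), pars$age[1], pars$age[2])
    sex[idx] <- stats::rbinom(length(idx), 1, pars$female)
    duration[idx] <- if (is.null(pars$dur)) NA_real_ else
      pmax(stats::rnorm(length(idx), pars$dur[1], pars$dur[2]), 0.1)
    med[idx] <- stats::rbinom(length(idx), 1, pars$med_on)
  }
  education <- round(pmax(stats::rnorm(n, 15.2, 3.1), 6))
  field <- ifelse(stats::runif(n) < 0.85, "3T", "1.5T")

  clinical <- data.frame(
    subject_id = ids,
    updrs3 = clin_scores[["UPDRS3"]],
    moca = clin_scores[["MoCA"]],
    quip_sum = clin_scores[["QUIP_SUM"]],
    age = round(age, 1),
    sex = ifelse(sex == 1, "F", "M"),
    education = education,
    disease_duration = round(duration, 2),
    medication_status = ifelse(med == 1, "on", "off"),
    field_strength = field,
    diagnosis = groups,
    stringsAsFactors = FALSE)

  features <- data.frame(subject_id = ids, X, check.names = FALSE)
  truth <- list(row_labels = r_lab, col_labels = c_lab,
                pathway_latents = U,
                planted_effects = config$pathway_effects,
                primary_pathway = prim, seed = config$seed)
  list(features = features, clinical = clinical, truth = truth)
}

#' Write a generated cohort to disk
#'
#' Writes `features.csv` and `clinical.csv` in the dialect
#' [load_feature_table()] reads, plus `truth.json`.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if absent).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  truth <- cohort$truth
  truth$pathway_latents <- as.data.frame(truth$pathway_latents)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Check realized against planted rank effects
#'
#' For every planted pathway--outcome pair, the realized Spearman
#' correlation between the pathway latent and the generated outcome, with
#' a bootstrap confidence interval; pairs whose CI excludes the planted
#' target are flagged.
#'
#' @param features,clinical,truth outputs of [generate_cohort()].
#' @param B bootstrap resamples for the CI.
#' @param seed RNG seed for the bootstrap.
#' @export
verify_planting <- function(features, clinical, truth, B = 200, seed = 1) {
  if (nrow(features) != nrow(clinical))
    stop("feature and clinical tables have different subject counts")
  rows <- list()
  for (p in names(truth$planted_effects)) {
    rho <- truth$planted_effects[[p]]
    for (o in names(rho)) {
      u <- truth$pathway_latents[, p]
      y <- clinical[[OUTCOME_COLUMNS[[o]]]]
      res <- spearman_with_ci(u, y, B = B, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        pathway = p, outcome = o, target = rho[[o]], realized = res$rho,
        ci_low = res$ci_low, ci_high = res$ci_high,
        flagged = rho[[o]] < res$ci_low | rho[[o]] > res$ci_high,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Recovery of a single planted pathway--outcome rank effect
#'
#' Generates `n_seeds` cohorts that plant one Spearman effect between a
#' pathway latent and an outcome (no cluster mean shifts, near-zero
#' feature noise so the pathway score isolates its latent), runs the real
#' scoring pipeline (ingestion, z-scoring, binning, MPIS), and returns the
#' per-cohort Spearman correlation between the pathway MPIS and the
#' outcome.
#'
#' @param pathway pathway name (e.g. `"nigrostriatal"`).
#' @param outcome outcome name (`"UPDRS3"`, `"MoCA"` or `"QUIP_SUM"`).
#' @param rho_s target Spearman correlation to plant.
#' @param n cohort size.
#' @param n_seeds number of independent cohorts.
#' @param seed master seed (per-cohort seeds are derived from it).
#' @param noise_sd residual feature noise (near zero by default so the
#'   score-level attenuation is negligible).
#' @return data.frame with one row per cohort (`seed`, `rho`).
#' @export
planted_effect_recovery <- function(pathway, outcome, rho_s, n,
                                    n_seeds = 25, seed = 1,
                                    noise_sd = 0.05) {
  prop <- c(PD = 185, HC = 72, SWEDD = 37) / 294
  counts <- floor(prop * n)
  rem <- n - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
  effects <- list(stats::setNames(rho_s, outcome))
  names(effects) <- pathway
  out <- data.frame(seed = integer(n_seeds), rho = numeric(n_seeds))
  for (s in seq_len(n_seeds)) {
    cfg <- synthetic_config(
      n_per_group = counts,
      row_clusters = list(k = 1, prop = 1, shift = 0),
      pathway_effects = effects,
      noise_sd = noise_sd,
      seed = derive_seed(seed, s))
    cohort <- generate_cohort(cfg)
    loaded <- load_feature_table(cohort$features, cohort$clinical)
    fm <- zscore_columns(loaded$features)
    bins <- assign_pathway_bins(fm$descriptors, cfg$bin_spec)
    mpis <- compute_mpis(fm, bins)
    out$seed[s] <- cfg$seed
    out$rho[s] <- stats::cor(mpis$scores[, pathway],
                             loaded$clinical[[OUTCOME_COLUMNS[[outcome]]]],
                             method = "spearman")
  }
  out
}
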