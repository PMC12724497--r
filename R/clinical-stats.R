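#' Pathway-aware clinical statistics
#'
#' Post hoc statistics linking pathway integrity scores and cluster labels
#' to clinical outcomes: rank correlations with bootstrap confidence
#' intervals under Benjamini-Hochberg FDR control, Kruskal-Wallis tests
#' with a rank eta-squared effect size, Cliff's delta dominance effects,
#' categorical association with Cramer's V, covariate-adjusted linear
#' models with partial R-squared for cluster terms, and permutation-based
#' partition concordance.
#'
#' @name clinical_stats
NULL

#' Spearman correlation with bootstrap CI
#'
#' Spearman rho with average-rank ties; 95 percent percentile bootstrap
#' CI over subject resamples; two-sided p-value from the large-sample
#' normal approximation `z = rho sqrt(n - 1)`.
#'
#' @param x,y paired numeric vectors (incomplete pairs dropped).
#' @param B bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level.
#' @return list with `rho`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
spearman_with_ci <- function(x, y, B = 1000, seed = 1, conf = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (sample_sd(x) == 0 || sample_sd(y) == 0) {
    warning("constant input: Spearman correlation undefined", call. = FALSE)
    return(list(rho = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                p = NA_real_, n = n))
  }
  rho <- stats::cor(x, y, method = "spearman")
  set.seed(seed)
  boot <- vapply(seq_len(B), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    if (sample_sd(x[i]) == 0 || sample_sd(y[i]) == 0) return(NA_real_)
    stats::cor(x[i], y[i], method = "spearman")
  }, numeric(1))
  alpha <- 1 - conf
  ci <- stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                        names = FALSE)
  p <- 2 * stats::pnorm(-abs(rho) * sqrt(n - 1))
  list(rho = rho, ci_low = min(ci[1], rho), ci_high = max(ci[2], rho),
       p = p, n = n)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; the adjustment
#' family is all tests passed in one call (one analysis table).
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}

#' Rank eta-squared from a Kruskal-Wallis statistic
#'
#' `eta^2 = (H - k + 1) / (n - k)`, the rank-based effect size mapping the
#' tie-corrected Kruskal-Wallis H to the unit interval.
#'
#' @param H Kruskal-Wallis statistic.
#' @param n total observations.
#' @param k number of groups.
#' @export
eta2_from_h <- function(H, n, k) {
  stopifnot(n > k, k >= 2)
  (H - k + 1) / (n - k)
}

#' Kruskal-Wallis test with rank eta-squared
#'
#' @param values numeric outcome.
#' @param group_labels group membership (>= 2 nonempty groups).
#' @return list with `H`, `k`, `n`, `eta2`, `p`.
#' @export
kruskal_eta2 <- function(values, group_labels) {
  ok <- is.finite(values) & !is.na(group_labels)
  values <- values[ok]
  g <- factor(group_labels[ok])
  if (nlevels(g) < 2 || any(table(g) == 0)) stop("need >= 2 nonempty groups")
  kt <- stats::kruskal.test(values, g)
  H <- unname(kt$statistic)
  k <- nlevels(g)
  n <- length(values)
  list(H = H, k = k, n = n, eta2 = eta2_from_h(H, n, k),
       p = unname(kt$p.value))
}

#' Cliff's delta with bootstrap CI
#'
#' `delta = (#(a_i > b_j) - #(a_i < b_j)) / (|a| |b|)`, computed from
#' average ranks (exactly the pair-count definition, including ties);
#' percentile bootstrap CI resampling both groups.
#'
#' @param a,b numeric samples for the two groups.
#' @param B bootstrap resamples (0 skips the CI).
#' @param seed RNG seed.
#' @param conf confidence level.
#' @return list with `delta`, `ci_low`, `ci_high`.
#' @export
cliffs_delta <- function(a, b, B = 1000, seed = 1, conf = 0.95) {
  stopifnot(length(a) > 0, length(b) > 0)
  delta_stat <- function(a, b) {
    m <- length(a); n <- length(b)
    r <- rank(c(a, b))
    u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
    2 * u / (m * n) - 1
  }
  d <- delta_stat(a, b)
  ci <- c(NA_real_, NA_real_)
  if (B > 0) {
    set.seed(seed)
    boot <- vapply(seq_len(B), function(i)
      delta_stat(sample(a, replace = TRUE), sample(b, replace = TRUE)),
      numeric(1))
    alpha <- 1 - conf
    ci <- stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  }
  list(delta = d, ci_low = ci[1], ci_high = ci[2])
}

#' Cramer's V effect size for a contingency table
#'
#' `V = sqrt(chi^2 / (n (min(r, c) - 1)))` with Pearson chi-squared and no
#' continuity correction.
#'
#' @param contingency_table nonnegative integer matrix with positive
#'   margins.
#' @export
cramers_v <- function(contingency_table) {
  tab <- as.matrix(contingency_table)
  stopifnot(all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate margins in contingency table")
  chi2 <- suppressWarnings(
    stats::chisq.test(tab, correct = FALSE)$statistic)
  sqrt(unname(chi2) / (sum(tab) * (min(dim(tab)) - 1)))
}

#' Categorical association across clusters
#'
#' Pearson chi-squared test of independence, switching to Fisher's exact
#' test when any expected cell count falls below 5, reporting Cramer's V
#' alongside.
#'
#' @param contingency_table counts (e.g. cluster x diagnosis).
#' @export
cluster_category_test <- function(contingency_table) {
  tab <- as.matrix(contingency_table)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sparse <- any(expected < 5)
  test <- if (sparse) stats::fisher.test(tab, simulate.p.value = sum(tab) > 200,
                                         B = 2000)
  else stats::chisq.test(tab, correct = FALSE)
  list(method = if (sparse) "fisher" else "chisq", p = unname(test$p.value),
       cramers_v = cramers_v(tab))
}

#' Covariate-adjusted linear regression with a predictor block
#'
#' Ordinary least squares with intercept; categorical covariates enter as
#' treatment-coded factors.  For a multi-column predictor block (cluster
#' indicators), partial R-squared is
#' `(SSE_reduced - SSE_full) / SSE_reduced` and a global F-test compares
#' the nested models.
#'
#' @param data data.frame with outcome, predictors and covariates.
#' @param outcome outcome column name.
#' @param predictors character vector naming the predictor block.
#' @param covariates character vector of covariate names (may be empty).
#' @return list with `coefficients` (estimate, CI, p per predictor term),
#'   `partial_r2`, `global_f`, `global_p`, `n`, `covariates`.
#' @export
adjusted_regression <- function(data, outcome, predictors,
                                covariates = character()) {
  vars <- c(outcome, predictors, covariates)
  stopifnot(all(vars %in% names(data)))
  df <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars,
             drop = FALSE]
  for (v in c(predictors, covariates))
    if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  full_fml <- stats::reformulate(c(predictors, covariates),
                                 response = outcome)
  fit <- stats::lm(full_fml, data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "))
  }
  red_fml <- if (length(covariates) > 0)
    stats::reformulate(covariates, response = outcome)
  else stats::as.formula(paste(outcome, "~ 1"))
  red <- stats::lm(red_fml, data = df)
  sse_full <- sum(stats::residuals(fit)^2)
  sse_red <- sum(stats::residuals(red)^2)
  partial_r2 <- (sse_red - sse_full) / sse_red
  an <- stats::anova(red, fit)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  keep <- setdiff(rownames(sm), "(Intercept)")
  cov_terms <- unlist(lapply(covariates, function(v)
    grep(paste0("^", v), keep, value = TRUE)))
  pred_terms <- setdiff(keep, cov_terms)
  coefs <- data.frame(term = pred_terms,
                      estimate = sm[pred_terms, 1],
                      ci_low = ci[pred_terms, 1],
                      ci_high = ci[pred_terms, 2],
                      p = sm[pred_terms, 4],
                      row.names = NULL, stringsAsFactors = FALSE)
  list(coefficients = coefs, partial_r2 = partial_r2,
       global_f = an$F[2], global_p = an$`Pr(>F)`[2],
       n = nrow(df), covariates = covariates, r_squared = summary(fit)$r.squared)
}

#' Concordance of two partitions with permutation p-values
#'
#' Observed NMI and ARI between two labelings of the same subjects, with
#' null distributions from shuffling one labeling; p-values use the
#' add-one rule `p = (1 + #(perm >= obs)) / (1 + n_perm)` and so are never
#' exactly zero.
#'
#' @param pathway_labels,global_labels aligned label vectors.
#' @param n_perm number of permutations (>= 1000 for reporting).
#' @param seed RNG seed.
#' @export
concordance_permutation <- function(pathway_labels, global_labels,
                                    n_perm = 1000, seed = 1) {
  if (length(pathway_labels) != length(global_labels))
    stop("labelings have different lengths")
  obs_nmi <- nmi(pathway_labels, global_labels)
  obs_ari <- ari(pathway_labels, global_labels)
  set.seed(seed)
  ge_nmi <- ge_ari <- 0L
  for (i in seq_len(n_perm)) {
    perm <- sample(global_labels)
    if (nmi(pathway_labels, perm) >= obs_nmi) ge_nmi <- ge_nmi + 1L
    if (ari(pathway_labels, perm) >= obs_ari) ge_ari <- ge_ari + 1L
  }
  list(nmi = obs_nmi, ari = obs_ari,
       p_nmi = (1 + ge_nmi) / (1 + n_perm),
       p_ari = (1 + ge_ari) / (1 + n_perm))
}

#' Cluster composition summary
#'
#' Per-cluster subject counts, diagnosis counts, percentages for
#' categorical covariates and mean +/- SD for continuous variables.
#'
#' @param clinical clinical data.frame (see [generate_cohort()]).
#' @param labels cluster labels aligned to `clinical` rows.
#' @export
summarize_clusters <- function(clinical, labels) {
  stopifnot(nrow(clinical) == length(labels))
  msd <- function(x) sprintf("%.1f ± %.1f", mean(x, na.rm = TRUE),
                             stats::sd(x, na.rm = TRUE))
  pct <- function(x, lev) 100 * mean(x == lev, na.rm = TRUE)
  rows <- lapply(sort(unique(labels)), function(cl) {
    d <- clinical[labels == cl, , drop = FALSE]
    data.frame(
      cluster = cl, n = nrow(d),
      n_pd = sum(d$diagnosis == "PD"), n_hc = sum(d$diagnosis == "HC"),
      n_swedd = sum(d$diagnosis == "SWEDD"),
      age = msd(d$age), female_pct = round(pct(d$sex, "F"), 1),
      on_medication_pct = round(pct(d$medication_status, "on"), 1),
      field_3t_pct = round(pct(d$field_strength, "3T"), 1),
      updrs3 = msd(d$updrs3), moca = msd(d$moca), quip_sum = msd(d$quip_sum),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pathway-outcome association table
#'
#' Spearman correlations between each pathway score and each clinical
#' outcome, with bootstrap CIs and BH q-values adjusted across the whole
#' pathway-by-outcome family (one analysis table).
#'
#' @param mpis an `mpis_table`.
#' @param clinical aligned clinical data.frame.
#' @param outcomes outcome names (subset of `UPDRS3`, `MoCA`, `QUIP_SUM`).
#' @param B bootstrap resamples per cell.
#' @param seed RNG seed.
#' @export
mpis_association_table <- function(mpis, clinical,
                                   outcomes = names(OUTCOME_COLUMNS),
                                   B = 1000, seed = 1) {
  stopifnot(inherits(mpis, "mpis_table"),
            nrow(clinical) == nrow(mpis$scores))
  rows <- list()
  for (p in colnames(mpis$scores)) {
    for (o in outcomes) {
      y <- clinical[[OUTCOME_COLUMNS[[o]]]]
      x <- mpis$scores[, p]
      if (all(!is.finite(x))) next
      res <- spearman_with_ci(x, y, B = B,
                              seed = derive_seed(seed, length(rows)))
      rows[[length(rows) + 1L]] <- data.frame(
        pathway = p, outcome = o, n = res$n, rho = res$rho,
        ci_low = res$ci_low, ci_high = res$ci_high, p = res$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out
}
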