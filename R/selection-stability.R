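#' Model selection and cluster stability
#'
#' Candidate cluster counts are scanned over a grid, each cell trained
#' from several random initializations; the working configuration is the
#' most parsimonious cell whose held-out reconstruction error is within a
#' small factor of the grid minimum (a reproducible formalization of the
#' "diminishing returns" elbow).  Stability of the selected solution is
#' quantified by pairwise ARI/NMI across seed retrains and by a
#' nonparametric subject bootstrap against the full-sample solution.
#'
#' @name selection_stability
NULL

#' Adjusted Rand index
#'
#' Permutation-model adjusted Rand index computed from the contingency
#' table of two labelings; 1 for identical partitions, expectation 0 under
#' random label permutation, and invariant to relabeling of cluster ids.
#'
#' @param labels_a,labels_b equal-length label vectors (length >= 2).
#' @export
ari <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("labelings have different lengths")
  stopifnot(length(labels_a) >= 2)
  tab <- table(labels_a, labels_b)
  n <- length(labels_a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_cells <- sum(ch2(tab))
  sum_rows <- sum(ch2(rowSums(tab)))
  sum_cols <- sum(ch2(colSums(tab)))
  expected <- sum_rows * sum_cols / ch2(n)
  max_index <- (sum_rows + sum_cols) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_cells - expected) / (max_index - expected)
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized mutual information
#'
#' Mutual information of the empirical joint label distribution normalized
#' by the arithmetic mean of the two label entropies.  Conventions for
#' degenerate partitions: both constant gives 1, exactly one constant
#' gives 0.
#'
#' @inheritParams ari
#' @export
nmi <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("labelings have different lengths")
  tab <- table(labels_a, labels_b) / length(labels_a)
  ha <- entropy_nats(rowSums(tab))
  hb <- entropy_nats(colSums(tab))
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  mi <- mutual_information(as.matrix(tab))
  mi / ((ha + hb) / 2)
}

#' Scan cluster-count candidates and select a working configuration
#'
#' @param fm feature matrix handed to [train_srvcc()].
#' @param kr_grid,kc_grid candidate row/column cluster counts.
#' @param seeds_per_cell random initializations per cell.
#' @param control base [srvcc_control()]; per-run seeds are derived from
#'   `control$seed`.
#' @param tol_frac parsimony tolerance: the selected cell is the smallest
#'   (ordered by `kr + kc`, then `kr`) whose median validation
#'   reconstruction error is within `tol_frac` of the grid minimum.  The
#'   default 0.10 separates the steep regime (under-clustered cells sit
#'   30 percent or more above the minimum) from the plateau (splitting a
#'   true cluster buys only a few percent).
#' @return list with `records` (one row per run: kr, kc, seed,
#'   final_loss, val_recon, mi_ratio), `cells` (per-cell medians) and
#'   `selected` (named vector kr, kc).
#' @export
model_selection_grid <- function(fm, kr_grid = 3:7, kc_grid = 3:7,
                                 seeds_per_cell = 5,
                                 control = srvcc_control(),
                                 tol_frac = 0.10) {
  records <- list()
  for (kr in kr_grid) for (kc in kc_grid) {
    for (s in seq_len(seeds_per_cell)) {
      ctl <- control
      ctl$seed <- derive_seed(control$seed, kr * 1000L + kc * 100L + s)
      fit <- tryCatch(train_srvcc(fm, kr, kc, ctl),
                      error = function(e) e)
      records[[length(records) + 1L]] <- if (inherits(fit, "error")) {
        data.frame(kr = kr, kc = kc, seed = ctl$seed,
                   final_loss = NA_real_, val_recon = NA_real_,
                   mi_ratio = NA_real_, failed = TRUE)
      } else {
        data.frame(kr = kr, kc = kc, seed = ctl$seed,
                   final_loss = fit$final_loss, val_recon = fit$val_recon,
                   mi_ratio = if (fit$mi_red > 1e-12)
                     fit$mi_org / fit$mi_red else NA_real_,
                   failed = FALSE)
      }
    }
  }
  records <- do.call(rbind, records)
  ok <- records[!records$failed, , drop = FALSE]
  if (nrow(ok) == 0) stop("every grid cell failed to train")
  cells <- stats::aggregate(
    ok[, c("final_loss", "val_recon", "mi_ratio")],
    by = list(kr = ok$kr, kc = ok$kc), FUN = stats::median)
  best <- min(cells$val_recon)
  cells <- cells[order(cells$kr + cells$kc, cells$kr), , drop = FALSE]
  sel <- cells[cells$val_recon <= best * (1 + tol_frac), , drop = FALSE][1, ]
  list(records = records, cells = cells,
       selected = c(kr = sel$kr, kc = sel$kc))
}

summary_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  c(median = q[2], iqr_low = q[1], iqr_high = q[3])
}

#' Stability across random seeds
#'
#' Retrains the model `n_seeds` times and reports all pairwise ARI/NMI
#' values between the hard subject-cluster labelings.
#'
#' @inheritParams model_selection_grid
#' @param kr,kc cluster counts of the configuration under study.
#' @param n_seeds number of retrains.
#' @return list with the pairwise `ari`/`nmi` distributions and their
#'   median/IQR summaries.
#' @export
seed_stability <- function(fm, kr, kc, n_seeds = 10,
                           control = srvcc_control()) {
  labelings <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    ctl <- control
    ctl$seed <- derive_seed(control$seed, 5000L + s)
    labelings[[s]] <- train_srvcc(fm, kr, kc, ctl)$assignments$row_labels
  }
  pairs <- utils::combn(n_seeds, 2)
  aris <- apply(pairs, 2L, function(p)
    ari(labelings[[p[1]]], labelings[[p[2]]]))
  nmis <- apply(pairs, 2L, function(p)
    nmi(labelings[[p[1]]], labelings[[p[2]]]))
  list(pairwise_ari = aris, pairwise_nmi = nmis,
       ari_summary = summary_iqr(aris), nmi_summary = summary_iqr(nmis),
       labelings = labelings)
}

#' Stability under a subject bootstrap
#'
#' Draws `B` resamples of `frac * N` subjects with replacement, refits the
#' model on each, and compares the resampled solution to the full-sample
#' solution on the unique subjects present (first occurrence per
#' duplicated subject).  Resamples collapsing to fewer than `kr` unique
#' subjects are skipped with a warning.
#'
#' @inheritParams seed_stability
#' @param B number of bootstrap resamples.
#' @param frac resample size as a fraction of the cohort.
#' @param full optional precomputed full-sample fit from [train_srvcc()].
#' @export
bootstrap_stability <- function(fm, kr, kc, B = 100, frac = 0.8,
                                control = srvcc_control(), full = NULL) {
  full <- full %||% train_srvcc(fm, kr, kc, control)
  full_labels <- full$assignments$row_labels
  X <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  N <- nrow(X)
  aris <- nmis <- numeric(0)
  skipped <- 0L
  set.seed(derive_seed(control$seed, 9000L))
  draws <- matrix(sample.int(N, B * round(frac * N), replace = TRUE),
                  nrow = B)
  for (b in seq_len(B)) {
    idx <- draws[b, ]
    uniq <- !duplicated(idx)
    if (sum(uniq) < kr) {
      skipped <- skipped + 1L
      warning("bootstrap resample ", b, " has fewer than kr unique subjects",
              call. = FALSE)
      next
    }
    ctl <- control
    ctl$seed <- derive_seed(control$seed, 9000L + b)
    fit <- train_srvcc(X[idx, , drop = FALSE], kr, kc, ctl)
    lab <- fit$assignments$row_labels[uniq]
    ref <- full_labels[idx[uniq]]
    aris <- c(aris, ari(lab, ref))
    nmis <- c(nmis, nmi(lab, ref))
  }
  list(bootstrap_ari = aris, bootstrap_nmi = nmis,
       ari_summary = summary_iqr(aris), nmi_summary = summary_iqr(nmis),
       skipped = skipped)
}
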