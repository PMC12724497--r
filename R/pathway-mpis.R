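#' Multimodal Pathway Integrity Scores (MPIS)
#'
#' For a pathway p with per-modality member sets, the score for subject i is
#' the standardized signed, weighted sum of the z-scored member features:
#'
#'   MPIS_i(p) = Z( sum_FA w_FA z_ij + sum_VOL w_VOL z_ij
#'                  + sum_SBR w_SBR z_ij - sum_MD w_MD z_ij )
#'
#' Mean diffusivity enters with a negative sign so that higher MPIS always
#' reads as greater inferred circuit integrity; the operator Z standardizes
#' the composite across subjects (sample SD), so each pathway column has
#' exactly zero mean and unit variance and the composite is invariant to a
#' common rescaling of the bin weights.
#'
#' @name pathway_mpis
NULL

#' Assign features to pathway bins
#'
#' Matches each feature descriptor against the bin specification's
#' ROI--modality member pairs.  A feature may belong to several pathways
#' (shared striatal and thalamic regions do); asymmetry-index features are
#' excluded by default because their sign under a "higher = more intact"
#' convention is undefined.
#'
#' @param descriptors descriptor data.frame (see [parse_descriptors()]).
#' @param bin_spec bin specification, e.g. [canonical_bin_spec()].
#' @param include_asym include `ASYM` hemisphere features in membership.
#' @return object of class `pathway_bins`: named list of bins, each with
#'   `name`, `members` (modality -> feature-name sets), `signs`, `weights`;
#'   attribute `counts` holds the per-bin feature totals.
#' @export
assign_pathway_bins <- function(descriptors, bin_spec = canonical_bin_spec(),
                                include_asym = FALSE) {
  hemis <- c("L", "R", "B", if (include_asym) "ASYM")
  bins <- lapply(names(bin_spec), function(p) {
    b <- bin_spec[[p]]
    members <- list()
    for (mod in intersect(unique(b$members$modality), MODALITIES)) {
      rois <- b$members$roi[b$members$modality == mod]
      missing <- setdiff(rois, descriptors$roi)
      if (length(missing) > 0)
        warning(sprintf("pathway %s: ROI(s) %s absent from descriptors", p,
                        paste(missing, collapse = ", ")), call. = FALSE)
      keep <- descriptors$roi %in% rois & descriptors$modality == mod &
        descriptors$hemisphere %in% hemis & descriptors$roi != "icv"
      members[[mod]] <- descriptors$name[keep]
    }
    list(name = p, members = members,
         signs = b$signs, weights = b$weights)
  })
  names(bins) <- names(bin_spec)
  counts <- vapply(bins, function(b) sum(lengths(b$members)), integer(1))
  structure(bins, counts = counts, class = "pathway_bins")
}

#' @export
print.pathway_bins <- function(x, ...) {
  cat("<pathway_bins>\n")
  cnt <- attr(x, "counts")
  for (p in names(x)) cat(sprintf("  %-15s |F_p| = %d\n", p, cnt[[p]]))
  invisible(x)
}

#' MPIS variant specification
#'
#' @param variant one of `"primary"` (equal weights, signed MD),
#'   `"icv_normalized"` (volumes divided by head size before z-scoring),
#'   `"pathway_weighted"` (per-pathway modality reweighting) or
#'   `"nonsigned_md"` (MD enters with positive sign, a control variant).
#' @param icv_column feature name holding intracranial volume (required
#'   for `icv_normalized`).
#' @param weight_overrides named list pathway -> named weight vector; the
#'   default for `pathway_weighted` upweights SBR in the nigrostriatal bin
#'   (w = 2) and downweights volumes in the microvascular bin (w = 0.5).
#' @export
mpis_variant <- function(variant = c("primary", "icv_normalized",
                                     "pathway_weighted", "nonsigned_md"),
                         icv_column = "ICV", weight_overrides = NULL) {
  variant <- match.arg(variant)
  if (variant == "pathway_weighted" && is.null(weight_overrides))
    weight_overrides <- list(nigrostriatal = c(SBR = 2),
                             microvascular = c(VOL = 0.5))
  structure(list(variant = variant, icv_column = icv_column,
                 weight_overrides = weight_overrides),
            class = "mpis_variant")
}

#' Compute pathway integrity scores
#'
#' @param fm a standardized `feature_matrix` (for the `icv_normalized`
#'   variant, a raw one containing the ICV column; volumes are divided by
#'   ICV per subject and the matrix standardized internally).
#' @param bins a `pathway_bins` object.
#' @param variant an [mpis_variant()].
#' @return object of class `mpis_table` with `subject_ids`, `scores`
#'   (subjects x pathways matrix) and `variant`.
#' @export
compute_mpis <- function(fm, bins, variant = mpis_variant("primary")) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(bins, "pathway_bins"),
            inherits(variant, "mpis_variant"))
  if (variant$variant == "icv_normalized") {
    if (fm$standardized)
      stop("icv_normalized requires the raw feature matrix (ICV scaling precedes z-scoring)")
    if (!variant$icv_column %in% colnames(fm$values))
      stop("ICV column not found: ", variant$icv_column)
    icv <- fm$values[, variant$icv_column]
    vol <- fm$descriptors$modality == "VOL" &
      fm$descriptors$name != variant$icv_column
    x <- fm$values
    x[, vol] <- x[, vol, drop = FALSE] / icv
    fm <- zscore_columns(new_feature_matrix(x, fm$subject_ids,
                                            fm$descriptors, qc = fm$qc_ledger))
  } else if (!fm$standardized) {
    stop("feature matrix must be standardized (see zscore_columns)")
  }
  x <- fm$values
  scores <- matrix(NA_real_, nrow(x), length(bins),
                   dimnames = list(fm$subject_ids, names(bins)))
  for (p in names(bins)) {
    b <- bins[[p]]
    w <- b$weights
    if (!is.null(variant$weight_overrides[[p]])) {
      ov <- variant$weight_overrides[[p]]
      w[names(ov)] <- ov
    }
    signs <- b$signs
    if (variant$variant == "nonsigned_md") signs["MD"] <- 1
    composite <- numeric(nrow(x))
    total <- 0L
    for (mod in names(b$members)) {
      cols <- intersect(b$members[[mod]], colnames(x))
      total <- total + length(cols)
      if (length(cols) == 0) next
      composite <- composite +
        signs[[mod]] * w[[mod]] * rowSums(x[, cols, drop = FALSE])
    }
    if (total == 0L) {
      warning("pathway ", p, " has no member features; column set to NA",
              call. = FALSE)
      next
    }
    s <- sample_sd(composite)
    if (s < .Machine$double.eps^0.5) {
      warning("pathway ", p, " composite has zero variance", call. = FALSE)
      next
    }
    scores[, p] <- (composite - mean(composite)) / s
  }
  structure(list(subject_ids = fm$subject_ids, scores = scores,
                 variant = variant),
            class = "mpis_table")
}

#' @export
print.mpis_table <- function(x, ...) {
  cat(sprintf("<mpis_table> %d subjects x %d pathways (variant: %s)\n",
              nrow(x$scores), ncol(x$scores), x$variant$variant))
  invisible(x)
}

#' Concordance between the primary MPIS and its variants
#'
#' Per pathway, Pearson and Spearman correlation between the primary score
#' and each variant; optionally, agreement in the sign and FDR-level
#' significance of pathway-outcome associations computed under each
#' specification.
#'
#' @param primary the primary `mpis_table`.
#' @param others named list of variant `mpis_table`s.
#' @param assoc_results optional named list (primary plus variants) of
#'   association tables as returned by [mpis_association_table()].
#' @param q_level FDR significance level used for agreement (default 0.05).
#' @return list with `correlations` (data.frame: variant, pathway,
#'   pearson, spearman), `median_pearson` per variant, and (when
#'   association tables are given) `agreement` per variant x pathway x
#'   outcome.
#' @export
mpis_variant_concordance <- function(primary, others, assoc_results = NULL,
                                     q_level = 0.05) {
  stopifnot(inherits(primary, "mpis_table"))
  rows <- list()
  for (v in names(others)) {
    o <- others[[v]]
    if (!identical(o$subject_ids, primary$subject_ids))
      stop("variant ", v, ": subject ids do not align with the primary table")
    for (p in colnames(primary$scores)) {
      a <- primary$scores[, p]; b <- o$scores[, p]
      ok <- is.finite(a) & is.finite(b)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, pathway = p,
        pearson = if (sum(ok) > 2) stats::cor(a[ok], b[ok]) else NA_real_,
        spearman = if (sum(ok) > 2)
          stats::cor(a[ok], b[ok], method = "spearman") else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  correlations <- do.call(rbind, rows)
  med <- tapply(correlations$pearson, correlations$variant,
                stats::median, na.rm = TRUE)
  agreement <- NULL
  if (!is.null(assoc_results)) {
    base <- assoc_results[["primary"]]
    ag <- list()
    for (v in setdiff(names(assoc_results), "primary")) {
      other <- assoc_results[[v]]
      m <- merge(base, other, by = c("pathway", "outcome"),
                 suffixes = c("_primary", "_variant"))
      ag[[length(ag) + 1L]] <- data.frame(
        variant = v, pathway = m$pathway, outcome = m$outcome,
        sign_agree = sign(m$rho_primary) == sign(m$rho_variant),
        fdr_agree = (m$q_primary <= q_level) == (m$q_variant <= q_level),
        stringsAsFactors = FALSE)
    }
    agreement <- do.call(rbind, ag)
  }
  list(correlations = correlations, median_pearson = med,
       agreement = agreement)
}
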