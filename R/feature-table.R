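#' Feature tables: ingestion, quality control and standardization
#'
#' The subject-by-feature table is a wide CSV (one row per subject, one
#' column per ROI--modality--hemisphere measurement) following the naming
#' convention `<ROI>_<MOD>_<HEMI>` with `MOD` in `VOL`, `FA`, `MD`, `SBR`
#' and `HEMI` in `L`, `R`, `B`, `ASYM`.  Clinical score columns use the
#' reserved names `NP3TOT` (MDS-UPDRS III), `NPTOT` (MDS-UPDRS total),
#' `MCATOT` (MoCA) and `QUIP_SUM`; `ICV` is a reserved head-size column.
#' Columns whose name ends in `-std` are acquisition nuisance summaries and
#' are dropped at ingestion, as are non-numeric columns.
#'
#' @name feature_table
NULL

CLINICAL_FEATURES <- c("NP3TOT", "NPTOT", "MCATOT", "QUIP_SUM")
MODALITIES <- c("VOL", "FA", "MD", "SBR", "CLIN")
HEMISPHERES <- c("L", "R", "B", "ASYM")

#' Parse feature column names into descriptors
#'
#' @param names character vector of column names.
#' @return data.frame with columns `name`, `roi`, `modality`, `hemisphere`
#'   and a logical `parseable`; clinical reserved names map to modality
#'   `CLIN` (hemisphere `B`), `ICV` to modality `VOL`.
#' @export
parse_descriptors <- function(names) {
  pat <- "^(.*)_(VOL|FA|MD|SBR)_(L|R|B|ASYM)$"
  ok <- grepl(pat, names)
  roi <- ifelse(ok, sub(pat, "\\1", names), NA_character_)
  mod <- ifelse(ok, sub(pat, "\\2", names), NA_character_)
  hemi <- ifelse(ok, sub(pat, "\\3", names), NA_character_)
  clin <- names %in% CLINICAL_FEATURES
  roi[clin] <- names[clin]
  mod[clin] <- "CLIN"
  hemi[clin] <- "B"
  icv <- names == "ICV"
  roi[icv] <- "icv"
  mod[icv] <- "VOL"
  hemi[icv] <- "B"
  data.frame(
    name = names, roi = roi, modality = mod, hemisphere = hemi,
    parseable = ok | clin | icv, stringsAsFactors = FALSE
  )
}

new_feature_matrix <- function(values, subject_ids, descriptors,
                               standardized = FALSE, qc = NULL) {
  stopifnot(nrow(values) == length(subject_ids),
            ncol(values) == nrow(descriptors))
  rownames(values) <- subject_ids
  colnames(values) <- descriptors$name
  structure(
    list(values = values, subject_ids = subject_ids,
         descriptors = descriptors, standardized = standardized,
         qc_ledger = qc %||% empty_ledger()),
    class = "feature_matrix"
  )
}

empty_ledger <- function() {
  data.frame(kind = character(), id = character(), reason = character(),
             stringsAsFactors = FALSE)
}

ledger_add <- function(ledger, kind, id, reason) {
  if (length(id) == 0) return(ledger)
  rbind(ledger, data.frame(kind = kind, id = as.character(id),
                           reason = reason, stringsAsFactors = FALSE))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d subjects x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$standardized) "standardized" else "raw"))
  cat(sprintf("  QC ledger: %d entries\n", nrow(x$qc_ledger)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Load a feature table and clinical table with quality control
#'
#' Ingests the wide metrics table, dropping non-numeric columns, columns
#' ending in `-std`, and columns whose names do not parse under the naming
#' convention.  Rows containing `NA`/`NaN`/`Inf`, or in which every value of
#' some imaging modality is exactly zero (a failed modality), are removed.
#' Every dropped row and column is recorded in the QC ledger with a reason.
#'
#' @param features path to the feature CSV, or a data.frame in the same
#'   layout (a `subject_id` column plus feature columns).
#' @param clinical optional path to the clinical CSV, or a data.frame,
#'   keyed by `subject_id`.
#' @return list with elements `features` (a raw `feature_matrix`) and
#'   `clinical` (a data.frame aligned to the retained subjects, or `NULL`).
#' @export
load_feature_table <- function(features, clinical = NULL) {
  df <- if (is.character(features)) {
    utils::read.csv(features, check.names = FALSE, stringsAsFactors = FALSE)
  } else as.data.frame(features, check.names = FALSE)
  id_col <- intersect(c("subject_id", "id"), names(df))
  if (length(id_col) == 0) stop("no subject-id column in feature table")
  ids <- as.character(df[[id_col[1]]])
  df <- df[, setdiff(names(df), id_col), drop = FALSE]

  ledger <- empty_ledger()
  is_std <- grepl("-std$", names(df))
  ledger <- ledger_add(ledger, "column", names(df)[is_std], "std-suffix column")
  df <- df[, !is_std, drop = FALSE]
  numeric_ok <- vapply(df, is.numeric, logical(1))
  ledger <- ledger_add(ledger, "column", names(df)[!numeric_ok], "non-numeric column")
  df <- df[, numeric_ok, drop = FALSE]
  desc <- parse_descriptors(names(df))
  ledger <- ledger_add(ledger, "column", desc$name[!desc$parseable],
                       "unparseable column name")
  df <- df[, desc$parseable, drop = FALSE]
  desc <- desc[desc$parseable, , drop = FALSE]
  desc$parseable <- NULL
  rownames(desc) <- NULL
  if (ncol(df) == 0) stop("no feature columns survived quality control")

  x <- as.matrix(df)
  bad <- !apply(x, 1L, function(r) all(is.finite(r)))
  # failed-modality rule: a row is dropped if every value of some imaging
  # modality is exactly zero
  imaging <- setdiff(unique(desc$modality), "CLIN")
  zero_mod <- rep(FALSE, nrow(x))
  for (m in imaging) {
    cols <- which(desc$modality == m)
    if (length(cols) > 0) {
      allz <- rowSums(x[, cols, drop = FALSE] != 0, na.rm = TRUE) == 0
      zero_mod <- zero_mod | (allz & !bad)
    }
  }
  ledger <- ledger_add(ledger, "row", ids[bad], "non-finite values")
  ledger <- ledger_add(ledger, "row", ids[zero_mod & !bad], "all-zero modality")
  keep <- !(bad | zero_mod)
  if (!any(keep)) stop("no rows survived quality control")
  fm <- new_feature_matrix(x[keep, , drop = FALSE], ids[keep], desc, qc = ledger)

  clin <- NULL
  if (!is.null(clinical)) {
    clin <- if (is.character(clinical)) {
      utils::read.csv(clinical, stringsAsFactors = FALSE)
    } else as.data.frame(clinical)
    if (!"subject_id" %in% names(clin)) stop("clinical table lacks subject_id")
    clin$subject_id <- as.character(clin$subject_id)
    m <- match(fm$subject_ids, clin$subject_id)
    if (anyNA(m)) stop("clinical table is missing subjects present in the feature table")
    clin <- clin[m, , drop = FALSE]
    rownames(clin) <- NULL
  }
  list(features = fm, clinical = clin)
}

#' Standardize feature columns (global z-transform)
#'
#' Each column is centred on the cohort mean and scaled by the cohort
#' sample standard deviation (denominator n - 1).  Columns with zero
#' variance carry no information and are excluded and logged.
#'
#' @param fm a `feature_matrix`.
#' @return a standardized `feature_matrix`.
#' @export
zscore_columns <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (nrow(fm$values) < 2) stop("need at least 2 subjects to standardize")
  x <- fm$values
  sds <- apply(x, 2L, sample_sd)
  zero <- sds < .Machine$double.eps^0.5
  ledger <- ledger_add(fm$qc_ledger, "column",
                       fm$descriptors$name[zero], "zero variance")
  x <- x[, !zero, drop = FALSE]
  desc <- fm$descriptors[!zero, , drop = FALSE]
  x <- scale(x, center = TRUE, scale = apply(x, 2L, sample_sd))
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  new_feature_matrix(x, fm$subject_ids, desc, standardized = TRUE, qc = ledger)
}

#' Left--right asymmetry index
#'
#' `Asym = (R - L) / (R + L)`, in `[-1, 1]` for nonnegative same-unit
#' measurements.  A zero denominator yields `NA` (the row-level QC then
#' applies downstream).
#'
#' @param right,left numeric vectors of right/left hemisphere values.
#' @export
asymmetry_index <- function(right, left) {
  stopifnot(length(right) == length(left))
  denom <- right + left
  out <- (right - left) / denom
  out[denom == 0] <- NA_real_
  out
}

#' Select a nested feature view
#'
#' Views V1--V4 are nested supersets: V1 (clinical only) is contained in
#' V2 (plus macrostructure and dopamine), which is contained in both V3
#' (plus standard diffusion) and V4 (plus fluid-corrected diffusion, the
#' primary analysis view).
#'
#' @param fm a `feature_matrix` whose descriptors carry a `views` column
#'   (comma-separated tags).
#' @param view one of `"V1"`, `"V2"`, `"V3"`, `"V4"`.
#' @export
select_view <- function(fm, view) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!view %in% c("V1", "V2", "V3", "V4")) stop("unknown view tag: ", view)
  if (is.null(fm$descriptors$views)) stop("descriptors carry no view tags")
  tags <- strsplit(fm$descriptors$views, ",", fixed = TRUE)
  keep <- vapply(tags, function(t) view %in% t, logical(1))
  new_feature_matrix(fm$values[, keep, drop = FALSE], fm$subject_ids,
                     fm$descriptors[keep, , drop = FALSE],
                     standardized = fm$standardized, qc = fm$qc_ledger)
}

#' Attach view tags from a schema
#'
#' View membership is a property of the study design, not of the column
#' names, so matrices read back from CSV carry no view tags; this
#' re-attaches them from a schema table (e.g. [canonical_schema()]) by
#' feature name.  Features absent from the schema get an empty tag (full
#' matrix only).
#'
#' @param fm a `feature_matrix`.
#' @param schema descriptor data.frame with `name` and `views` columns.
#' @export
attach_views <- function(fm, schema) {
  stopifnot(inherits(fm, "feature_matrix"),
            all(c("name", "views") %in% names(schema)))
  v <- schema$views[match(fm$descriptors$name, schema$name)]
  v[is.na(v)] <- ""
  fm$descriptors$views <- v
  fm
}

#' Per-column then per-row normalization for model training
#'
#' Re-applies the column z-transform and then centres and scales each row
#' to unit sample standard deviation.  This is a training-time conditioning
#' step for the co-clustering model only; pathway scores are always
#' computed from the plain column-standardized matrix.  Constant rows are
#' centred but not scaled (logged).
#'
#' @param fm a standardized `feature_matrix`.
#' @export
row_col_normalize <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  x <- fm$values
  csd <- apply(x, 2L, sample_sd)
  csd[csd < .Machine$double.eps^0.5] <- 1
  x <- sweep(sweep(x, 2L, colMeans(x)), 2L, csd, "/")
  rm_ <- rowMeans(x)
  rsd <- apply(x, 1L, sample_sd)
  skipped <- rsd < .Machine$double.eps^0.5
  rsd[skipped] <- 1
  x <- sweep(sweep(x, 1L, rm_), 1L, rsd, "/")
  ledger <- ledger_add(fm$qc_ledger, "row",
                       fm$subject_ids[skipped], "constant row: scaling skipped")
  out <- new_feature_matrix(x, fm$subject_ids, fm$descriptors,
                            standardized = TRUE, qc = ledger)
  out
}

#' Write a feature matrix back to the CSV dialect it was read from
#' @param fm a `feature_matrix`.
#' @param path output CSV path.
#' @export
write_feature_table <- function(fm, path) {
  df <- data.frame(subject_id = fm$subject_ids, fm$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
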