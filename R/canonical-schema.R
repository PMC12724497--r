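#' Canonical feature schema and pathway bin specification
#'
#' The canonical schema describes the column layout of the metrics table
#' this package is designed around: ROI--modality--hemisphere features from
#' T1 volumetry (`VOL`), diffusion microstructure (`FA`, `MD`) and
#' dopamine-transporter SPECT binding (`SBR`), plus the four clinical score
#' columns, a head-size (`ICV`) column, asymmetry summaries and `-std`
#' acquisition nuisance columns.  Six anatomically predefined pathway bins
#' (nigrostriatal, frontostriatal, cerebello--thalamo--cortical, limbic,
#' microvascular, sensory/visuospatial) group these features for pathway
#' integrity scoring, with per-bin feature counts of 88, 128, 20, 80, 4 and
#' 112 respectively.
#'
#' @name canonical_schema_doc
NULL

PATHWAY_NAMES <- c("nigrostriatal", "frontostriatal", "ctc",
                   "limbic", "microvascular", "sensory")

.roi_sets <- function() {
  list(
    nigro_vfm = c("substantia_nigra", "putamen", "caudate", "pallidum",
                  "thalamus", "precentral", "premotor_cortex", "sma",
                  "subthalamic_nucleus", "red_nucleus", "internal_capsule",
                  "cerebral_peduncle"),
    nigro_sbr = c("putamen", "caudate", "pallidum", "accumbens",
                  "putamen_ant", "putamen_post", "caudate_head",
                  "caudate_body"),
    fronto_vfm = c("dlpfc", "rostral_middle_frontal", "caudal_middle_frontal",
                   "superior_frontal", "lateral_orbitofrontal",
                   "medial_orbitofrontal", "anterior_cingulate",
                   "caudal_anterior_cingulate", "insula", "frontal_pole",
                   "pars_opercularis", "pars_triangularis", "pars_orbitalis",
                   "caudate", "putamen", "thalamus", "anterior_corona_radiata",
                   "superior_frontal_wm", "cingulum", "frontal_wm"),
    fronto_sbr = c("caudate", "putamen", "accumbens", "pallidum"),
    ctc_vfm = c("cerebellar_cortex", "cerebellar_wm", "dentate"),
    limbic_vfm = c("hippocampus", "amygdala", "accumbens", "entorhinal",
                   "parahippocampal", "posterior_cingulate",
                   "isthmus_cingulate", "rostral_anterior_cingulate",
                   "fornix", "uncinate_fasciculus", "mammillary_body",
                   "septal_nuclei", "subgenual_cingulate"),
    sensory_vfm = c("lateral_occipital", "lingual", "cuneus", "pericalcarine",
                    "fusiform", "superior_parietal", "inferior_parietal",
                    "supramarginal", "precuneus", "postcentral",
                    "superior_temporal", "middle_temporal",
                    "inferior_temporal", "transverse_temporal", "bankssts",
                    "temporal_pole", "optic_radiation",
                    "posterior_corona_radiata")
  )
}

pairs_df <- function(roi, modality) {
  expand.grid(roi = roi, modality = modality, stringsAsFactors = FALSE,
              KEEP.OUT.ATTRS = FALSE)[, c("roi", "modality")]
}

#' Canonical pathway bin specification
#'
#' Each bin lists its ROI--modality member pairs, per-modality signs
#' (MD negative: higher diffusivity means degraded microstructure) and
#' per-modality weights (all 1 for the primary, equal-weights score).
#'
#' @return named list of bins, each with `members` (data.frame of `roi`,
#'   `modality`), `signs` and `weights` (named numeric vectors over
#'   modalities).
#' @export
canonical_bin_spec <- function() {
  r <- .roi_sets()
  default_signs <- c(VOL = 1, FA = 1, MD = -1, SBR = 1)
  default_weights <- c(VOL = 1, FA = 1, MD = 1, SBR = 1)
  bin <- function(members) {
    list(members = members, signs = default_signs, weights = default_weights)
  }
  list(
    nigrostriatal = bin(rbind(
      pairs_df(r$nigro_vfm, c("VOL", "FA", "MD")),
      pairs_df(r$nigro_sbr, "SBR"))),
    frontostriatal = bin(rbind(
      pairs_df(r$fronto_vfm, c("VOL", "FA", "MD")),
      pairs_df(r$fronto_sbr, "SBR"))),
    ctc = bin(rbind(
      pairs_df(r$ctc_vfm, c("VOL", "FA", "MD")),
      pairs_df("thalamus", "VOL"))),
    limbic = bin(rbind(
      pairs_df(r$limbic_vfm, c("VOL", "FA", "MD")),
      pairs_df("accumbens", "SBR"))),
    microvascular = bin(pairs_df("wm_hypointensities", c("VOL", "FA", "MD"))),
    sensory = bin(rbind(
      pairs_df(r$sensory_vfm, c("VOL", "FA", "MD")),
      pairs_df("occipital_pole", c("VOL", "FA"))))
  )
}

# Hemisphere layout: L/R for everything except the white-matter
# hypointensity diffusion summaries, which only exist as bilateral means.
.hemis_for <- function(roi, modality) {
  if (roi == "wm_hypointensities" && modality %in% c("FA", "MD")) "B"
  else c("L", "R")
}

#' Canonical feature schema
#'
#' Builds the descriptor table for the canonical metrics layout: all
#' ROI--modality--hemisphere features referenced by the canonical pathway
#' bins, plus a bilateral striatal SBR summary, a brainstem volume, the
#' reserved `ICV` column, the four clinical score columns, two asymmetry
#' summaries and (optionally) `-std` nuisance columns.  View tags follow
#' the nested ablation design: V1 clinical only (4), V2 adds 27 volumes and
#' 17 SBR summaries (48), V3 adds 64 standard-diffusion features (112) and
#' V4 adds 96 fluid-corrected diffusion features (144).
#'
#' @param include_std emit `-std` nuisance columns (dropped at ingestion).
#' @param include_asym emit asymmetry summary columns.
#' @return data.frame of descriptors: `name`, `roi`, `modality`,
#'   `hemisphere`, `views` (comma-separated tags, possibly empty).
#' @export
canonical_schema <- function(include_std = TRUE, include_asym = TRUE) {
  spec <- canonical_bin_spec()
  seen <- character()
  rows <- list()
  add <- function(roi, modality, hemisphere, views = "") {
    name <- if (modality == "CLIN") roi else
      paste(roi, modality, hemisphere, sep = "_")
    if (name %in% seen) return(invisible())
    seen <<- c(seen, name)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, roi = roi, modality = modality, hemisphere = hemisphere,
      views = views, stringsAsFactors = FALSE)
    invisible()
  }
  for (p in names(spec)) {
    m <- spec[[p]]$members
    for (i in seq_len(nrow(m))) {
      for (h in .hemis_for(m$roi[i], m$modality[i]))
        add(m$roi[i], m$modality[i], h)
    }
  }
  add("striatum", "SBR", "B")
  add("brainstem", "VOL", "B")
  for (cl in CLINICAL_FEATURES) add(cl, "CLIN", "B")
  if (include_asym) {
    add("putamen", "SBR", "ASYM")
    add("putamen", "FA", "ASYM")
  }
  desc <- do.call(rbind, rows)
  icv <- data.frame(name = "ICV", roi = "icv", modality = "VOL",
                    hemisphere = "B", views = "", stringsAsFactors = FALSE)
  desc <- rbind(desc, icv)

  # view tags
  v2_vol_rois <- c("putamen", "caudate", "pallidum", "accumbens", "thalamus",
                   "hippocampus", "amygdala", "substantia_nigra", "insula",
                   "precentral", "lateral_occipital", "dlpfc",
                   "cerebellar_cortex")
  tag <- function(idx, views) {
    desc$views[idx] <<- vapply(seq_along(idx), function(j)
      paste(views, collapse = ","), character(1))
    invisible()
  }
  clin_idx <- which(desc$modality == "CLIN")
  tag(clin_idx, c("V1", "V2", "V3", "V4"))
  vol_idx <- which(desc$modality == "VOL" & desc$hemisphere %in% c("L", "R") &
                     desc$roi %in% v2_vol_rois)
  vol_idx <- c(vol_idx, which(desc$name == "brainstem_VOL_B"))
  sbr_idx <- which(desc$modality == "SBR" & desc$hemisphere %in% c("L", "R"))
  sbr_idx <- c(sbr_idx, which(desc$name == "striatum_SBR_B"))
  tag(c(vol_idx, sbr_idx), c("V2", "V3", "V4"))
  dti_idx <- which(desc$modality %in% c("FA", "MD") &
                     desc$hemisphere %in% c("L", "R", "B"))
  stopifnot(length(dti_idx) >= 160)
  tag(dti_idx[1:96], "V4")
  tag(dti_idx[97:160], "V3")

  if (include_std) {
    std_src <- desc$name[c(sbr_idx)]
    std <- data.frame(name = paste0(std_src, "-std"),
                      roi = NA_character_, modality = NA_character_,
                      hemisphere = NA_character_, views = "",
                      stringsAsFactors = FALSE)
    desc <- rbind(desc, std)
  }
  rownames(desc) <- NULL
  desc
}

#' Read or write a pathway bin specification as YAML
#'
#' The on-disk form is a mapping `pathway -> {members: [{roi, modality}],
#' signs: {...}, weights: {...}}`; the canonical specification ships with
#' the package in `inst/extdata/canonical_bins.yaml`.
#'
#' @param path YAML file path.
#' @return for `read_bin_spec`, a bin-spec list as from
#'   [canonical_bin_spec()].
#' @export
read_bin_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(b) {
    members <- do.call(rbind, lapply(b$members, function(m)
      data.frame(roi = m$roi, modality = m$modality,
                 stringsAsFactors = FALSE)))
    list(members = members,
         signs = unlist(b$signs), weights = unlist(b$weights))
  })
}

#' @rdname read_bin_spec
#' @param spec a bin-spec list.
#' @export
write_bin_spec <- function(spec, path) {
  out <- lapply(spec, function(b) {
    list(members = lapply(seq_len(nrow(b$members)), function(i)
      list(roi = b$members$roi[i], modality = b$members$modality[i])),
      signs = as.list(b$signs), weights = as.list(b$weights))
  })
  yaml::write_yaml(out, path)
  invisible(path)
}
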