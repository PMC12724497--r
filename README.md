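# pathwaycc

Pathway-anchored multimodal co-clustering of neuroimaging cohorts.

## What this is for

Multimodal imaging studies of Parkinson's disease collect, for every
subject, regional T1 volumes (`VOL`), diffusion microstructure (`FA`,
`MD`) and dopamine-transporter SPECT binding ratios (`SBR`), alongside
clinical scales for motor severity (MDS-UPDRS III), global cognition
(MoCA) and impulsive-compulsive behavior (QUIP). `pathwaycc` is for
analysts who want two linked readouts from such a subject-by-feature
table:

* **data-driven strata**: joint patient clusters and feature modules
  from a variational co-clustering model, with model selection, seed
  stability and bootstrap stability built in;
* **mechanism-aligned scores**: a Multimodal Pathway Integrity Score
  (MPIS) per predefined anatomical circuit (nigrostriatal,
  frontostriatal, cerebello–thalamo–cortical, limbic, microvascular,
  sensory/visuospatial), linked to the clinical scales post hoc with
  rank statistics under FDR control.

Because the cohorts this targets sit under data-use agreements, the
package includes a Gaussian-copula synthetic cohort generator with
planted block structure and planted rank effects, so every stage of the
pipeline can be exercised and tested against known truth.

## The two core constructions

**MPIS.** For subject *i* and pathway *p* with per-modality member sets
*F_p*, the score is the standardized signed sum of z-scored features

    MPIS_i(p) = Z( Σ_FA w_FA z_ij − Σ_MD w_MD z_ij + Σ_VOL w_VOL z_ij + Σ_SBR w_SBR z_ij )

with mean diffusivity entering negatively (higher MD means degraded
tissue) so that higher MPIS always reads as greater inferred circuit
integrity; `Z` standardizes across subjects. Robustness variants swap in
ICV-normalized volumes, pathway-specific modality weights, or an
unsigned MD term.

**Co-clustering.** Subjects and features are clustered jointly by a
pair of variational autoencoders with learnable Gaussian-mixture latent
priors — a row model on X and a column model on Xᵀ — trained with
`L = L_row + L_col + L_MI`, where each side is reconstruction plus a
KL term against its mixture (`β` warm-up), and `L_MI` couples the two
soft partitions through the mutual information of their data-weighted
cross-tabulation, vanishing exactly when hard assignment loses no
association. Cluster counts are chosen by a parsimony rule on
cluster-aware held-out reconstruction error over a (Kr, Kc) grid.

The methods vignette (`vignettes/pathway-coclustering.Rmd`) documents
the models, defaults and numerical choices in detail.

## A worked example

Generate a cohort of 294 subjects (185 PD, 72 HC, 37 SWEDD) with two
planted pathway–outcome rank effects, score the six pathways and test
the associations:

```r
library(pathwaycc)

cfg <- synthetic_config(
  n_per_group = c(PD = 185, HC = 72, SWEDD = 37),
  pathway_effects = list(nigrostriatal = c(UPDRS3 = -0.201),
                         sensory = c(MoCA = 0.163)),
  seed = 42)
cohort <- generate_cohort(cfg)

loaded <- load_feature_table(cohort$features, cohort$clinical)
fm   <- zscore_columns(loaded$features)
bins <- assign_pathway_bins(fm$descriptors, canonical_bin_spec())
mpis <- compute_mpis(fm, bins)
mpis
#> <mpis_table> 294 subjects x 6 pathways (variant: primary)

assoc <- mpis_association_table(mpis, loaded$clinical, B = 1000, seed = 1)
subset(assoc, q <= 0.05)
#>          pathway outcome   n   rho ci_low ci_high      p     q
#> 1  nigrostriatal  UPDRS3 294 -0.16 -0.268  -0.048 0.0050 0.045
#> 17       sensory    MoCA 294  0.18  0.062   0.295 0.0017 0.031
```

Exactly the two planted effects survive FDR at q = 0.05, at magnitudes
consistent with their targets (−0.201 and 0.163) given a single cohort
of n = 294: lower nigrostriatal integrity goes with higher motor
severity, higher sensory/visuospatial integrity with better cognition.

The full analysis is laid out as numbered drivers under `analysis/`
(cohort generation → QC and views → co-clustering with model selection
→ stability → MPIS and variants → clinical statistics), each a thin
script over the package functions that prints what it found and writes
its tables under `results/`.

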