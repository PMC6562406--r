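---
title: "Quantifying combinatorial histone H3 PTMs with a super-SILAC spike-in"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying combinatorial histone H3 PTMs with a super-SILAC spike-in}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histonePTM)
```

## The measurement problem

Histone H3 tails carry combinatorial lysine methylation and acetylation that
regulate chromatin state, and their global levels shift in disease —
most notably a broad loss of H3K14 acetylation reported across tumor types.
Bottom-up mass spectrometry quantifies these marks at the peptide level: the
protein is digested into a handful of tail peptides (spans 3–8, 9–17, 18–26,
27–40 and 73–83 on the mature H3 numbering, A = 1), and each peptide is
observed as a set of *peptidoforms* — distinct modification combinations on
the same backbone.

Two chemical tricks make the measurement tractable:

1. **D6-acetic anhydride derivatization.** Before trypsin digestion,
   unmodified and monomethylated lysines are chemically d3-acetylated. This
   (a) blocks tryptic cleavage after lysine, so digestion becomes
   "Arg-C-like" (cleavage strictly after arginine, giving reproducible
   peptides), and (b) shifts unmodified lysines by +45.0294 Da — resolvable
   from endogenous acetylation (+42.0106 Da).
2. **Super-SILAC spike-in.** A fixed mixture of heavy-labeled
   (\(^{13}C_6\,^{15}N_4\)-arginine, +10.00827 Da per R) histones is added to
   every sample before digestion. Quantification is reported as light/heavy
   (L/H) ratios of relative abundances, which cancels processing and
   instrument variability between runs.

The quantity of interest is the **percent relative abundance** of form \(i\)
within its peptide family:

\[
\%RA_i = 100 \cdot \frac{AUC_i}{\sum_{j \in \text{observed forms}} AUC_j},
\qquad
\text{L/H ratio}_i = \frac{\%RA_i^{\text{light}}}{\%RA_i^{\text{heavy}}},
\]

where \(AUC\) is the area under the extracted ion chromatogram (XIC) of the
2+ and 3+ precursors, summed. Single-residue **total marks** aggregate
combinatorial forms, e.g. total H3K14ac = K14ac + K9me1/K14ac + K9me2/K14ac +
K9me3/K14ac + K9ac/K14ac, total H3K9me3 = K9me3 + K9me3/K14ac, and total
H3K27me3 = K27me3 + K27me3/K36me1.

## The substrate model

`build_h3_library()` digests the mature H3 reference in silico, enumerates the
Cartesian product of allowed lysine states per family and computes exact
monoisotopic masses and m/z values:

```{r}
lib <- build_h3_library()
head(lib[lib$family_id == "9-17",
         c("form_id", "states", "mass", "mz_light_z2", "mz_heavy_z2")])
```

Lysine states are `d3ac` (chemically derivatized, endogenously unmodified),
`d3ac_me1` (monomethyl + derivatization), `me2`, `me3` and `ac`. Two mass
tables coexist: full double precision derived from atomic masses (used for
all m/z computation) and the "configured" values as printed in the
database-search setup (+45.0294, +14.016, +28.031, +42.046, +42.010,
+59.0454 Da). The configured me3/ac entries are truncations, not roundings,
of the exact values (42.04695, 42.01056); we keep them verbatim as
configuration echoes and never mix the two tables. The protein-level
derivatization is modeled as a single round on lysine side chains only;
peptide N-termini are not derivatized (the chemistry happens at the protein
level, before digestion), and N-terminal A1 acetylation is not enumerated by
default.

Default state sets per family follow the marks the assay routinely reports
(e.g. K14 is enumerated as `d3ac`/`ac` only; K36 has no `ac` state; K37 stays
derivatized). Users can widen any of these via the `states` argument.

## XIC quantification

`extract_xic()` matches centroids within 10 ppm of the target m/z (rounded to
four decimals first), per scan, and `integrate_auc()` integrates the trace
trapezoidally. Moving methyl groups between lysines does not change the
peptide mass, so several peptidoforms are strictly isobaric (e.g. K9ac vs
K14ac on the 9–17 peptide; K27me3, K36me3, K27me1/K36me2 and K27me2/K36me1 on
27–40). Such sets share one chromatogram with multiple apexes.
`resolve_isobaric()` splits the trace at the intensity valleys between
detected apexes and assigns the segments to forms by their expected elution
order; if the apex count does not match the number of expected forms the set
is flagged and all areas are withheld rather than guessed. This is a
deterministic, testable replacement for the expert manual curation the
workflow traditionally relies on; the expected-order template ships per
peptide family and is configurable. AUCs of the 2+ and 3+ precursors are
summed per form. Identifications are pre-filtered by search score (≥ 60) and
site-localization probability (≥ 0.75), boundary values kept.

## Downstream statistics

- `relative_abundance()` uses a per-sample, per-channel denominator over the
  *observed* forms, so forms missing in one sample shrink only that sample's
  denominator.
- `lh_ratio()` drops heavy-without-light pairs (spike-in signal with no
  sample counterpart carries no information about the sample) but keeps
  light-without-heavy as missing ratios, so channel-level outputs retain
  them.
- `normalize_ratios()` divides each column by the mean of its present values,
  across all samples or within sample groups (e.g. within each tumor type);
  it is idempotent and leaves column means at 1.
- `aggregate_marks()` sums member %RA per channel first and then takes the
  ratio. A ratio of sums is the natural reading of a "total mark" L/H ratio
  and is invariant to independent rescaling of the channels; the
  mean-of-ratios alternative is available as a mode for sensitivity analysis.
  Members missing in a sample contribute zero as long as at least one member
  is observed, with the count of missing members carried in the output.
- `compare_groups()` runs two-sided Student's t tests (pooled variance by
  default, Welch optional; paired via matched sample ids) with the display
  tiers p < 0.05 (dark) and p < 0.1 (light). No multiple-testing correction
  is applied at this stage by design — the profiling comparison is
  exploratory; `bh_fdr()` provides Benjamini–Hochberg adjustment where a
  cutoff-based screen is wanted.
- `ki67_correlation()` reports Pearson r against the proliferation index with
  the display rule r > 0.4 taken literally (a strongly negative correlation
  is not flagged for display; an absolute-value mode exists because the
  intended behavior for negative r is ambiguous).
- `pca_with_policy()` removes samples with more than 10 missing values, then
  features with no valid value in one group or more than 5 missing values,
  imputes the rest with the feature mean over all retained samples, centers,
  and decomposes. With no missing data it reduces exactly to plain centered
  PCA (tested against a direct covariance eigendecomposition).
- `hcluster_corr()` clusters with correlation distance (1 − Pearson r) and
  average linkage (UPGMA); constant profiles are excluded and reported rather
  than silently given undefined distances.

Degenerate-input conventions: identical paired vectors give t = 0, p = 1
(the underlying test is undefined there and "no change, no evidence" is the
honest summary); groups with fewer than two values are flagged not
computable, mirroring the grey cells of a heatmap display.

## The synthetic cohort generator

`generate_cohort()` produces ground-truth cohorts so every stage is testable
without any raw-data download. What it emulates:

- light/heavy channels with a **fixed spike-in profile** shared by all
  samples (the heavy mixture is blended once);
- group-level effect sizes as **fold changes on total-mark members**,
  renormalizing each family to 100 (default: total H3K14ac halved and total
  H3K9me3 increased 1.5-fold in "tumor", the directions seen in tissues);
- **multiplicative lognormal noise** on AUCs (sd 0.2 on the log2 scale by
  default), the standard error model for MS intensities, plus a per-sample
  global loading factor that %RA cancels by construction;
- a **Ki-67 covariate** linked to a chosen mark (default total H3K9me3,
  target r = 0.6) through a per-sample biological multiplier, plus residual
  noise;
- optional missingness, and Gaussian elution peaks (`simulate_peaks()`) at
  the exact library m/z for charges 2+ (70%) and 3+ (30%), with isobaric
  partners spaced 0.7 min apart.

Default cohort sizes (8 samples per group) mirror desk-scale tissue panels.
Baseline %RA profiles are the package's own choice of realistic resting
values (every form non-zero so isobaric resolution is exercised); real
inter-sample variance structure, chromatographic drift, batch effects,
FFPE storage artifacts and MS2-level identification errors are *not*
modeled — so passing tests demonstrate correctness of the computation, not
robustness to every artifact of real acquisitions. FFPE artifacts are
representable only as a form-exclusion mask on the affected marks.

Numerical choices: peaks carry ~35 points (sd 0.12 min sampled every
0.02 min), keeping trapezoidal integration error well below 0.5%; XIC
apex detection uses a 5% relative-height floor; problem sizes in the test
suite (100 seeded cohorts for sign recovery, 15 × 46 features for null
calibration, 1000 random sequences for the digestion oracle) were chosen to
give stable Monte-Carlo answers at desk scale.

## A worked example

```{r}
cfg <- cohort_config(n_per_group = c(normal = 8, tumor = 8),
                     fold_changes = c(total_H3K14ac = 0.5),
                     noise_sd = 0.2)
co <- generate_cohort(cfg, seed = 1)
res <- analyze_cohort(truth_auc(co), co$metadata)
res$mark_results[, c("feature", "t", "p", "direction", "tier")]
res$fold_change
```

The halved total H3K14ac is recovered as a significant decrease; the
fold-change estimate is compared against the renormalized truth (halving the
members changes the family denominator too, so the true mark-ratio change is
0.5 divided by the renormalization factor, ≈ 0.578 for the default
baseline).

## The HME catalogue

`load_hme_catalog()` ships a curated table of 88 histone-modifying enzymes
(17 acetyltransferases, 18 deacetylases, 32 methyltransferases, 21
demethylases) with substrate residues. Exact membership at the margins
(moonlighting and putative enzymes) is a curation choice documented per
entry, and the file is replaceable by any TSV of the same schema.
`hme_consistency_report()` checks measured mark directions against enzyme
expression changes supplied by the user (writers up ⇒ mark up, erasers up ⇒
mark down); it performs no differential-expression analysis itself.

## Known limitations

- No retention-time alignment across runs; expected elution times come from
  identifications or the simulator.
- No isotopic-impurity correction and no profile-mode peak picking (input is
  centroided MS1).
- Unresolvable co-eluting isobars are withheld, never apportioned.
- %RA denominators are per channel; a joint-denominator mode restricted to
  forms observed in both channels is available
  (`relative_abundance` on a pre-filtered table) but per-channel independence
  is the default, matching the observed-forms definition.
- A single H3 reference is used; sequence variants (e.g. H3.3 S31) are not
  quantified separately.
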