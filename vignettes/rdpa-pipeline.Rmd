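---
title: "Identifying RNA-dependent PIP2-associated proteins and profiling their disordered regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying RNA-dependent PIP2-associated proteins and profiling their disordered regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdpatools)
```

## The biological question

Nuclear phosphatidylinositol 4,5-bisphosphate (PIP2) resides in membraneless
compartments — nuclear speckles, nucleoli and nuclear lipid islets — and
co-purifies with a specific set of proteins.  Part of that association is
mediated by higher-order RNA: when double-stranded RNA is digested with
RNase III, some proteins lose their PIP2 association (the dsRNA+ set) and a
few gain it (dsRNA−).  We call the union of proteins whose PIP2 association
responds to RNA removal the RNA-dependent PIP2-associated (RDPA) proteome.

`rdpatools` implements the full desk-side analysis for this experimental
design: the statistical identification of RDPA proteins from a three-condition
label-free pull-down (a wild-type PH-domain probe with high PIP2 specificity,
its binding-deficient R40A point mutant as control, and the wild-type probe
after RNase III treatment, three replicates each), followed by the sequence-
level characterization of the identified proteins — intrinsically disordered
regions (IDRs), polybasic K/R motifs, per-IDR charge and hydropathy, PTM
co-location, set enrichment — and the companion image quantification (3D foci
counting and colocalization).  Because raw mass-spectrometry data of this
kind are rarely redistributable, the package ships generators that produce
every input with planted ground truth, and the whole pipeline is validated
against those truths.

## The statistical model for RDPA discovery

The pipeline starts from a log2 LFQ intensity matrix (protein groups ×
samples) with missing values.  Three steps mirror standard label-free
practice:

1. **Valid-value filtering** (`filter_valid_values()`): a protein group is
   kept only if it has 100% valid values in at least one sample group.
   This guarantees that at least one condition provides a complete,
   observed profile before anything is imputed.

2. **Downshifted-normal imputation** (`impute_downshifted()`): missing
   values in label-free data are predominantly left-censored (low
   abundance).  Each missing cell in column $c$ is replaced by a draw from
   $\mathcal{N}(m_c - 1.8\,s_c,\ (0.3\,s_c)^2)$, where $m_c$ and $s_c$ are
   the observed mean and SD of that sample.  `width = 0.3` and
   `shift = 1.8` are the conventional defaults; imputation is per sample
   because each sample has its own intensity distribution (a global mode is
   available).

3. **S0-moderated testing with permutation FDR** (`permutation_fdr()`):
   for each protein the moderated statistic is

   $$d = \frac{\bar{x}_A - \bar{x}_B}{SE + s_0},$$

   with $SE$ the pooled equal-variance standard error and $s_0 = 0.2$ a
   fudge factor that penalizes small fold-changes attained with small
   variance (with $s_0 = 0$, $d$ is the classical two-sample t statistic).
   Significance is assessed by relabeling the samples: for a threshold
   $t^*$ the estimated FDR is the mean number of permuted statistics beyond
   $t^*$, divided by the number of observed statistics beyond $t^*$
   ($\pi_0$ fixed at 1, conservative), and a protein's q-value is the
   minimum estimated FDR over thresholds at which it is called.

The **two-step RDPA call** (`call_rdpa()`) chains two such tests: step 1 is
one-sided (enrichment of WT over R40A, FDR < 0.05) and defines the
PIP2-associated proteome; step 2 restricts the WT vs WT+RNaseIII matrix to
the step-1 significant proteins and tests two-sided.  Proteins significantly
lower after RNase III are dsRNA+, significantly higher dsRNA−.  The gating
matters: a protein with a huge RNase response but no R40A enrichment is never
called.

Numerical choices worth knowing:

* With three replicates per group there are only $\binom{6}{3} = 20$
  distinct label assignments; whenever the requested permutation count
  exceeds the number available, all of them are enumerated exactly, making
  the test deterministic given the data.
* The observed labeling — and, in balanced designs, its mirror image (the
  same partition with group labels swapped) — is excluded from the
  permutation set.  The mirror assignment reproduces the observed $|d|$
  exactly, so keeping it would bound the estimated FDR below by
  $1/n_\text{perm}$ and, with a two-sided test, no call could ever clear an
  FDR of 0.05 with 20 assignments.
* Equal observed statistics receive equal q-values; q-values are clamped to
  $[0, 1]$ and are monotone in the statistic by construction.
* Replicate quality control (`qc_replicates()`) reports per-sample medians
  and inter-sample correlations; flagging an outlier replicate never removes
  it automatically — removal is a deliberate user decision.

## Dataset construction

`build_fraction_datasets()` derives the named protein sets used by all
downstream comparisons from nuclear- and cytosolic-fraction quantification
evidence.  A protein is *quantifiable* in a fraction if it has at least
`min_reps = 2` valid values there.  "Not in the other fraction" is read as
the mirror of the same rule (fewer than `min_reps` valid values), not as
zero observations; we prefer the mirror reading because it applies one
quantifiability criterion symmetrically, and expose `strict_absence = TRUE`
for the literal reading.  RDPA members are added to the nuclear-side sets,
so `RDPA ⊆ Nucleo-specific ⊆ Nuclear-fraction ⊆ Total-cell` holds by
construction and is asserted on every build.

## IDR annotation and the consensus rule

Disorder predictions arrive as per-predictor interval tables (several
independent predictors per protein, as in multi-predictor disorder
databases).  Coordinates are 1-based inclusive everywhere.  Two consensus
notions are exposed, and they serve different purposes:

* `consensus_regions(k = 3, min_len = 20)` — maximal runs of residues
  covered by at least three distinct predictors, at least 20 residues long.
  These *regions* are the unit for per-IDR metrics (length, pI, GRAVY, PTM
  co-location).
* `assign_hits_to_idrs(k = 3, min_len = 20)` — a motif *site* counts as
  inside an IDR only if at least three predictors each report an interval of
  ≥ 20 residues fully containing the motif span.  Full containment (rather
  than midpoint or partial overlap) is the default because a site-level
  claim should hold for the whole motif.

A protein counts as IDR-containing when any single-predictor interval
reaches 20 residues (`protein_has_idr()`); a stricter 30-residue variant is
a plain parameter.  Per-IDR pI and GRAVY are computed on the ≥3-predictor
coverage consensus by default; single-predictor intervals can be supplied
instead, since either convention appears in practice.

## K/R motif scanning

Three polybasic patterns are scanned (PROSITE notation):
`[KR]-x(3,7)-K-x-[KR]-[KR]` (long), `[KR]-x(3,7)-K-x-[KR]` (mid) and
`[KR]-x(3,7)-K-x-K` (short).  Matching is greedy with no overlaps: the scan
walks left to right, the longest feasible spacer wins at each start, and
scanning resumes immediately after an accepted hit.  The three patterns are
scanned independently because each motif class is reported separately; the
wildcard `x` matches the 20 canonical residues plus `X`.  The test suite
pins the scanner against a brute-force candidate-enumeration oracle (sort
candidates by start, then longest-first; accept non-overlapping) on tens of
thousands of random K/R-enriched sequences.

## Physicochemistry

The isoelectric point is the root of the Henderson–Hasselbalch net-charge
curve (positive terms: N-terminus, H, K, R; negative: C-terminus, D, E, C,
Y), found by bisection on pH ∈ [0, 14] and iterated well past the requested
tolerance so the residual charge at the returned pH stays below $10^{-3}$
even for long, highly charged sequences.  The pKa set defaults to the EMBOSS
constants; it is configuration, and the package's claim is internal
consistency (the returned pH verifiably zeroes the charge curve), not
agreement with any particular external implementation.  GRAVY is the mean
Kyte–Doolittle hydropathy; `X` is excluded from numerator and denominator.
IDRs split into an acidic population (pI < 7, D/E-enriched) and a basic one
(pI ≥ 7, K/R-enriched); the boundary value 7.0 goes to the basic class, and
bimodality is reported descriptively (summary/density exports) rather than
by a formal mixture fit.

## PTM co-location and enrichment statistics

`ptm_frequency_table()` reports, per dataset, the number of consensus IDRs
containing at least one hit of a chosen K/R pattern and the percentage of
those IDRs containing at least one site of each modification type
(acetylation, methylation, phosphorylation, sumoylation, ubiquitination).
The unit is the IDR, not the protein — one protein may contribute several
qualifying IDRs — and presence, not site count, is what matters.  Datasets
with no qualifying IDRs report `NA` percentages, never 0.

Over-representation of a feature list in a dataset against a background
uses the exact hypergeometric tail, inclusive form ($P(X \ge k)$ for
enrichment), computed with `phyper`.  Metric distributions across datasets
are compared with pairwise two-sided Wilcoxon rank-sum tests under
Benjamini–Hochberg correction; summaries follow boxplot conventions
(median, type-7 quartiles, 1.5 × IQR whiskers, outliers listed).

## Image quantification

Volumes are 3D arrays.  Nucleus segmentation blurs the DAPI channel with a
separable Gaussian, applies a global Otsu threshold and labels 26-connected
components.  Foci counting deletes the signal outside the nuclear mask,
blurs (default σ = 1.5 voxels; the σ of the original acquisition macro is
not a published constant, so it is an explicit parameter), thresholds within
the mask and discards components below 10 voxels (the minimum size filter
keeps ≥ 10).  Because Otsu always splits a unimodal histogram somewhere, a
focus-free nucleus would otherwise yield large spurious "foreground"
patches of smoothed noise; the foci threshold therefore takes the maximum of
the within-mask Otsu value and mean + 3 SD of the in-mask intensities — a
standard guard for degenerate, signal-free images.

Colocalization reports Pearson and Spearman correlations over in-mask
voxels plus the Manders coefficients.  M1/M2 default to the original
unthresholded form (fraction of one channel's intensity where the other
channel is above zero) so that the identity "identical channels give
M1 = M2 = 1" holds exactly; per-channel Otsu thresholds are available as an
option.  The randomized null rotates one channel by a right angle in-plane —
an interpolation-free operation that preserves the intensity histogram
exactly — and recomputes the coefficients over the intersection of the mask
with its rotated image.  Rotation is about the grid centre (90°/270° require
square x–y dimensions), which coincides with the mask centroid for the
generated, centred nuclei.

## What the synthetic data emulate — and what they do not

The generators define the study conditions under which the pipeline is
validated:

* `generate_pulldown_experiment()` — 2,000 protein groups, baselines
  $\mathcal{N}(25, 2^2)$ log2 units, replicate noise SD 0.3, three
  replicates per condition; 195 planted PIP2-associated proteins (+2 log2
  in WT vs R40A), of which 150 dsRNA+ (−2 log2 after RNase III) and 15
  dsRNA− (+2); missingness logistic in true intensity (midpoint 7 log2
  units below the baseline mean), the left-censoring structure the
  downshifted imputation presumes.  The planted set sizes mirror the scale
  of the real design (195 step-1 calls, 168 + 15 step-2 calls).
* `generate_proteome()` — proteins of 300–600 residues; truth IDRs of
  40–120 residues with D/E-rich (D+E mass 0.30, K+R 0.05) or K/R-rich
  (mirrored) composition; a panel of nine synthetic predictors, each
  jittering truth boundaries by up to ±3 residues and dropping intervals
  with probability 0.1, so the ≥3-predictor consensus rule is genuinely
  exercised; planted K/R motifs inside or outside truth IDRs, flanked by a
  short non-K/R clear zone so the greedy scanner provably recovers exactly
  the planted span (accidental motifs elsewhere are allowed and are counted
  through the scanner itself); motif-hosting IDRs are exempt from predictor
  drop-out so their in/out truth is deterministic at full panel support.
  PTM sites are planted into motif-hosting IDRs at per-type rates, without
  residue-type specificity (a documented simplification).
* `generate_image_stack()` — 96 × 96 × 32 voxel volumes, ellipsoidal
  nuclei, Gaussian-profile foci (radius 3 voxels, peak 10 × the
  intra-nuclear background, centres at least 3 radii apart), additive
  Gaussian noise at SNR 5, and an optional second channel sharing a
  configurable fraction of focus positions.

These generators reproduce the *statistical structure* of the real inputs
— effect sizes, missingness mechanism, predictor disagreement, charge
composition, image SNR — not their scale or biology.  Passing tests
demonstrate that the algorithms recover planted truth under realistic noise;
they do not certify recovery of any particular real dataset's membership
lists, which depend on unreleased raw spectra and versioned external
databases.  Every generator is a pure function of its configuration and
seed.

## Problem sizes used by the validation suite

The test suite and the acceptance script validate at these scales: 10,000
random sequences per motif pattern against the scanner oracle; 1,000 random
interval configurations against per-residue coverage counting; 500 random
sequences for the pI contract plus a 0.0001-pH grid search; 10,000 imputed
draws for the imputation distribution; five replicate simulations of the
full two-step design (2,000 × 6 matrices, 250 permutations); twenty null
matrices for FDR control; fifty synthetic nuclei with planted counts 0–20;
and twenty random proteomes for the PTM-table oracle.

## Known limitations

* The S0/permutation-FDR machinery follows the canonical SAM-style form;
  exact numerical equivalence with any specific GUI implementation is not
  claimed, since their internals are not published.
* Protein-group inference, raw spectral processing and LFQ normalization
  are out of scope: the pipeline starts at the intensity matrix.
* One canonical sequence per protein id; no isoform handling.
* No disorder prediction and no database clients: disorder intervals, PTM
  tables and annotation memberships are consumed as files.
* Image analysis assumes isotropic voxels apart from metadata pass-through;
  no deconvolution or super-resolution reconstruction.

## A worked example

```{r example, eval = FALSE}
library(rdpatools)

# 1. identify RDPA proteins from a synthetic pull-down
exp <- generate_pulldown_experiment(seed = 11)
call <- call_rdpa(exp$wt_vs_r40a, exp$wt_vs_rnase, seed = 11)
print(call)

# 2. characterize a synthetic proteome
pt <- generate_proteome(n_proteins = 200, seed = 11)
hits <- assign_hits_to_idrs(scan_proteome(pt$proteome), pt$disorder)
regions <- consensus_regions(pt$disorder)
profile <- idr_physchem(pt$proteome, regions)
table(profile$charge_class)

# 3. PTM co-location, Table-2 style
ptm_frequency_table(list(all = names(pt$proteome)), regions, hits, pt$ptm_truth)
```
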