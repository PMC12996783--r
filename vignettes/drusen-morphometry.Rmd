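---
title: "Methods: drusen morphometry, POS clearance, and reporting statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drusen morphometry, POS clearance, and reporting statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retquant)
```

This vignette documents the measurement model behind `retquant`: what each
stage computes, the assumptions it makes, the parameters that matter and
their defaults, what the synthetic generators do and do not emulate, and
the numerical choices taken where the procedures admit more than one
reasonable reading.

## 1. The measurement problem

Drusen — lipoprotein deposits between the retinal pigment epithelium
(RPE) and Bruch's membrane (BrM) — are the hallmark lesion of early
age-related macular degeneration. On spectral-domain OCT they appear as
focal elevations of the RPE/photoreceptor-outer-segment (RPE/POS)
boundary above the Choroid/BrM boundary. This package quantifies them
from *segmented boundary surfaces* (the output of clinical layer
segmentation software), not from raw OCT intensities: segmentation is
upstream and out of scope.

A second, mechanistically linked assay is photoreceptor outer-segment
(POS) clearance: outer segments shed at a morning peak are phagocytosed
by the RPE, and delayed digestion is visible on RPE flat mounts as
rhodopsin-positive dots that persist hours after shedding. The clearance
statistic here is the percentage of dots per RPE cell remaining at 11 am
relative to 8 am.

## 2. Drusen morphometry

### Thickness

For one eye at one visit the input is a complete rectangular grid of
boundary depths over `n_bscans x n_ascans` (defaults 61 x 512; B-scans
109 µm apart). Depths increase posteriorly, so layer thickness is

$$T(b, a) = z_{\mathrm{BrM}}(b, a) - z_{\mathrm{RPE/POS}}(b, a) \quad [\mu m].$$

A missing sample is an error, never imputed: silent imputation of a
segmentation hole inside a druse would bias heights. Small negative
values can arise from segmentation noise; values below
\(-3\sigma_{\mathrm{noise}}\) are counted in an attribute as a data-quality
flag.

### Detection

The study-level criterion for counting a druse is visual ("a clear,
visible distortion of the boundary"); `detection_params()` operationalizes
it:

| parameter | default | meaning |
|---|---|---|
| `min_peak_height_um` | 10 µm | peak excess over the reference a component must reach |
| `min_sections` | 2 | B-scans a *visible* druse must span |
| `min_footprint_ascans` | 3 | A-scans in the widest section of a visible druse |
| `baseline_smoothing_window` | 31 A-scans | running-median window for the per-B-scan reference |

The reference profile is a running median per B-scan: with a 31-sample
window (~530 µm laterally) it follows smooth retinal curvature and any
shared surface undulation while stepping over druse-scale bumps. The
excess map `T - reference` is thresholded at *half* the peak threshold, so
a footprint includes the druse's flanks down to 5 µm of elevation;
4-connected components (labelled via `EBImage::bwlabel`) whose peak
reaches 10 µm are kept. Components failing the section/width rules are
still reported but flagged not visible — they do not enter counts or
track building, which keeps single-pixel noise excursions out of the
longitudinal analyses.

### Height

The drusen-free baseline for a druse is the mean thickness of the two
adjacent sections — the first B-scan before its footprint and the first
after — over the druse's A-scan span, the same two sections for every
section of that druse. Two readings of the published wording were
possible here and we note both explicitly:

* Read literally, druse thickness "subtracted from" the flanking average
  yields negative elevations; we compute druse minus baseline so heights
  are positive, matching how growth is reported (larger heights, ratios
  above 1).
* Per-section druse thickness is not specified as peak or mean over the
  druse's lateral extent; we use the mean over the footprint's A-scans in
  that section for noise robustness, and also report the peak
  (`peak_height_um`).

Per-section heights are clipped at 0 — residual small values where a
druse is absent are kept as small positives so ratios stay interpretable
— and the average height is the arithmetic mean over the sections the
footprint spans. A footprint touching the first or last B-scan uses a
one-sided baseline and is flagged `edge` rather than excluded, keeping
counts conservative and auditable.

The flanking sections are required to be free of *the measured druse*
only (their residual elevation from it is what the default seed geometry
keeps below ~1 µm); they are not required to be free of all drusen, since
with the default footprint threshold a neighbouring druse overlapping the
flanking section would have merged into the same component anyway.

## 3. Longitudinal analyses

Tracking links visible detections at consecutive visits by greedy
nearest-centroid matching within 200 µm (about two B-scan spacings), ties
broken toward the earlier detection and logged. The matching is greedy
because the real procedure it stands in for is manual inspection of a
few dozen drusen per eye, where ambiguous matches are rare by
construction; unmatched detections start new tracks. Merges and splits
between visits are not modelled — each keeps its own track.

Every track has a fixed anchor (the footprint of its first detection) and
is measured at *every* visit: where it has no detection, the height is
re-measured at the anchor footprint on that visit's thickness map, so
appearance and disappearance yield genuine 0 (or small residual) heights
rather than missing data. Three per-arm summaries follow:

1. **Counts** (`count_visible`): visible tracks per visit, pooled across
   the arm's eyes.
2. **Average height change** (`average_height_change`): mean height over
   all tracked locations at the visit minus the same mean at baseline;
   positive means growth. All locations enter, including zero heights.
   Drusen are pooled directly across an arm's eyes (each druse is one
   observation), not averaged per eye first.
3. **Change ratios** (`change_ratio`): `h(t)/h(0)` per track, with the
   two degenerate rules applied literally: a zero baseline sets the
   denominator to 1 (so the ratio numerically equals the later height in
   µm — a deliberate unit mix we preserve because downstream
   classification only asks whether the ratio is 0, below, at, or above
   1), and a zero later height gives ratio 0. For reporting, ratios are
   classified with a tolerance of 0.05 around 1 ("unchanged"), a band the
   source procedure leaves unstated.

The packaged count series (`nhp_drusen_counts()`) transcribes the
published per-arm totals; the two unreported mid-study values of the
uninjected arm are `NA`, and its 9-month value follows arithmetically
from the reported equal 7-drusen increment in both arms between 9 and 12
months.

## 4. POS clearance

`filter_dots` keeps dots with diameter **strictly** greater than 2 µm — a
2.0 µm dot is excluded, and a mount whose dots all measure exactly 2 µm
counts zero. `sample_fields` places 10 axis-aligned squares of
40,000 µm² (side 200 µm) with centers uniform in the 1.5 mm disk,
non-overlapping by rejection sampling (10,000-attempt budget),
deterministic under a seed. Squares are used because the source protocol
says only "areas"; squares make containment tests exact. Cells belong to
a field by centroid and dots by center point, so nothing is
double-counted across fields. Per field, dots/cell is the ratio of the
two counts; per mount the 10 fields are averaged, and

$$\mathrm{percent\ remaining} = 100 \times
  \frac{\overline{\mathrm{dots/cell}}_{11\,\mathrm{am}}}
       {\overline{\mathrm{dots/cell}}_{8\,\mathrm{am}}}.$$

A zero 8 am mean is an explicit undefined-ratio error. Whether the
original fields could overlap, or straddling cells were fractionally
counted, is unstated; non-overlap and centroid membership are this
package's choices.

## 5. Reporting statistics

* **Lipid composition**: every species response becomes a relative
  percentage of a sum — class percentages of the per-sample total, and
  species percentages of the per-sample class total — with group means
  ± SEM. Per-sample class percentages sum to 100 by construction.
* **Margin of error**: phenotype frequencies k/n carry a binomial margin
  of error. No formula is stated by the source; the default is the Wald
  margin at 95%, \(z\sqrt{\hat p(1-\hat p)/n}\), with Wilson available via
  `method = "wilson"` because Wald degenerates to zero at \(\hat p \in \{0, 1\}\).
* **Group tests**: two groups get a two-tailed Welch t test (the
  unequal-variance form is the safer default where only "t test" is
  specified); more groups get one-way ANOVA. SEM is `sd/sqrt(n)`; stars
  at 0.05/0.01/0.001/0.0001. No multiple-testing correction by default,
  matching the descriptive reporting style; `bonferroni_m` exists for
  users who want it.

## 6. Synthetic data: what it emulates and what it does not

The generators provide seeded, ground-truth-annotated inputs carrying
the statistical structure the analysis stages assume.

**OCT volumes** (`generate_oct_series`): the BrM surface is a smooth
two-axis sinusoidal undulation (default amplitude 5 µm, wavelength
2 mm) shared by both boundaries — so it perturbs depths but not
thickness — plus i.i.d. Gaussian axial noise per boundary sample
(default sd 2 µm, a plausible per-A-scan segmentation jitter). Drusen
are anisotropic Gaussian elevations of the RPE/POS boundary; the real
geometry of macaque drusen is not published at this resolution, and the
Gaussian is chosen for analytic evaluability: every test can compare
against closed-form peak heights and section means. Default scales
(σ 80 µm across B-scans, 60 µm laterally) make a 15–60 µm druse span
2–3 sections at 109 µm spacing — small drusen near the visibility
threshold, as in the motivating study — while keeping the first flanking
section's residual elevation under 1 µm so the flanking baseline is
honest. Two eyes per arm by default, mirroring the two-animal design
whose counts are pooled per arm. Amplitude trajectories are geometric
(`A0 · g^(t/3)` per arm); real drusen appear, merge and regress more
irregularly, so passing recovery tests shows the *pipeline's* fidelity,
not that real drusen are Gaussian. Speckle, raw intensities and
segmentation failure modes are not simulated.

**Flat mounts** (`generate_flatmount`): RPE cell centroids sit on a
jittered hexagonal lattice at the density implied by the mean cell area
(default 400 µm², a typical mouse RPE cell); the implied Voronoi regions
tile the disk, and each dot is generated inside its parent cell, making
dot-to-cell membership exact by construction (explicit cell polygons are
never needed downstream and are not materialized). Dot counts are
Poisson per cell — rate 10/cell at 8 am, within the ≥8 regime the
fixtures require — and the 11 am set is an independent redraw at rate
`10 × clearance_fraction`, modelling clearance as thinning. Diameters
are truncated normal (3 ± 0.6 µm), so the >2 µm filter passes ~95% at
both clock times and cancels in the ratio. The fixture catalog pins the
two genotype conditions the assay distinguishes: `rescued` (40%
remaining, normal clearance) and `diseased` (80%, delayed). Real mounts
add segmentation errors, uneven illumination and radial density
gradients that are not emulated.

**Lipid panels** (`generate_lipid_panel`): six classes with baseline
fractions, fixed uneven species weights within class, multiplicative
group effects and log-normal noise (CV 0.15), six samples per group —
enough structure to exercise normalisation and group tests, with the
closed-form renormalised fractions as the oracle.

## 7. Numerical choices and degenerate inputs

* Running median (`stats::runmed`, `endrule = "median"`) rather than a
  mean filter: robust to the druse's own mass inside the window.
* Footprint threshold at half the peak threshold: one fixed rule for the
  footprint extent, so per-section means are comparable across drusen.
* Component ordering by (centroid B-scan, centroid A-scan) makes
  detection output deterministic; matching ties are broken toward the
  lower detection id and logged.
* `change_ratio(0, 0) = 0` (never present), per the rule that zero later
  heights give 0 regardless of the denominator rule.
* Determinism: all generators consume an explicit seed via
  `withr::with_seed`, leaving the caller's RNG state untouched; identical
  spec + seed reproduces outputs bit-for-bit.

## 8. Problem sizes in the test suite

Unit and property tests that need many simulated studies run on reduced
grids (21 B-scans × 128 A-scans) — the measurement rules are
grid-size-agnostic, so nothing is lost by testing them small. The
end-to-end recovery checks (height recovery at 15–60 µm amplitudes with
2 µm noise; arm-ordering recovery over 10 studies; clearance recovery
over 5 seeds per fixture) use the full default geometry, since their
point is behaviour under the study conditions.

## 9. Known limitations

* Height only: en-face druse area and volume are not computed (the
  motivating analyses report heights and counts).
* Greedy 1:1 linkage cannot represent merging or splitting drusen.
* The descriptive statistics are not an inferential framework for
  two-animal designs; no mixed models or eye-level random effects.
* The Wald margin of error understates uncertainty at extreme
  frequencies; use Wilson there.
* Synthetic defaults for druse geometry and growth are plausible
  placeholders, not calibrated to primate data (none are published at
  this granularity).
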