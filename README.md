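# retquant

Quantification pipeline for longitudinal drusen morphometry on segmented
OCT volumes, photoreceptor outer-segment (POS) clearance on RPE flat
mounts, and the accompanying composition/frequency statistics. It is
aimed at retinal-degeneration labs that already have upstream
segmentation (OCT layer boundaries, flat-mount cell/dot detection) and
need the downstream measurement rules implemented reproducibly. Seeded
synthetic generators for every input type make the whole pipeline
testable without imaging data.

## What it computes

**Drusen morphometry.** From per-(B-scan, A-scan) depths of the
Choroid/Bruch's-membrane (BrM) and RPE/POS boundaries, layer thickness is
`T(b, a) = z_BrM(b, a) − z_RPE/POS(b, a)` (µm). Drusen are detected as
4-connected components of the excess of `T` over a per-B-scan
running-median reference, with a peak threshold (default 10 µm). Each
druse's drusen-free baseline is the average thickness of the two adjacent
sections — the first B-scan before and after its footprint — over its
A-scan span; its height in each section is the footprint's mean thickness
minus that baseline (clipped at 0), and its average height is the mean
over the sections it spans.

**Longitudinal analyses.** Drusen are linked across visits by greedy
nearest-centroid matching (default radius 200 µm); every tracked location
is re-measured at every visit even when no druse is present. Three
summaries per arm and visit: visible-druse counts, average height change
from baseline (positive = growth), and per-druse change ratios
`r = h(t) / h(0)` with the degenerate rules: if `h(0) = 0` the
denominator is set to 1, and `h(t) = 0` gives `r = 0`.

**POS clearance.** Rhodopsin-positive dots with diameter strictly
greater than 2 µm are counted per RPE cell in 10 randomly placed,
non-overlapping 40,000 µm² fields within 1.5 mm of the mount center; the
clearance statistic is `100 × (mean dots/cell at 11 am) / (mean dots/cell
at 8 am)`, the percentage of outer segments remaining three hours after
the shedding peak.

**Reporting statistics.** Per-sample phospholipid class percentages
(`100 × class sum / total response`) and species-within-class
percentages; binomial margins of error for phenotype frequencies (Wald by
default, Wilson optional); Welch t tests (two groups) or one-way ANOVA
(more), two-tailed, with per-group SEM.

## Worked example

```r
library(retquant)

spec  <- oct_study_spec(rng_seed = 1L)     # 61 B-scans, 109 um apart, 5 visits
seeds <- random_druse_seeds(spec, n_per_eye = 10,
                            growth_by_arm = c(injected = 0.85, uninjected = 1.15),
                            seed = 1L)
study  <- generate_oct_series(spec, seeds)
tracks <- build_tracks(study$volumes)
summarize_study(tracks)
```

At 3 and 6 months this prints:

```
         arm timepoint_months n_drusen mean_height_change_um mean_ratio
1   injected                3       20                -0.572      0.983
2   injected                6       20                -2.193      0.869
3 uninjected                3       20                 1.623      1.128
4 uninjected                6       20                 2.834      1.198
```

The treated (injected) arm, simulated with a 0.85× per-3-month growth
multiplier, shows negative mean height change and mean ratios slightly
below 1; the untreated arm (1.15×) grows, with most of its drusen in the
ratio > 1 class — the orderings the longitudinal analyses are designed to
expose.

```r
mount <- generate_fixture_mount("rescued", seed = 1L)  # 40% ground truth
clearance_percent(mount, n_fields = 10, seed = 1L)
#>   mean_dpc_8am mean_dpc_11am percent_remaining
#> 1         9.49          3.86              40.6
```

The full clearance pipeline (diameter filter, field sampling, dots per
cell) recovers the fixture's ground-truth 40% within sampling noise.

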