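# toscore

Rank-threshold colocalization analysis for two-channel microscopy signals.

## The problem

Quantifying whether two labeled molecules occupy the same regions of a cell
is a routine but surprisingly fragile task. Global statistics such as
Pearson's correlation (PCC), Spearman's rank correlation (SRCC) or Manders'
coefficients (M1/M2) summarize a whole cell with one number, and they
mislead when signals are mixed: a dim, diffuse *off-target* signal
(background, autofluorescence, unbound probe) together with a bright
*on-target* signal produces cells in which the answer genuinely depends on
the intensity threshold — correlated at low thresholds, anti-correlated at
high ones.

`toscore` implements the **threshold overlap score (TOS)**, a metric built
for exactly this situation, for anyone extracting per-cell pixel vectors
from fluorescence images (or simulating them).

## The metric

Thresholds are parameterized as *selected fractions*: after rank-ordering a
cell's pixels by intensity, the top fraction `F_T1` of channel-1 pixels and
`F_T2` of channel-2 pixels are selected. For a cell of `N` pixels:

- **AO** (fractional area of overlap): `AO1 = |sel1 ∩ sel2| / |sel1|`, and
  symmetrically `AO2`.
- **AO ratio**: observed AO over its chance expectation. Under a
  uniform-independent null, `E[AO1] = F_T2` and `E[AO2] = F_T1`, so
  `r = AO1 / F_T2 = AO2 / F_T1`. `r = 1` is chance-level overlap.
- Analytic bounds: `r_max = 1 / max(F_T1, F_T2)` (the smaller selection
  nested in the larger); `r_min = 0` when `F_T1 + F_T2 ≤ 1`, else
  `(F_T1 + F_T2 − 1) / (F_T1 · F_T2)` (forced overlap).
- **TOS** rescales `r` piecewise-linearly so that, at every fraction pair,
  `r_min → −1`, `1 → 0`, `r_max → +1`:

  ```
  TOS = (r − 1) / (r_max − 1)   if r ≥ 1
        (r − 1) / (1 − r_min)   if r < 1
  ```

  TOS > 0 is colocalization, TOS < 0 anti-colocalization, and values inside
  a band around 0 (default ±0.1) are reported as non-colocalization.

Computing TOS over all 81 combinations of `F_T1, F_T2 ∈ {0.9, …, 0.1}`
gives the **TOS matrix**, a heat map of localization versus signal
intensity. Three features summarize it: `TOS_h` (the score at the highest
thresholds, fraction pair (0.1, 0.1) — the on-target regime), `TOS_max` and
`TOS_min` (the grid extrema, locating strongest co- and anti-colocalization).

The package also ships reference implementations of the metrics TOS is
benchmarked against (PCC, SRCC, M1/M2 under Costes automatic thresholding,
and the chance-corrected M1diff/M2diff), three synthetic-cell simulators,
Mann–Whitney and ROC evaluation utilities, and TIFF + ImageJ-ROI per-cell
extraction.

## Worked example

A simulated "condition negative" cell: 600 pixels, half positively
correlated off-target signal (mean 20,000 a.u., slope e^0.2), half
anti-correlated on-target signal (mean 30,000 a.u.), multiplicative
Gaussian noise (mean 1, sd 0.2):

```r
library(toscore)
cell <- simulate_condition_cell(condition_config("negative", q = 0.2),
                                seed = 42, cell_id = "demo")
m <- tos_matrix(cell)
print(m, digits = 2)
#> <tos_matrix> demo: 9x9 grid
#>      f_t1
#> f_t2   0.9  0.8  0.7  0.6  0.5  0.4  0.3   0.2   0.1
#>   0.9 0.11 0.27 0.33 0.42 0.37 0.46 0.50  0.42  0.33
#>   0.8 0.31 0.29 0.36 0.36 0.35 0.38 0.36  0.25  0.17
#>   0.7 0.48 0.40 0.28 0.31 0.29 0.29 0.28  0.14  0.06
#>   0.6 0.61 0.51 0.38 0.28 0.27 0.28 0.25  0.17  0.08
#>   0.5 0.73 0.60 0.46 0.32 0.22 0.20 0.19  0.13  0.03
#>   0.4 0.71 0.67 0.50 0.33 0.23 0.15 0.12  0.07 -0.08
#>   0.3 0.72 0.72 0.56 0.37 0.24 0.15 0.07  0.06 -0.17
#>   0.2 0.83 0.79 0.64 0.46 0.33 0.18 0.05  0.01 -0.17
#>   0.1 0.67 0.75 0.56 0.50 0.40 0.17 0.02 -0.25 -0.33
#> tos_h = -0.333  tos_max = 0.833  tos_min = -0.333

classify_localization(m$tos_h)
#> [1] "anti-colocalization"

round(metric_panel(cell)[, c("tos_h", "pcc", "srcc", "m1diff", "m2diff")], 3)
#>    tos_h   pcc  srcc m1diff m2diff
#> 1 -0.333 0.244 0.285  0.073  0.093
```

Read the matrix like the heat maps it renders to: high selected fractions
(low thresholds, upper-left) include the correlated off-target signal and
show colocalization (TOS up to 0.83); the lowest fractions (highest
thresholds, lower-right) isolate the anti-correlated on-target signal and
TOS_h = −0.33 correctly reports anti-colocalization. The global metrics —
PCC 0.24, SRCC 0.29, M1diff/M2diff ≈ 0.1 — call the same cell weakly
*colocalized*: they cannot see the mixture.

## Pipeline / CLI

```r
run_pipeline("simulate-roc", "out/", seed = 1, n_slopes = 15, cells_per_slope = 10)
run_pipeline("analyze-images", "out/", channel1 = "ch1.tif", channel2 = "ch2.tif",
             mask_path = "mask.tif")   # or roi_path = "RoiSet.zip"
```

or from the shell via the installed wrapper
(`inst/scripts/toscore <mode> --seed 1 --out out/ ...`), with modes
`simulate-null`, `simulate-two-pop`, `simulate-roc`, `analyze-images`.
Outputs are per-cell metric CSVs, median-matrix CSVs, PNG heat maps
((0.1, 0.1) upper-right), ROC CSV/JSON summaries and a JSON run log.

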