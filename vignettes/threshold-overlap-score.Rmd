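---
title: "Threshold overlap score analysis: model, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold overlap score analysis: model, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toscore)
```

## The model

The unit of analysis is a cell: two pixel-aligned vectors of nonnegative
intensities, one per channel (`cell_pixels`). All thresholding is done on
*ranks*: a "selected fraction" `F` keeps the top `k = max(1, round(F·N))`
pixels by intensity (round half away from zero, capped at `N − 1`). Because
only ranks matter, every statistic in the TOS family is invariant under any
strictly increasing transform of either channel — bit depth, gain and
nonlinear detector response are irrelevant, and cells of different sizes
and brightnesses can be pooled.

For selections `sel1`, `sel2` at fractions `F_T1`, `F_T2`:

* observed overlap `AO1 = |sel1 ∩ sel2|/|sel1|`, `AO2 = |sel1 ∩ sel2|/|sel2|`;
* the uniform-independent null gives `E[AO1] = F_T2` and `E[AO2] = F_T1`,
  so the AO ratio `r = AO1/F_T2 = AO2/F_T1` equals 1 at chance overlap;
* analytic bounds `r_max = 1/max(F_T1, F_T2)` and
  `r_min = max(0, (F_T1 + F_T2 − 1)/(F_T1·F_T2))`;
* TOS maps `r` piecewise-linearly with fixed points
  `(r_min, −1), (1, 0), (r_max, +1)`.

The piecewise form is the unique linear rescaling consistent with those
three anchors; the published account states the anchors and linearity but
not the algebra, so the form is pinned down here by construction and
verified in the tests (`tos(r_min) = −1`, `tos(1) = 0`, `tos(r_max) = +1`
for all 81 grid pairs, and 0.9 lands nine tenths of the way from the null
to the maximum).

### Effective-fraction normalization inside the matrix

`tos_matrix()` normalizes by *effective* fractions `k/N` rather than the
requested grid values. With `k` pixels actually selected, every integer
overlap count then maps exactly into `[r_min, r_max]`: the bounds are
attainable, `AO1/f2 = AO2/f1` holds identically, and no clamping is needed
beyond float fuzz. The standalone `tos()` primitive accepts arbitrary
fractions and clamps excursions below `1e-8` (larger ones error). For the
default grid and cells of a few hundred pixels the difference between
nominal and effective fractions is at most `0.5/N`.

### Ties and degenerate channels

Ties at the selection boundary are broken by ascending pixel index after
descending intensity — deterministic across platforms — and the effective
fraction is recorded so tie inflation is visible. A channel with all
intensities equal still yields a selection (by index order) but flags the
result and raises a `toscore_degenerate_channel` warning; the score for
such a channel is not biologically meaningful.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| fraction grid | 0.9…0.1 step 0.1 | — | 81 combinations; fraction 1 excluded since total selection forces total overlap (TOS ≡ 0) |
| non-colocalization band | ±0.1 | TOS | avoids flip-flopping chance-level cells between "weak co-" and "weak anti-"; boundary closed into the band |
| `TOS_h` location | (0.1, 0.1) | fractions | the highest thresholds, where on-target signal is most separated from background/off-target |
| object size filter | 400–5000 | pixels | removes mistraced boundaries and merged objects before per-cell analysis |
| Mann–Whitney exact cutover | combined n ≤ 16 | — | exact enumeration below, tie-corrected normal approximation with 0.5 continuity correction above |

`tos_max`/`tos_min` are reported as grid extrema regardless of sign; the
interpretation rules ("maximum colocalization if > 0", "maximum
anti-colocalization if < 0") belong to reporting, not extraction.

## Comparison metrics

Pearson and Spearman (mid-rank) correlations error on zero-variance input
(`metric_panel()` converts that to `NA`). Manders `M1` is the summed
channel-1 intensity over pixels strictly exceeding **both** thresholds
divided by the sum over pixels exceeding its own threshold; the
chance-corrected `m1diff = M1 − f_above2` subtracts the fraction of pixels
above the *other* channel's threshold. Costes' automatic thresholds are
found by ordinary least squares of channel 2 on channel 1 (the regression
flavor is not specified in the source account; OLS matches the common
JACoP practice), then scanning candidate `t1` over the distinct channel-1
intensities from high to low with `t2` coupled along the line, choosing the
candidate minimizing the Pearson correlation of pixels strictly below both
thresholds (minimum-correlation variant, not first-non-positive). Ties keep
the highest threshold; candidates with fewer than 3 below-pixels or zero
variance are skipped; an unevaluable scan or constant channel returns a
`failed` flag rather than an error. When the fitted slope is positive the
below-sets are nested along the scan and an O(n log n) prefix-sum path is
used; both paths are checked against a literal brute-force scan.

## What the simulators emulate

* **Uniform null** (`simulate_uniform_cell`): two independent
  uniform channels — the world in which the AO ratio centers on 1.
* **Two-population mixtures** (`simulate_two_population_cell`): two
  equal subpopulations (300 pixels each) with additive uniform noise on
  0–10^4 a.u.; population 1 carries the correlation under study
  (shared deviate = positive, complementary = negative, independent =
  none), population 2 is always uncorrelated; one population's mean steps
  from 6.5×10^4 down to 2.5×10^4 a.u. in 40 equal increments. How noise
  and mean combine is not stated in the source account; additive
  combination is used. The signed "distance" is positive when population 1
  is the shifted one.
* **Condition populations** (`simulate_condition_cell`,
  `sweep_conditions`): 600 pixels per cell, half off-target (positively
  correlated line of slope θ = e^q, mean 20,000 a.u.), half on-target
  (mean 30,000 a.u.; positively correlated in condition-positive cells,
  mirrored about the mean in condition-negative ones), every value then
  multiplied by an independent Gaussian factor (mean 1, σ = 0.2) per
  channel and pixel, clamped at 0 (clamps are counted and warned; they are
  ~3×10⁻⁷ per value at these means). The default sweep is 141 slopes
  `q ∈ [−0.7, 0.7]` × 50 cells = 7050 cells per condition. The
  distribution of base intensities along the component lines is not
  printed in the source account; a uniform spread of ±5000 a.u. around
  each component mean was fixed a priori as a realistic cloud width and is
  not tuned. A `recenter_off` switch pivots the off-target line about its
  mean instead of scaling through the origin.

None of the simulators model spatial structure: pixels are exchangeable,
there is no point-spread-function autocorrelation, no segmentation error,
no bleed-through. A green simulation test therefore establishes the
rank/overlap arithmetic and the statistical machinery, not robustness to
optics; expected values are unaffected by PSF correlation but variances in
real images will be larger.

## Evaluation conventions

ROC curves slide a threshold from the highest histogram edge to the
lowest; "above" is strict. TPR/FPR are fractions of condition-positive /
-negative cells above the threshold, with implicit (0,0) and (1,1)
endpoints; AUC is the trapezoidal integral (the source account compares
curves visually; a scalar is needed for automated ordering claims).
Histogram edges cover [−1.2, 1.2] with Scott's-rule width
`3.49·σ·n^(−1/3)` for simulated data, or fixed 0.1 / 0.001 increments for
experimental-style data; a zero-spread sample falls back to a single bin.
Cells with undefined values (failed Costes thresholding) are excluded
per-metric, not per-cell, and exclusion counts are reported. Cohort
percentiles use linear interpolation between order statistics
(`quantile` type 7).

## Numerical and design choices

* Selection count rounding: half away from zero (`round(0.5·7) = 4`); the
  source account does not state its rounding rule.
* Overlapping ROIs rasterize last-drawn-wins; polygon containment is
  even-odd at pixel centers, 0-based row-major coordinates.
* Background exclusion keeps an object if its mean exceeds the unlabeled
  ("non-cell") mean in at least one channel.
* The TIFF codec is deliberately minimal (uncompressed grayscale baseline
  TIFF, 8/16-bit unsigned and 32-bit float, both byte orders on read):
  nothing in the supported R dependency set reads TIFF, and the pipeline
  needs nothing more. Compressed, multi-plane or RGB files error with the
  offending path.
* One global seed spawns per-cell substreams (`sample.int` of seeds), so
  sweeps are reproducible and insensitive to evaluation order.

## Known limitations (and the three deliberately red tests)

The piecewise rescale is *asymmetric about the null*: above `r = 1` scores
are divided by `r_max − 1`, below by `1 − r_min`, and these differ —
at (0.1, 0.1) by a factor of 9. Consequently, although `E[r] = 1` under
the uniform null, `E[TOS] ≠ 0`: exact hypergeometric enumeration gives
−0.14 at (0.1, 0.1) and (0.9, 0.9) and +0.14 at the mixed corners for
500-pixel cells. The *median* TOS per combination is ~0, and the
per-combination expectations cancel exactly over the grid (the bias matrix
is zero-sum), but three consequences are asserted red in
`test-acceptance.R` rather than papered over:

1. the per-combination **mean** over 200 uniform cells is not within
   ±0.05 everywhere (it converges to the ±0.14 bias, which a companion
   test verifies against the exact enumeration);
2. in the two-population design with both populations uncorrelated, the
   mean `TOS_h` is −0.136 at distance 0 (the same corner bias) and
   ≈ +0.11 at full separation (a co-occurrence effect: both channels' top
   decile concentrates in whichever subpopulation is brighter, doubling
   the observed-to-expected overlap), so "mean TOS_h within ±0.1 at all
   distances" fails at the ends;
3. in the condition-population benchmark, `TOS_h` narrowly but
   consistently out-classifies `TOS_min` (mean AUC 0.80 vs 0.77, 20/20
   seeded repetitions at 15 slopes × 10 cells); the expected ordering with
   `TOS_min` first does not reproduce under this generator, plausibly
   because the unprinted base-intensity spread differs. All other
   orderings — TOS family above PCC and SRCC, `M1diff`/`M2diff` near
   chance, `TOS_max` poor — reproduce in 20/20 repetitions.

Users comparing cohorts should therefore aggregate TOS matrices by
**median** (as `aggregate_cohort()` and the pipeline do) and treat small
mean TOS values at extreme fraction pairs as metric structure, not
biology. Out of scope by design: logarithmic rescaling, below-threshold /
band-pass selection variants, distance-based selected fractions, 3-D
voxels, more than two channels, and segmentation.
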