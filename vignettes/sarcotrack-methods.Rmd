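---
title: "Methods: sarcomere morphometry, turnover and screen quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sarcomere morphometry, turnover and screen quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcotrack)
```

This vignette describes the models and procedures the package implements,
the assumptions behind them, and the design decisions taken where the
underlying experimental conventions leave room for choice.

## The striation model

A phalloidin-stained myofibril profile is modelled as a periodic template:
at every period boundary a Gaussian Z-disc peak (amplitude `z_peak_level`,
full width at half maximum `z_disc_width`), over each thin-filament array a
plateau at `filament_level`, and centered mid-period an H-zone trough at
`h_zone_level` of width `h_zone_width`. The geometric identity

$$SL = 2\,TFL + HZ$$

holds exactly in every ground-truth record by construction (the constructor
accepts any two of the three lengths and derives the third). The template is
convolved with a 1-D Gaussian point-spread function (`psf_sigma`), sampled
at pixel centers (`pixel_size`, index 0 at the profile start), and Gaussian
noise is added. The template is periodic across the whole sampled window —
the margins contain the continuation of the fibril — so every recorded
Z-disc is an interior peak and peak localization is unbiased; a template
that fell to background at the ends would drag the outermost peaks inward by
a substantial fraction of a pixel.

Default geometry (`striation_truth()`): SL 3.36 µm, TFL 1.60 µm, HZ
0.16 µm, Z-disc FWHM 0.25 µm, pixel 0.05 µm — typical adult flight-muscle
values at high-magnification confocal sampling. The default `psf_sigma` is
one pixel (0.05 µm): sub-pixel recovery of all three lengths is guaranteed
only for `psf_sigma <= pixel_size`, because a wide PSF partially fills the
narrow H-zone trough and biases the 50% crossings outward. The generator
refuses `pixel_size >= h_zone_width` outright (the trough would be
unresolvable).

## Morphometry

Z-discs are detected on the Gaussian-smoothed profile (default sigma = one
pixel) as local maxima whose *topographic prominence* exceeds
`min_prominence` (default 20%) of the smoothed dynamic range; plain
height thresholds would fire on noise bumps riding the thin-filament
plateau, whereas the prominence of such bumps is only the noise amplitude.
Each peak is refined by parabolic interpolation through its three
neighbouring samples (offset clamped to half a pixel). M-lines are bright
peaks in the obscurin channel (detected identically) or dark mid-sarcomere
troughs in the phalloidin channel, where they are localized as the refined
minimum between each adjacent Z-disc pair — restricting the search to
Z-bounded intervals avoids spurious "troughs" in the background.

Thin-filament length follows the half-slope convention: within one
sarcomere, intensity is normalized between the H-zone minimum (searched in
the central half of the period) and the thin-filament plateau level, taken
as the median intensity over the 15–35% and 65–85% fractional spans of the
period — regions well clear of both the Z-disc tails and the H-zone for any
realistic geometry. The 50% crossings of the descending slopes are found by
linear interpolation; TFL is the mean crossing-to-nearer-Z distance over the
two sides (measured from the Z-disc *peak center*, which is sub-pixel
definable and symmetric, rather than an ill-defined peak edge), HZ the
distance between the crossings. When no interior trough deeper than 2% of
the plateau exists the sarcomere is flagged degenerate and reported as
HZ = 0, TFL = SL/2. Because the two crossings are measured independently,
the closure identity SL = 2·TFL + HZ is *not* enforced on measurements; it
is recovered within two pixels on synthetic data and serves as an internal
consistency check.

Group comparison uses the two-sided equal-variance Student's t-test by
default (Welch behind the `welch` flag), with the star convention
p < 0.05 / 0.005 / 0.0005. Percent changes are computed from unrounded
means and rounded only at report time.

## Pulse-chase turnover

The kinetic ground truth is deliberately minimal: baseline until `lag`,
linear rise to `peak` at `rise_end`, then single-exponential decay of the
excess over baseline with `decay_halflife` (or a plateau for a stable
cytoplasmic label, `decays = FALSE`). This is the simplest shape exhibiting
the qualitative features the assay resolves — delayed incorporation,
maximum after repression due to maturation lag, slow loss — and all
parameters are exposed, not hard-coded.

Onset detection declares the earliest timepoint whose mean exceeds the
first-timepoint baseline by a one-sided two-sample t-test at `alpha`
(default 0.05), *with every later pre-peak timepoint also significant*.
The sustained-rise requirement makes the call robust to a single noisy
timepoint; the cost is that onset can never be declared before the first
grid point after the true lag, so recovery is accurate to one sampling
interval. Baseline is the first-timepoint mean — the experimental
normalization is not fully specified, and t = 0 precedes induction, so it
is the natural reference. Half-life comes from least squares on
log(mean − baseline) over post-peak timepoints (at least three, and only
those above baseline); a non-negative slope yields no estimate. The
single-exponential assumption is explicit; a maturation-limited early chase
or a two-compartment pool would bias it.

## Comparative Ct

Ct values are generated under the doubling model — one cycle earlier per
two-fold more template, amplification efficiency fixed at 2.0 — with
Gaussian replicate noise on the cycle scale. Analysis averages replicates on
the Ct scale (the common convention; averaging folds instead would
Jensen-bias them upward), forms ΔCt against the reference gene within each
sample, and ΔΔCt against the genotype-matched day-0 calibrator, so each
arm's day-0 fold is exactly 1. Error propagation is worth keeping in mind:
with triplicates at 0.15-cycle noise the ΔΔCt standard deviation is
0.15·2/√3 ≈ 0.17 cycles, i.e. about 12% multiplicative error on the fold —
negligible in percent-knockdown terms for strong knockdowns (a 98% knockdown
is recovered within a fraction of a point) but worth several points for mild
ones; the tests assert exactly this scaling rather than a flat bound.

## Geotaxis scoring and severity classes

Each (vial, technical replicate) contributes the fraction of flies crossing
the scoring line; the timepoint score is the mean fraction, with the
standard error over vial means (vials are the independent unit; technical
replicates are repeated measurements of the same flies). Trajectories are
normalized to day 0 (scores above 1 are kept — improvement is information,
not an artifact) and a line whose day-0 score is 0 is flagged unusable.
"Complete loss of climbing ability" is formalized as *sustained* zero: the
earliest assay day with score 0 such that every later assayed day is also
0 — at 10 flies a single all-fail day is not rare, and the sustained rule
prevents it from being called a loss. Severity windows (≤ 9 Severe, 12–21
Intermediate, ≥ 24 Weak, never None) are exhaustive on the 3-day assay grid
(days 10–11 and 22–23 are never assayed); a day falling in a gap is treated
as an error rather than silently assigned.

## Enrichment ratios and the interaction network

The enrichment ratio is purely descriptive:
$(k_c/n_c)/(K/N)$ — the frequency of a term in a phenotypic class over its
frequency in the whole screened set. No significance machinery is attached,
matching the descriptive use of these ratios; genes without any annotation
still count in denominators (they were screened). The definition implies an
exact conservation law — when the classes partition the universe,
$\sum_c (n_c/N)\,r_{t,c} = 1$ for every term present in the set — which the
tests verify algebraically. The network is an undirected igraph with
severity and functional-group vertex attributes, self-loops retained
(self-interaction is biologically meaningful for multimerizing sarcomeric
proteins), duplicate edges collapsed by (endpoints, kind), and GraphML/TSV
round-trip serialization.

## What the generators do and do not emulate

The generators reproduce the *quantitative structure* of each data type:
striation periodicity with PSF blur and additive Gaussian noise, lag–rise–
decay kinetics, the Ct doubling model, binomial climbing outcomes, and
class-structured day-of-loss values. They do not attempt photorealistic
confocal simulation (no shot noise, no depth attenuation, no fibril
curvature or Z-disc waviness), diffusion of the label within the sarcomere,
qPCR efficiency drift, or behavioural correlations between flies in a vial.
Passing recovery tests therefore demonstrates that the measurement chain is
unbiased and correctly calibrated under the stated noise model — not that it
is robust to every artifact of real microscopy; the polyline-based profile
extraction in particular assumes the user (or the fixture geometry)
provides a line actually along a fibril.

## Numerical choices and degenerate inputs

Smoothing and the PSF use a discrete Gaussian kernel with reflect padding
(truncated at 4 sigma). Peak ties in turnover resolve to the earliest
timepoint. Sub-pixel offsets are clamped to ±0.5 px. Profiles must be
uniformly sampled within 1e-9 µm and contain at least 16 samples. Detection
failures (fewer than two landmarks) are no-measurement outcomes — empty or
short position vectors, `NULL` measurements — never errors; genuinely
invalid *inputs* (negative noise, unsorted positions, out-of-bounds ROIs,
successes exceeding flies) are errors. All generators take explicit seeds,
restore the caller's RNG state, and are bit-reproducible.

## Problem sizes used by the tests

The test suite and the reproduction script run at deliberately desk-scale
sizes chosen to make the assertions statistically meaningful while keeping
runs fast: 8-sarcomere profiles at 0.05 µm pixels (a few hundred
measurements per recovery check), 40 sarcomeres per timepoint for turnover
(the sampling depth the study's imaging used), 10 vials × 10 flies × 5
technical replicates for climbing simulations, triplicate Ct tables, and a
132–238-gene screen fixture. These match the study's stated experimental
scales rather than stress-testing asymptotics.

## Known limitations

Morphometry assumes reasonably straight, user-traced fibrils; there is no
automatic myofibril segmentation. The half-slope TFL convention inherits a
small outward bias in HZ when the PSF is comparable to the H-zone width.
Half-life estimation is single-exponential. Enrichment ratios carry no
uncertainty. The comparative-Ct analysis fixes efficiency at 2.0; no
standard-curve correction is available.
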