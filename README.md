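# sarcotrack

Quantification toolkit for studies of adult muscle maintenance in
*Drosophila* flight muscle. Adult flies progressively lose climbing ability,
and the sarcomeric cytoskeleton — the actin thin filaments, myosin thick
filaments and their anchoring structures — turns over throughout adult life;
when the synthesis of key structural proteins is knocked down in adults,
sarcomere geometry drifts even while gross muscle architecture looks intact.
Detecting those drifts requires sub-pixel morphometry of fluorescence
profiles, careful scoring of behavioural assays, and standard molecular
quantification, all of which this package implements end to end, together
with synthetic-data generators with known ground truth so every stage is
testable without any raw imaging data.

## What it computes

**Sarcomere morphometry** from 1-D fluorescence intensity profiles (or line
profiles extracted from 2-D images). In the phalloidin channel a sarcomere
reads as a bright Z-disc peak, a thin-filament plateau, and a dark central
H-zone trough. Z-discs are localized sub-pixel (Gaussian smoothing,
prominence-filtered local maxima, parabolic refinement); sarcomere length
(SL) is the Z-to-Z (or M-line-to-M-line) spacing; thin-filament length (TFL)
is measured from the Z-disc center to the point where the descending
intensity slope crosses 50% of the plateau-to-H-zone range, and H-zone width
(HZ) is the distance between the two crossings, so that ideally

    SL = 2 · TFL + HZ.

**Pulse-chase turnover**: per-timepoint Z-disc and sarcomere-body
intensities, the Z/body enrichment ratio, onset of incorporation (earliest
sustained significant rise over the t = 0 baseline), peak time, and the
post-peak half-life from a log-linear fit assuming single-exponential decay.

**Comparative-Ct qPCR**: replicates averaged on the Ct scale, then

    fold change = 2^-((Ct_target - Ct_ref) - (Ct_target,cal - Ct_ref,cal))

against a genotype-matched day-0 calibrator, with percent knockdown
`100 · (1 - fold)`.

**Negative-geotaxis screen scoring**: per-(vial, replicate) success
fractions, day-0-normalized trajectories, total percent decline, the day of
sustained complete loss of climbing, and severity classes (loss by day 9 =
Severe, days 12–21 = Intermediate, day 24 on = Weak, never = None).

**Screen summarization**: GO-term enrichment ratios (term frequency in a
phenotypic class over its frequency in the whole screened set) and a
severity-annotated gene-interaction network (igraph; GraphML/TSV export).

## Worked example

```r
library(sarcotrack)

truth <- striation_truth(thin_filament_length = 1.60, h_zone_width = 0.16)
prof  <- gen_striation_profile(truth, n_sarcomeres = 8,
                               noise_sd = 0.0475, seed = 1)
m <- measure_striation(prof)
g <- summarize_group(m$sl_um)
sprintf("SL: %.3f +/- %.3f um (n = %d sarcomeres)", g$mean, g$sd, g$n)
#> "SL: 3.354 +/- 0.020 um (n = 8 sarcomeres)"
```

The generator built a myofibril with a true period of 3.36 µm (2 × 1.60 +
0.16) and 5% noise; the measured mean of 3.354 µm recovers it within a
tenth of a pixel. Comparing a healthy geometry against a shortened one:

```r
day0 <- gen_striation_profile(striation_truth(sarcomere_length = 3.42,
                              h_zone_width = 0.16), 8, 0.0475, seed = 2)
day6 <- gen_striation_profile(striation_truth(sarcomere_length = 3.10,
                              h_zone_width = 0.16), 8, 0.0475, seed = 3)
a <- measure_striation(day0)$sl_um
b <- measure_striation(day6)$sl_um
compare_groups(a, b)
#> Two Sample t-test: t = 33.77, df = 14, p = 8.114e-15 (***)
sprintf("percent change: %.1f%%", percent_change(mean(a), mean(b)))
#> "percent change: -9.5%"
```

A 0.32 µm shortening is detected as a highly significant ~9.5% decrease —
the kind of drift the morphometry is built to resolve.

The full synthetic pipeline (morphometry, turnover, qPCR, screen scoring,
enrichment/network) runs from one config:

```r
run_pipeline(list(out_dir = "out", seed = 1))
```

or from the shell via `Rscript inst/cli/sarcotrack.R run --config cfg.yaml`.

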