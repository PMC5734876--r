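# SpineGlia

Quantification toolkit for structural and functional imaging of adult-born
granule cells (abGCs) in the mouse olfactory bulb, and of the microglia that
shape their synapses. The package re-implements, as tested and reusable R
functions, the bespoke measurement procedures used in studies of microglial
regulation of adult neurogenesis:

- **Spine morphometry** — normalized spine-head size in arbitrary units
  (AU): at the z-frame maximizing the head's integrated fluorescence, the
  background-subtracted head integral is divided by the mean of the
  brightest 10% of adjacent-shaft pixels, cancelling excitation and
  expression inhomogeneities. Spine density is heads per micrometre of
  traced dendrite, every head of a multi-headed protrusion counting once.
- **Spine dynamics** — matching of spines across two time-lapse imaging
  sessions by arc-length position (exact maximum-cardinality,
  minimum-distance matching within a 1 um radius), fate classification
  (stable / lost / gained), session-wise fate fractions
  `Nstable/(Nstable+Nlost)` etc., and the turnover rate
  `TOR = (Nlost + Ngained) / (N1 + N2)` per dendritic segment.
- **Calcium responses** — blank-referenced classification of odor-evoked
  transients: per-trial smoothing (span-5 moving average), deltaF/F against a
  4 s pre-stimulus baseline, `Z = (peak_odor - peak_blank) / sd_blank` over a
  stimulus + 3 s window, significance when at least two trials *and* the mean
  trace exceed Z = 2, plus blank-response / pre-stimulus-artifact QC and
  population and paired-session summaries.
- **Microglia contacts and counting** — per-plane overlap events between
  microglial-process and dendrite/spine masks (8-connected, merged across
  adjacent planes), shaft-contact density per mm, contacted-spine
  percentage, and areal densities of annotated cells restricted to the first
  8 um of each section.
- **Statistical battery** — pooled-variance two-sample t (with Bonferroni
  correction), two-sample Kolmogorov-Smirnov, split-plot repeated-measures
  ANOVA (group x fate-category interaction), and a Lilliefors normality test
  with a seeded Monte-Carlo null.
- **Synthetic data** — generators for each of the above with exact ground
  truth (paired spine cohorts with known survival/gain parameters, rendered
  dendrite stacks with known head intensities, trial-structured calcium
  traces with planted transients and a blank channel, two-channel contact
  scenes), so every stage is verifiable at desk scale.

## Worked example

Simulate a control-like cohort (17 segments of 33 spines, 70% survival,
Poisson gains at 0.557 per stable spine), classify fates and compute the
turnover rate:

```r
library(SpineGlia)
set.seed(42)
sim   <- simulateSpineSessions(nSegments = 17, spinesPerSegment = 33,
                               survivalProb = 0.70, gainRate = 0.557)
fates <- spineFateTable(sim$records)
fateFractions(fates)$summary
#>   category      mean        sem  n
#> 1   stable 0.7076649 0.02110061 17
#> 2     lost 0.2923351 0.02110061 17
#> 3   gained 0.3205752 0.01599235 17
tor <- turnoverRate(fates)
sprintf("mean TOR = %.3f +/- %.3f (n = %d segments)", tor$mean, tor$sem, tor$n)
#> "mean TOR = 0.311 +/- 0.012 (n = 17 segments)"
```

About 71% of spines came back stable and the mean turnover rate is 0.31 —
within sampling error of the generative regime (0.70 survival, expected TOR
near 0.33 at this gain rate).

Render a dendrite with spines of known intensity and measure their sizes:

```r
r  <- renderDendriteStack(5, spineIntensity = c(40, 120, 300, 750, 1500),
                          noiseSd = 1)
sz <- measureSpineHeadSizes(r$stack, r$annotations)
cbind(sz[, c("spine_id", "size_au", "frame")], true_au = r$truth$true_size_au)
#>   spine_id    size_au frame true_au
#> 1 spine001  0.7110008     2     0.8
#> 2 spine002  2.4059437     3     2.4
#> 3 spine003  5.7887833     4     6.0
#> 4 spine004 14.5318047     5    15.0
#> 5 spine005 28.6005600     6    30.0
```

Each spine is measured at the frame where its head is brightest; the small
systematic shortfall (a few percent) comes from the top-decile shaft
normalizer, whose brightest-pixel average is slightly inflated by noise (see
the methods vignette).

## Vignette

`vignettes/spineglia-methods.Rmd` documents the measurement model and its
assumptions, every tunable parameter with its default and rationale, what
the synthetic generators do and do not emulate, and known limitations.
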