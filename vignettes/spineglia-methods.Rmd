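---
title: "SpineGlia: measurement models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SpineGlia: measurement models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

SpineGlia quantifies structural and functional imaging of adult-born granule
cells (abGCs) in the mouse olfactory bulb: the size and density of their
dendritic spines, the day-to-day turnover of those spines, the odor-evoked
calcium responses of the mitral cells they inhibit, and the contacts between
microglial processes and their dendrites. This vignette documents the
measurement models, the tunable parameters and the choices made where the
underlying procedures left the design open.

## Spine-head size in arbitrary units

The measurement treats the integrated fluorescence of a spine head as a
proxy of its size and hence of synaptic strength. For a spine with manually
annotated head, adjacent-background and adjacent-shaft regions:

1. stacks are first denoised with a per-frame 3 x 3 pixel median filter
   (`medianFilterFrames()`; the window is clipped at frame borders);
2. the frame `z*` maximizing the summed head intensity is selected
   (`measureSpineHeadSize()`); ties break toward the lower z index so the
   result is deterministic;
3. the head pixels at `z*` are summed after subtracting the mean of the
   adjacent background at `z*`;
4. the result is divided by the mean of the brightest 10% of adjacent-shaft
   pixels at `z*`. The top-decile pixel count is `ceiling(0.1 * n)`, never
   fewer than one pixel (the rounding is otherwise unspecified).

The ratio is dimensionless ("AU") and exactly invariant to a global
intensity scale, which is the point: it removes differences in excitation
power and indicator expression between cells. The measurement is
deliberately two-dimensional — one frame, no volumetric integration.
Background-subtracted integrals that come out negative (very dim spines,
bright local background) are **kept and flagged** rather than clipped:
clipping would distort the lower tail of size distributions that downstream
KS tests compare, while the flag marks low-SNR annotations for review.

Two numerical caveats documented by the recovery tests: (a) a 3 x 3 median
filter erodes structures whose support is comparable to the window, so the
synthetic recovery experiments measure unfiltered renders (the filter is for
shot noise in real acquisitions, and its correctness is tested separately
against a brute-force oracle); (b) under noise, the brightest-decile shaft
average is an extreme-value statistic and sits slightly above the true shaft
level, biasing sizes low by a few percent at realistic noise — an inherent
property of the normalization rule, not of this implementation.

Spine density is heads per micrometre of traced dendrite
(`spineDensity()`), with every head of a multi-headed protrusion counting
as one spine regardless of neck origin. The denominator is the polyline arc
length of the dendrite trace scaled anisotropically by the lateral pixel
size and axial step (`DendriteTrace`, `traceLength()`); coordinates are
voxel indices. Absolute densities depend on those calibrations, which is why
the synthetic checks validate the computation contract rather than any
particular density value.

## Spine fates and turnover

Two-session records are matched per dendritic segment by arc-length
position (`matchSpines()`). Among all one-to-one matchings whose pairs lie
within `radius` (default 1.0 um, about the lateral resolution limit for
telling neighbouring spines apart), the implementation returns the one with
the maximum number of pairs and, among those, the smallest total distance.
Because positions live on a line and all pairs share one radius, an optimal
matching is non-crossing, so it is computed exactly by an O(n^2) dynamic
program over position-sorted records; position ties are ordered by spine id,
making the output deterministic. A greedy nearest-first assignment was
considered and rejected: it fails to reach the optimal pair count on a few
percent of dense instances (e.g. sessions {0, 1.0} vs {0.9, 1.9} at radius
1), which would inflate apparent turnover; the tests assert equality with a
brute-force enumeration of the optimum on small instances. A useful
consequence of the min-distance refinement is that records at identical
positions are always paired with each other, so on jitter-free data the
classifier recovers planted fates exactly.

Matched spines are stable, unmatched first-session spines lost, unmatched
second-session spines gained (`classifyFates()`). Per segment
(`fateFractions()`, `turnoverRate()`):

- stable fraction = Nstable / (Nstable + Nlost), lost likewise;
- gained fraction = Ngained / (Nstable + Ngained);
- TOR = (Nlost + Ngained) / (N1 + N2), bounded in [0, 1].

Group statistics are means with SEM **across segments** — the segment is
the unit of analysis, matching how such data are tested (t-tests with
n = segments). A pooled TOR over all spines is also reported for
transparency. Segments empty in both sessions are dropped with a message;
zero-denominator fractions become `NA` with a warning and leave the group
summary. When dynamics are scored from images rather than record tables, a
per-frame Gaussian blur (`gaussianBlurFrames()`, sigma default 1 px) is
provided as the standard pre-filter.

## Odor-response classification

Traces arrive as a `TrialSet`: raw fluorescence on a common grid of 164
samples at 7 Hz by default, with a blank (no-odor) channel. The trial
timing in the source protocols is stated inconsistently (a 22 s total, a
5 s / 2 s / 5 s = 14 s breakdown, and 164 points at 7 Hz which is about
23.4 s); rather than guess which governed the analysis, the package makes
every timing element explicit and configurable — sampling rate, onset
sample, stimulus duration — and defaults to 164 samples at 7 Hz with onset
at sample 70 (about 10 s of pre-stimulus), which is consistent with the
10 s pre-stimulus acquisition description. All outputs carry the timing
used.

Per trial, the pipeline is smooth, then normalize: a span-5 moving average
(`smoothTrace()`; near the ends the window shrinks symmetrically 1, 3, 5,
..., so length is preserved and a line passes through unchanged), then
deltaF/F with F0 the mean over the 4 s before onset (`dff()`). The response
statistic (`responseStatistic()`) uses a window of stimulus duration + 3 s
from onset: magnitude is the peak odor deltaF/F minus the peak blank
deltaF/F in the parallel window; noise is the sample standard deviation
(n - 1 denominator) of the blank in the window; Z is their ratio. A
cell-odor pair is significant when at least `minTrials = 2` single trials
*and* the pointwise-mean trace exceed the threshold, read as a strict
inequality Z > 2 (the literal "surpassed"; the boundary case Z = 2 is not
significant). The reported magnitude is the mean-trace magnitude — whether
population histograms used mean-trace or averaged per-trial magnitudes is
not specified in the source procedures; mean-trace was chosen and is flagged
here. Thresholds between 1.5 and 3 give qualitatively similar calls; the
tests verify the null call rate is monotone non-increasing over {1.5, 2, 3}.

QC (`qcFilter()`) discards cells whose blank trials exceed 0.3 deltaF/F in
the response window (the null reference is unusable) or that show absolute
pre-stimulus excursions above 0.5 deltaF/F on any trial (acquisition
artifacts); the first matching reason is recorded. Population summaries
(`populationSummary()`) report tuning breadth (odors with significant calls
per cell, 0..8) and the magnitudes of significant pairs;
`pairedResponses()` restricts to re-identified cells and to pairs
significant in at least one session, reporting the change in mean magnitude
as a percentage of the first session.

## Microglia contacts and cell counting

A putative contact is double staining — overlap between the
microglial-process mask and a target mask in a focal plane. The detector
(`detectContacts()`) takes binary masks (from annotation or synthetic
truth; a fixed-threshold binarizer `binarizeStack()` is provided for
rendered fixtures — no intensity thresholding is otherwise imposed). Per
z-plane, each 8-connected 2-D component of the overlap is one contact;
whether multi-plane overlaps were historically merged into single contacts
is unstated, so the package adopts and documents a merge rule: components
of the same target sharing at least one (y, x) voxel column between
consecutive planes are one event. Shaft-contact density is events per mm of
shaft length; the contacted-spine fraction counts distinct spines once no
matter how many events touch them. Areal cell densities (`cellDensity()`)
count annotated points within the first 8 um of the slice (boundary
inclusive at exactly 8 um), inside the region polygon, per mm^2; for
birthdating counts only co-labeled points are eligible.

## Statistical battery

`twoSampleT()` is the pooled-variance (Student) two-tailed test — chosen
over Welch because the classical degrees of freedom n1 + n2 - 2 are what
such analyses report — with Bonferroni adjustment `min(1, p * m)` for
planned-comparison families. `ksTwoSample()` is the standard two-sample KS
with asymptotic p. `mixedAnova()` fits the split-plot design (group between
subjects, fate category within) with `stats::aov` and an `Error(subject)`
stratum and reports the uncorrected interaction F — no sphericity
correction, matching the conventional uncorrected degrees of freedom; the
all-equal degenerate case is defined as F = 0. `lillieforsTest()` computes
the KS distance to a normal with estimated parameters and obtains p by
seeded Monte-Carlo (10,000 null draws by default) because closed forms for
the estimated-parameter null are approximate; the global RNG state is saved
and restored. Tests are run regardless of normality outcomes for larger
samples (n > 30), mirroring common practice; the package leaves that
decision to the caller.

## What the synthetic generators emulate

`simulateSpineSessions()` draws first-session positions uniformly on a
segment (default length gives 0.5 spines/um), survival as independent
Bernoulli(survivalProb), and gains as Poisson with mean gainRate x realized
stable count — Poisson because only group-level fractions are observable
and it is the maximum-entropy count model that keeps the expected TOR
analytically computable. Gained spines are placed at genuinely new sites:
candidates within `minSeparationUm` (default 1 um, the matching radius) of
any first-session position are rejected, because a new spine within the
resolution limit of an existing site cannot be distinguished from that
site's spine — a same-site loss-plus-gain would be scored stable by any
observer. Gains impose no exclusion on one another (two new spines may
crowd). This rule is always geometrically feasible and makes the planted
matching the unique optimum, so fate recovery is exact on jitter-free data.
Spines per segment is a fixed count (the reference cohorts all use a fixed
size); position jitter between sessions is not modelled.

`renderDendriteStack()` renders a two-pixel shaft (present in every frame),
3 x 3 spine heads confined to single frames with exactly known integrated
intensity, a uniform background, and additive Gaussian noise clamped at
zero. `simulateCalciumTrials()` uses a difference-of-exponentials transient
(rise 0.1 s, decay 1.5 s defaults, resembling GCaMP3 kinetics; the source
procedures specify none, and both are configurable) whose continuous-time
peak equals the requested deltaF/F amplitude, plus additive Gaussian noise
in deltaF/F units (default SD 0.05, a typical single-cell noise floor at
this magnification) — the simplest model sufficient to characterize the
classifier. `renderContactScene()` plants exact numbers of shaft and spine
contacts, with every second shaft contact spanning two focal planes to
exercise the merge rule, plus distractor processes.

None of the generators model a point-spread function (off by default, by
design), photobleaching, motion artifacts, or the correlated, signal-
dependent noise of real photomultipliers; real annotations are also
imperfect in ways synthetic truth is not. Passing recovery tests therefore
demonstrates that the *computations* implement their contracts and are
well-conditioned at realistic noise — not that the pipeline is robust to
every pathology of real acquisitions.

## Problem sizes used in the checks

The recovery benchmarks use 500 segments of 30 spines (about 15,000
first-session spines per regime), chosen so that the SEM of the mean
turnover rate is a few thousandths — comfortably inside the +/- 0.01
reporting tolerance; fate-classification exactness is checked on just over
10,000 spines; classifier operating characteristics use 150 planted-response
pairs and 1,000 null pairs; brute-force oracle comparisons run on instances
up to 16 pixels/points a side, where exhaustive enumeration is instant.

## Known limitations

- Spine matching is one-dimensional (arc length); real scoring also uses
  local image context.
- The AU size measure inherits the biases of its definition: single-frame
  2-D integration, and the extreme-value inflation of the top-decile shaft
  normalizer under noise.
- More than two imaging sessions, survival analysis over longer series, and
  automatic segmentation of raw histology are out of scope; the package
  consumes annotations or synthetic ground truth.
- The asymptotic KS p value is approximate for small samples with ties.
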