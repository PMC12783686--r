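---
title: "Models and methods behind condensquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind condensquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condensquant)
```

condensquant quantifies three assays used to characterize condensate-
forming adhesion proteins: in-vitro droplet formation, sub-micron cluster
detection along cell-cell contacts, and FRAP turnover of membrane
clusters. This vignette explains the models each stage assumes, the
tunable parameters and their defaults, what the synthetic generator does
and does not emulate, and the numerical choices made where the procedure
left room for interpretation.

## Droplet metrics

A field is a set of aligned per-channel intensity grids (`multichannel_field`).
Segmentation (`segment_droplets`) thresholds one channel (Otsu by default,
or an absolute value, or median + k·sd of the image), labels connected
components, and filters by area (default 10–10^4 px) and circularity
`4*pi*area / perimeter^2` (default minimum 0.8). The perimeter is measured
on the boundary polygon traced around each label rather than by counting
boundary pixels: pixel counting underestimates the perimeter of small
disks so badly that a radius-4 disk would score a circularity of ~1.5,
while the polygon measure gives 0.99 for that disk and ~0.21 for a 30x2
bar. Circularity is capped at 1.05 to absorb residual discretization.
Threshold and morphology defaults are declared package choices — the
assay names the criteria but not their values.

Per droplet, the partition ratio is `C_in / C_out`: mean intensity inside
the label over the mean bulk intensity, the bulk being every pixel outside
all droplet labels (one global bulk estimate per field; additional
channels' droplet sets can be unioned into the excluded mask so the bulk
is condensate-free everywhere). The condensed fraction is
`TC_in / TC_out`: summed intensity over droplet pixels over the summed
intensity of the whole field, hence in [0, 1], and its complement is the
bulk intensity share exactly. The co-condensed fraction evaluates a client
channel's condensed fraction over a *scaffold* channel's droplet mask,
quantifying recruitment of clients into scaffold condensates.

Bleedthrough between fluorophores inflates apparent enrichment, so
droplets are filtered per channel by a minimum partition ratio: 1.1 for
red/green-class channels and 1.35 for the blue class (where green-channel
spillover is strongest). Filtering removes droplets from a channel's
*statistics*, never from the geometry, because the scaffold mask must stay
intact for co-condensation; filters are applied before metric aggregation.
Condition tables are normalized per channel by dividing by the reference
condition's mean (`normalize_to_reference`), mapping the reference to 1.

## Junction cluster profiles

`extract_line_profile` samples an image along a polyline at 1-px arclength
steps; each sample averages `width` (default 4) bilinearly interpolated
pixels perpendicular to the local direction. Polylines are supplied as
CSV/JSON sidecars (0-based coordinates, origin top-left); the package
never auto-traces junctions.

`normalize_profile` divides by a baseline defined as the mean of the 20th
through 40th *smallest* samples (1-based ranks, inclusive — 21 values).
Ranks below 20 are skipped as dark shot-noise outliers; ranks up to 40
stay well below cluster peaks as long as clusters occupy a minority of the
trace, so the baseline tracks the unclustered membrane level (recovered
within 2% on synthetic traces where clusters cover <15% of samples).
Profiles shorter than 40 samples are refused. Ranks, not percentiles, were
chosen; division, not subtraction, so that the peak-amplitude thresholds
act on fold-over-baseline contrast. Normalization is therefore exactly
scale-invariant.

`detect_peaks` calls local maxima whose prominence is at least a set
fraction (default 0.5; 0.25 for brighter exogenous expression) of the
normalized profile's dynamic range. Prominence of a peak is its height
minus the higher of its two bases, each base being the minimum between
the peak and the nearest strictly-higher sample (profile edge if none) —
the standard definition used by common signal-processing libraries, fixed
here because the interactive tool this emulates does not publish its
formula. Plateau maxima report their center sample; peak positions are
integer sample indices with no sub-pixel refinement. A consequence of
range-relative prominence worth knowing: on a signal-free but noisy
profile the global noise maximum always has prominence equal to the range
and will be called; a truly flat profile yields zero peaks.

Per contact, the package reports peaks per µm; the overlap fraction (the
share of reference-channel peaks with a partner-channel peak within 3
samples, inclusive and symmetric, one-to-many matching — undefined and
reported as not-applicable when the reference channel has zero peaks);
and the squared Pearson correlation of the two normalized profiles. R² is
the square of Pearson r, so perfect anti-correlation also gives 1 — a
documented caveat of reporting R² alone. Cluster diameters come from a
bounded Levenberg–Marquardt fit of `offset + A*exp(-(x-mu)^2/(2*sigma^2))`
in a window around each peak, reported as `FWHM = 2*sqrt(2*ln 2)*sigma`
in nm. The estimator is exact (≤0.5% error) on noiseless Gaussians with
sigma ≥ 1.5 px and unbiased within 3% under 5% amplitude noise.

## FRAP kinetics

Traces come from CSV or from time-lapse z-stacks (`extract_frap_trace`:
maximum-intensity z-projection per frame, then ROI means; ROIs are
half-open rectangles in 0-based coordinates). `normalize_frap` applies
double normalization to background-subtracted intensities: the pre-bleach
mean maps to 1 and the immediate post-bleach value — the single first
frame after the bleach, since the bleach occupies one frame at the default
10-s interval — maps to 0. Gain and offset changes of the raw signal
cancel exactly. The reference (distal junction) trace is normalized to its
own pre-bleach mean only.

`fit_recovery` fits `Y(t) = Y0 + (F_mob - Y0)*(1 - exp(-t*ln2/tau_half))`
to the post-bleach samples by bounded nonlinear least squares
(Y0 in [-0.2, 0.5], F_mob in [0, 1.5], tau_half in (0, 10x duration];
starting values: first post-bleach sample, last-decile mean, and the time
at which the trace first crosses halfway between them). Although
normalization anchors the first post-bleach sample at 0, Y0 remains a free
parameter near 0 because the model includes it; this reconciles the
anchoring convention with the printed model. A fitted half-time at its
upper bound is flagged unreliable, and a perfectly flat post-bleach trace
short-circuits to the immobile solution `F_mob = Y0` (the exponential is
then unidentifiable). `"ensemble-mean"` mode (the default, matching how
replicate-averaged recovery curves are fitted) averages traces pointwise
before one fit; per-trace mode fits each separately. Ensemble fitting of
identical-truth traces has strictly lower parameter variance than
averaging per-trace fits, which the test suite verifies. No acquisition-
photobleaching correction is applied. `compare_to_reference` divides the
fitted mobile fraction by the time-averaged normalized reference level:
1 means recovery to the surrounding junction intensity.

## Synthetic data generator

The generator is first-class, tested code whose defaults define the study
conditions the analyses are validated under.

- **Droplet fields**: hard-edged disks (interior level overwrites an
  exterior level), mixed across channels by a bleedthrough matrix with
  unit diagonal, then additive Gaussian noise clipped at zero. Disks are
  hard-edged by default so interior/exterior means equal the truth levels
  exactly; a `blur_sd` argument adds soft edges when realism matters
  (1 px is a reasonable value at these pixel sizes). Pixel size defaults:
  120 nm/px for droplet fields, 100 nm/px for junction images (typical
  60x spinning-disk values; the source assay does not state them, so they
  are explicit stand-ins, always recorded in the truth object).
- **Junction profiles**: a positive baseline plus Gaussian clusters
  parameterized by FWHM (250–600 nm is the relevant cortical-cluster
  range), with a second channel carrying a Gaussian at each cluster whose
  co-occurrence flag is set, jittered with sd 1 px by default so the 3-px
  overlap window is meaningfully exercised.
- **FRAP traces**: pre-bleach frames at 1, post-bleach frames following
  the recovery model exactly, a constant reference level, Gaussian noise
  throughout. A duration under three half-lives warns.

What the generator does *not* emulate: Poisson photon statistics (noise is
additive Gaussian for analytic tractability), optical blur and the
point-spread function, droplet fusion or 3-D structure, uneven
illumination, or drift. Passing parameter-recovery tests therefore shows
the estimators are correct under the stated statistical model, not that
they are robust to every artifact of real microscopy.

Study-condition choices used by the validation suites, fixed up front: the
FRAP anchor simulates 200 traces at half-time 17 s (the free-membrane
kinetics), Y0 = 0.1, mobile fraction 0.7, 10-s sampling over 300 s, noise
sd 0.05; cluster-size anchors use noiseless profiles at 50 nm/px; the
overlap-recovery suite uses noiseless two-channel profiles with jitter
sd 1 px (because range-relative prominence always calls the global noise
maximum of a signal-free noisy channel, the no-signal case is represented
by the flat-profile guard instead). Problem sizes (200 traces, 200
profiles, fields of a few hundred pixels) keep the whole suite in seconds
while leaving Monte-Carlo error well inside the asserted tolerances.

## Workbench

Measurements live in tidy long tables (condition, replicate, image,
metric, value). `aggregate_replicates` builds the three-level "superplot"
summary — per-image points, per-replicate means, and a condition grand
mean whose sd is computed across replicate means, respecting the nesting
of pseudoreplicated images within independent experiments. Hypothesis
testing is deliberately left to standard routines (nested t-tests, ANOVA,
Kruskal–Wallis) applied to these aggregates. `summarize_contact_scores`
turns manually scored de-novo contact tables into per-condition clustering
and junction-formation fractions, their cross-tabulation, and onset-delay
summaries; contacts whose cortical enrichment never appeared within the
movie are right-censored — excluded from onset means, retained in the
fractions — and a condition with only censored contacts reports its onset
as not applicable.

`run_pipeline` validates a YAML/JSON/list config, dispatches to the
simulate/droplets/junction/frap/report stages, and writes CSV outputs
(header comment carrying a deterministic config hash) plus a JSON manifest
of inputs, parameters and seeds. Reruns with identical config and seed are
byte-identical. Conventions throughout: 0-based pixel coordinates, origin
top-left, half-open ROI rectangles, µm conversions always via an explicit
pixel size (a junction config without one is refused). TIFF fields are
written as 32-bit float pages scaled into [0, 1] with the scale recorded
in the JSON sidecar, since float TIFF pages carry values in that range.

## Known limitations

- Peak positions are integer pixels; overlap and density inherit that
  granularity.
- The amplitude criterion is prominence relative to dynamic range; an
  absolute fold-over-baseline criterion would behave differently on
  profiles with a single dominant cluster.
- R² conflates correlation and anti-correlation.
- The FRAP model is a single exponential; reaction–diffusion kinetics,
  two-component recovery and bleach-spot geometry corrections are out of
  scope.
- Droplet segmentation assumes roughly circular, non-touching droplets;
  merged droplets are not split.
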