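# condensquant

Quantification tools for three assays used to study proteins that form
biomolecular condensates and sub-micron membrane clusters — here motivated
by β-catenin, whose intrinsically disordered termini drive condensation and
clustering of the cadherin/catenin adhesion complex:

1. **In-vitro droplet assays.** Multi-channel fields of phase-separated
   droplets are segmented by intensity, size and circularity thresholds.
   Per droplet, the *partition ratio* C<sub>in</sub>/C<sub>out</sub>
   (mean intensity inside a droplet over the mean bulk intensity) measures
   enrichment in the condensed phase; per field, the *condensed fraction*
   TC<sub>in</sub>/TC<sub>out</sub> (total intensity inside droplets over
   the total field intensity) measures how much of the protein is
   condensed. Cross-channel bleedthrough is corrected by excluding, per
   channel, droplets with partition ratios below 1.1 (red/green channels)
   or 1.35 (blue channel), and a *co-condensed fraction* evaluates a client
   channel over a scaffold channel's droplet mask. Per-condition tables can
   be normalized channel-wise to a reference condition.
2. **Cluster detection along cell-cell contacts.** Intensity profiles are
   read along user-drawn polylines (4 px wide, bilinear interpolation),
   normalized to the mean of their 20th–40th lowest values, and clusters
   are called as local maxima whose prominence exceeds a set fraction
   (50% or 25%) of the profile's dynamic range. Outputs: peaks per µm,
   the fraction of reference-channel peaks with a partner-channel peak
   within 3 px, the squared Pearson correlation R² of paired profiles, and
   cluster diameters as Gaussian full widths at half maximum,
   FWHM = 2√(2 ln 2)·σ.
3. **FRAP recovery kinetics.** ROI traces are double-normalized
   (pre-bleach mean → 1, immediate post-bleach value → 0) and fitted with
   the single-exponential recovery model
   Y(t) = Y(0) + (F<sup>mob</sup> − Y(0))·(1 − e<sup>−t·ln2/τ½</sup>)
   to estimate the mobile fraction F<sup>mob</sup> and half-time τ½, with
   an optional comparison of the recovery plateau to a distal junction
   reference region.

A seeded synthetic-data generator (`droplet_truth()`/`gen_droplet_field()`,
`profile_truth()`/`gen_junction_profile()`,
`frap_truth()`/`gen_frap_trace()`) produces droplet fields, two-channel
junction profiles and FRAP traces with recorded ground truth, so every
stage is validated by parameter recovery without any experimental data. A
workbench layer adds replicate-aware ("superplot") aggregation, summaries
of manually scored de-novo junction formation, TIFF/CSV/JSON I/O, run
manifests and a CLI.

## Worked example

```r
library(condensquant)

# simulate a two-channel droplet field: interiors 10/6, exteriors 2/2
truth <- droplet_truth(centers = cbind(c(15, 40), c(15, 40)),
                       radii = c(6, 6),
                       interior = c(green = 10, red = 6),
                       exterior = c(green = 2, red = 2), seed = 2)
field <- gen_droplet_field(truth, dims = c(60, 60))
ds <- segment_droplets(field, "green", intensity_thresh = 6)
field_metrics(field, ds, channel_class = c(green = "green", red = "red"))
#> # A tibble: 2 × 6
#>   channel C_out n_droplets mean_partition_ratio condensed_fraction co_condensed_fraction
#>   <chr>   <dbl>      <int>                <dbl>              <dbl>                 <dbl>
#> 1 green       2          2                    5              0.251                 0.251
#> 2 red         2          2                    3              0.167                 0.167

# FRAP: fit the recovery model to an ensemble of simulated noisy traces
sims <- lapply(1:50, function(s) as_frap_normalized(gen_frap_trace(
  frap_truth(Y0 = 0.1, F_mob = 0.7, tau_half = 17, noise_sd = 0.05,
             seed = s))))
fit_recovery(sims, mode = "ensemble-mean")
#> <frap_fit> Y0 = 0.094, F_mob = 0.700, tau_half = 16.44 s
```

The partition ratios equal the generative interior/exterior ratios (10/2 =
5 and 6/2 = 3), the condensed fraction is the share of each channel's
total intensity inside the two disks, and the ensemble fit recovers the
simulated half-time of 17 s from 50 noisy traces.

The CLI mirrors the R API:

```sh
Rscript inst/cli/condensquant.R simulate --kind frap --seed 4 --out out/
Rscript inst/cli/condensquant.R frap --config frap.yaml
```

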