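# microtissue

Quantitative image analysis for de novo microtissues grown in 45° angular
scaffold clefts. Fibroblast microtissues in such clefts organize along a
steep spatial program: a myofibroblast-rich growth front (fibronectin,
tenascin-C, αSMA peaking in a 10–20 µm band facing the medium) and a
maturing collagen-rich core visible by second-harmonic generation (SHG).
This package implements the analysis pipeline for multi-channel micrographs
of these tissues, for researchers quantifying ECM organization, front
dynamics and marker gradients:

* **Fiber orientation** — per-pixel local orientation of the SHG collagen
  signal via second-order Gaussian-derivative (Kroon) operators:
  `Hxx = Hx·Hx`, `Hyy = Hy·Hy`, `Hxy = Hx·Hy` applied sequentially, Gaussian
  smoothing at σ = 4 px, and the half-angle arctangent
  `φ = ½·atan2(−2 I*xy, I*xx − I*yy) ∈ [−90°, 90°)`, with orientation
  histograms, a midline-symmetry score, and HSV renderings (hue = 2φ,
  saturation 1, value = brightness).
* **Cleft-aligned intensity profiles** — rotation to the bisector frame
  (tip left), symmetry-axis selection, 100-pixel band column averages,
  per-channel max normalization, growth-front detection at 25% of the
  cumulated signal maximum, and integrated intensities.
* **Growth kinetics** — tip-to-front distances along the bisector over days
  and an OLS growth rate (µm/day).
* **Visualization** — percentile contrast (0.05% pixel saturation) and
  split-LUT two-marker-set overlays.
* **Synthetic data** — fiber phantoms with exact orientation ground truth
  and multi-channel microtissue images with known front position and
  profiles, so every stage is validated against ground truth.

Tabular results are tibbles that pipe through dplyr, with `autoplot()`
methods and broom-style `tidy()`/`glance()` on fitted growth rates.

## Worked example

Simulate a microtissue grown 150 µm into a 45° cleft, extract its profiles,
detect the front, and map fiber orientation:

```r
library(microtissue)

spec <- microtissue_spec(growth_um = 150, seed = 42)
mt <- make_microtissue(spec)
mt
#> <microtissue> 256 x 320 px, growth 150.0 um, front at x = 190.0 px

prof <- extract_profiles(mt$image, mt$geometry)
front_position(prof)      # detected front (px); generator truth is 190
#> [1] 190
integrated_intensity(prof)
#> # A tibble: 4 × 2
#>   channel integrated
#>   <chr>        <dbl>
#> 1 Fn            24.5
#> 2 SHG           56.1
#> 3 TNC           23.5
#> 4 aSMA          22.9
autoplot(prof)            # normalized profiles vs distance to growth front

of <- orientation_field(mt$image, channel = "SHG")   # sigma = 4 px
h  <- orientation_histogram(of, bin_width = 2)
modal_angle(h); symmetry_score(h)
#> [1] 23.9
#> [1] 0.906
```

The detected front sits exactly on the generator's ground truth; the
integrated intensities are the per-channel sums of the raw band profiles
(arbitrary units); and the SHG orientation histogram of this intact
synthetic tissue is close to mirror-symmetric about the bisector
(score 0.906 of 1).

Growth kinetics on a simulated 9-day series at 60 µm/day with 5 µm
distance noise:

```r
gs  <- make_growth_series(60, 0:8, spec = microtissue_spec(width = 560, tip = c(30, 128)),
                          distance_noise_sd = 5, seed = 42)
fit <- growth_rate(measure_growth(gs), window = c(0, 8))
fit
#> <growth_fit> rate 60.50 um/day over days [0, 8] (n = 9)
tidy(fit)
#> # A tibble: 2 × 5
#>   term            estimate std.error statistic  p.value
#>   <chr>              <dbl>     <dbl>     <dbl>    <dbl>
#> 1 intercept_um       0.667     2.66      0.251 8.09e- 1
#> 2 rate_um_per_day   60.5       0.558   108.    1.51e-12
```

`run_pipeline(run_config(simulate = microtissue_spec(), seed = 1), out_dir = "out")`
runs every stage on one image and writes profile/histogram CSVs, the
orientation map (TIFF) and HSV/split-LUT renders (PNG), plus a JSON report
of all parameters and results. A thin command-line wrapper with
`simulate` / `orient` / `profile` / `kinetics` / `render` / `run`
subcommands lives at `inst/cli/microtissue.R`.

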