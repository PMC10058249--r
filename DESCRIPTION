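Package: microtissue
Title: Fiber Orientation Mapping and Growth-Front Profiling of Microtissues in Angular Clefts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis pipeline for de novo microtissues grown in angular
    scaffold clefts. Computes per-pixel collagen fiber orientation from
    second-harmonic-generation (SHG) images using second-order Gaussian-derivative
    (Kroon) operators and a half-angle arctangent, with orientation histograms,
    a midline-symmetry score, and HSV renderings. Extracts cleft-aligned
    multi-channel intensity profiles (100-pixel band column averages, per-channel
    max normalization), detects the growth front from a 25% cumulative-intensity
    threshold, measures tip-to-front growth distances over time and fits growth
    rates, and reproduces percentile contrast adjustment and split-LUT channel
    overlays. Includes a synthetic microtissue and fiber-phantom generator with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    graphics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
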