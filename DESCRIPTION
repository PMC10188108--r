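Package: zeitconflict
Title: Circadian Rhythm Analysis Under Conflicting Light and Temperature Cycles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for analysing circadian locomotor
    behavior and rhythmic gene expression in animals entrained by competing
    zeitgebers (light and temperature). Provides pose-track cleaning and bout
    detection, hourly activity binning and group profiles, Lomb-Scargle
    permutation tests (plain and replicate-aware), an empirical reference-
    waveform 24-h test, multi-harmonic period/phase estimation, an umbrella
    (Jonckheere-Terpstra) screen for asymmetric waveforms, cosinor fitting and
    between-group comparison of mesor/amplitude/acrophase, circular statistics
    (Rayleigh, bootstrapped Watson two-sample, Monte-Carlo homogeneity),
    zeitgeber phase attribution, half-period alignment, Morlet wavelet spectra
    with distance-based PCA clustering and multiscale-bootstrap AU support,
    TMM-normalised expression screening with condition-specific rhythm
    classification and phase-shift analysis, and sliding-window time-of-day
    enrichment scores. Includes synthetic-data generators with known ground
    truth for every input kind.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    stats,
    utils,
    generics,
    withr,
    nlme,
    emmeans,
    car,
    edgeR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ape,
    limma
Config/testthat/edition: 3
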