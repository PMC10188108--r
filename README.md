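# zeitconflict

Tools for analysing circadian behavior and rhythmic gene expression in
animals entrained by two competing zeitgebers — a light:dark cycle and a
gradually ramping temperature cycle that may be misaligned against it
("sensory conflict"). The package re-implements, as tested and reusable R
functions, the complete computational path from raw pose-estimation tracks
and RNA-seq count matrices to rhythm statistics, phase comparisons, cluster
support values and time-of-day enrichment scores, together with
synthetic-data generators that emulate both input kinds with known ground
truth.

## What it computes

**Behavior.** Pose tracks (frame time, x, y, tracking likelihood) are
cleaned by a likelihood filter (< 0.90 removed and interpolated) and a jump
filter (> 2 cm per frame), scored for movement bouts (speed ≥ 0.03 cm s⁻¹
sustained ≥ 3 s), binned into wall-clock hourly activity, normalised to each
animal's maximum hour, averaged per group and smoothed with a centered 4-h
moving average.

**Rhythm detection.** Lomb-Scargle periodograms with permutation nulls in a
20–28 h (circadian) or 10–14 h (circatidal) band, including a
replicate-aware variant that shuffles all replicate values jointly before
re-averaging; an empirical reference-waveform 24-h test (max Kendall tau
against cosines peaking at each hour, permutation-calibrated); multi-harmonic
least-squares period/phase estimation with BIC harmonic selection; and an
umbrella (Jonckheere–Terpstra) screen for asymmetric waveforms with 4-h
asymmetry steps, exact permutation-null calibration and familywise
correction over candidate shapes.

**Rhythm comparison.** Cosinor fits
`y = M + A·cos(2π(t − φ)/τ)` and joint two-group comparison with Wald tests
on mesor, amplitude and acrophase differences; circular summaries (mean
direction, resultant length `R`); Rayleigh, bootstrapped Watson two-sample
and Monte-Carlo homogeneity tests; attribution of individual phases to the
light-entrained (ZT18) versus temperature-entrained (ZT18 + offset) target;
and the half-period alignment procedure for short-period zeitgebers.

**Activity metrics.** Dark/light contrasts per animal and mixed-model
(random intercept + AR(1)) comparisons of the dark-minus-light effect across
groups; Kruskal–Wallis/Dunn/Levene comparisons of rhythm strength.

**Clustering.** Morlet continuous wavelet spectra (periods 2–36 h), a
unit-power-normalised wavelet distance, PCA embedding, complete-linkage
clustering and approximately unbiased (AU) cluster support from multiscale
bootstrap.

**Expression.** TMM normalisation to log2 CPM, per-condition umbrella
screens, classification into shared / condition-specific rhythmic genes with
the marginal-significance (p < 0.1) exclusion rule, per-gene phase shifts
relative to the light and temperature cycles with a temperature-tracking
flag (10–12 h shift against light, no shift against temperature), amplitude
comparisons, and sliding-window (4 h) Fisher-test enrichment scores averaged
over the three windows covering each hour.

## Worked example

```r
library(zeitconflict)
library(tibble)

# simulate two animals with a nocturnal peak at ZT18 and process the tracks
cfg <- behavior_sim_config(seed = 1, n_animals = 2, duration_h = 48,
                           dropout_prob = 0.02)
sim <- simulate_tracks(cfg)
tr  <- dplyr::filter(sim$tracks, animal_id == "animal_01")
attr(tr, "fps") <- 2; attr(tr, "zt_offset_h") <- 0
act <- tr |> clean_track() |> detect_movement() |> bin_hourly()

lsp_permutation_test(tibble(time_h = act$zt_h, value = act$norm_distance),
                     n_perm = 199, seed = 1)
#> # A tibble: 1 x 8
#>   method p_value p_adj statistic period_h phase_h amplitude n_perm
#>   <chr>    <dbl> <dbl>     <dbl>    <dbl>   <dbl>     <dbl>  <int>
#> 1 lsp      0.005    NA      5.33     21.7    17.4     0.141    199
```

The p-value 0.005 is the permutation floor at 199 shuffles — the rhythm is
unambiguous even for this single noisy animal — and the fitted acrophase
(17.4 h) sits near the planted ZT18 peak; with only 48 h of one animal's
bouts the peak-period estimate is coarse, which is exactly why group means
and longer recordings feed the period estimators. The same grammar runs the
expression side:

```r
es  <- simulate_expression(expression_sim_config(seed = 1, n_genes = 100,
                                                 rhythmic_fraction = 0.3))
em  <- normalize_counts(es$counts, es$design)
scr <- screen_rhythmicity(em, "Aligned")
table(scr$rhythmic)
#> FALSE  TRUE
#>    68    32
```

32 genes flagged at the calibrated familywise p < 0.01 against 30 planted
rhythmic genes (30 true positives plus 2 nulls at the threshold). Fitted objects follow broom conventions (`tidy()`,
`glance()`), result types have `autoplot()` methods, and every seeded stage
is byte-reproducible.

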