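---
title: "Models and methods for circadian analysis under conflicting zeitgebers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for circadian analysis under conflicting zeitgebers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the tunable parameters that matter, the
numerical conventions, the places where the design was genuinely open and
how we decided them, and the limits of what the synthetic-data tests
establish.

## The scientific setting

Many coastal invertebrates experience two daily environmental cycles at
once: light and temperature. When both cycles are aligned they reinforce a
single circadian program; when the temperature cycle is delayed against the
light cycle ("sensory conflict", up to a 12-h offset), behavior and the
rhythmic transcriptome can follow one cue, the other, or break down. The
package covers the full computational path used to ask such questions:
locomotor tracks → cleaned hourly activity → rhythm statistics and group
comparisons → spectral clustering of behavioral profiles, and count matrix →
normalised expression → per-condition rhythm screens → shared/specific
classification → phase-shift attribution → time-of-day enrichment.

Throughout, ZT0 denotes lights-on in regimes with a light cycle, and the
coldest point of the cycle in dark temperature-only regimes. Phases live on
a 24-h circle; signed phase differences are wrapped to (−12, 12].

## Track processing

Cleaning removes frames with tracking likelihood below 0.90 and frames with
implausible jumps (> 2 cm per frame), replacing them by linear
interpolation in x and y separately between the nearest surviving frames
(nearest-value extension at the edges). The jump rule is applied after the
likelihood rule and re-checked once; we do not iterate to a fixpoint, and
cleaning is idempotent. Movement bouts are maximal runs of frame speeds
≥ 0.03 cm s⁻¹ lasting ≥ 3 s (6 frames at 2 fps); shorter excursions are
treated as tracking noise. The threshold comparison carries a 10⁻⁹ cm s⁻¹
tolerance so that float noise from position reconstruction cannot flip a
frame sitting exactly on the threshold.

Hourly binning assigns each frame to its wall-clock hour, sums within-bout
displacement, and normalises each animal by its maximum hour so animals of
different sizes and overall activity are comparable. A fully inactive
animal would give 0/0; we define its normalised series as all zeros, flag
it, and exclude it from group means. Group profiles carry the mean, SEM and
a centered moving average over 4 hourly bins; for the even window we use
bins t−2 … t+1, a deterministic convention recorded in the output
attributes.

## Rhythm detection

**Lomb–Scargle.** The classical variance-normalised periodogram is computed
on a period grid (default 20–28 h; 10–14 h for circatidal screens).
Significance comes from shuffling values across time points; with `n_perm`
permutations the smallest attainable p is 1/(n_perm+1). For replicated
designs the observed statistic is the peak power of the per-timepoint mean
series and the null shuffles *all* individual replicate values jointly
before re-averaging, which preserves the replicate structure of the design;
with one replicate everywhere this reduces exactly to the plain test.
Power is scale-free, so permutation p-values are invariant to affine
transforms of the series.

**Empirical reference-waveform test.** A 24-h-specific test: the statistic
is the maximum Kendall tau between the series and reference cosines peaking
at each of 24 hourly phases, calibrated by permutation against the fixed
reference set. This reproduces the decision semantics of rank-based
empirical JTK approaches without their closed-form null; at desk scale the
permutation calibration is exact enough and carries no distributional
assumptions.

**Multi-harmonic curve fitting.** For each candidate period on a 0.02-h
grid we fit truncated Fourier models with 1…3 harmonics by least squares
and score them by BIC; the period minimising BIC wins (ties to the smaller
period), and phase/amplitude are read off a dense (0.01 h) resampling of
the fitted waveform. Selecting the harmonic count matters: forcing three
harmonics onto a pure cosine makes the extra terms fit noise and roughly
doubles the phase error at moderate signal-to-noise. A caveat worth
stating: with hourly data over 72 h at amplitude-to-noise 2, the median
period error of even an exact maximum-likelihood fit is ≈ 0.25 h — that is
the information content of such series (the single-tone Cramér–Rao bound
gives sd ≈ 0.37 h), not an implementation ceiling.

**Umbrella screen for asymmetric waveforms.** Expression waveforms are
often sawtooth-like, so the screen tests ordered ("umbrella") alternatives:
for each candidate shape — a peak time at an observed timepoint and a rise
length in 4-h increments — values pooled per mod-24 timepoint should
increase along the rising arm and decrease along the falling arm. Each arm
is scored by a Jonckheere–Terpstra pair-count statistic; the arms share the
peak group, and the falling arm excludes the trough so no comparison is
counted twice. Three null calibrations are implemented:

* *exact enumeration* of all value permutations when the pooled sample has
  ≤ 8 observations;
* a *normal approximation* whose null mean and variance are computed
  exactly under permutation of the pooled values — including ties and the
  covariance induced by the shared peak group (the naive sum of per-arm
  variances is badly anticonservative: we measured a false-positive rate of
  0.25 at a nominal 0.01 before fixing this);
* the default *rank-permutation table*: for tie-free data the statistic
  depends only on ranks, so the per-shape null distribution is a function
  of the design alone. It is simulated once (20,000 draws, fixed seed) and
  shared across every series measured on that design — e.g. all genes of a
  screen. The exact-moment normal approximation remains the automatic
  fallback for tied data. The table matters because the normal
  approximation, even with exact moments, overstates far-tail p-values by
  almost a factor of two at the multiplicity-adjusted thresholds the screen
  uses, which costs real sensitivity.

The reported raw p is the minimum over shapes. For the familywise
correction we read the exact single-step min-p (Westfall–Young) adjustment
off the same permutation table; this is the quantity the Bonferroni factor
approximates, computed without its conservatism for correlated shapes. The
shape-count Bonferroni bound is still reported by the expression screen
(below) because one downstream rule depends on its conservative behavior.

## Rhythm comparison

The cosinor model `y = M + β₁cos(ωt) + β₂sin(ωt)` is linear at fixed
period; amplitude `A = √(β₁²+β₂²)` and acrophase `φ = atan2(β₂,β₁)/ω` are
derived quantities with delta-method standard errors. The two-group
comparison fits a joint model with group interactions on the cosine terms
and Wald-tests the differences in mesor, amplitude and (wrapped) acrophase;
this linearised route has closed-form covariance and matches the decision
behavior of published nonlinear cosinor-comparison tools. A constant
series gives `A = 0` with the acrophase reported as 0 and flagged
undefined.

Circular statistics work internally in radians and expose hours. The
Rayleigh test uses `Z = nR̄²` with Zar's finite-sample series correction
and switches to a 10⁵-draw Monte-Carlo null below n = 10 (at n = 10 the
two agree to better than 0.005). Watson's two-sample U² is calibrated by
pooled-resampling bootstrap (9999 draws by default); identical samples give
U² = 0 and p = 1. The circular homogeneity test compares the samples'
first *and* second trigonometric moment vectors with a Monte-Carlo
permutation null (10,000 replications by default); the second moment is
essential for antipodally symmetric (bimodal) phase distributions, whose
first resultant vanishes and would otherwise make rotations invisible.

Phase attribution compares each individual's phase with the expected
light-entrained phase (ZT18, the activity peak under light entrainment) and
the expected temperature-entrained phase (ZT18 + offset), using circular
distances and a paired Wilcoxon signed-rank test (exact for n ≤ 25). The
half-period alignment procedure assigns each animal to the 12-h window
holding more of its activity, circularly shifts the second group by 12 h,
and re-tests the aligned mean; ties go deterministically to the first
window and are flagged. The procedure is idempotent and cannot manufacture
24-h power from purely 12-h inputs.

## Activity metrics

Dark/light contrasts are computed on un-normalised activity (percent time
active, distance per hour), with hour membership decided by the bin's start
hour. Group comparisons fit `activity ~ phase × group` with a random
intercept per animal and AR(1) residual correlation within animal (hourly
observations are strongly autocorrelated); the reported contrast is the
group difference of the dark-minus-light effect, with BH-adjusted pairwise
comparisons and a Welch fallback (with a warning) if the mixed model fails.
Rhythm-strength distributions are compared by Kruskal–Wallis with Dunn's
pairwise z-tests (BH-adjusted) and Levene's median-centered variance test.

## Wavelet clustering

Each smoothed profile is decomposed with a Morlet continuous wavelet
transform (ω₀ = 6, FFT implementation with zero padding) on a log-spaced
period grid from 2 to 36 h. The dissimilarity between two series is the
Frobenius distance between their unit-power-normalised *complex* transforms.
This was a genuinely open design point: the obvious alternative — distance
between |W|² power maps — is blind to a 12-h phase inversion of a
stationary rhythm, because the modulus of the transform of a time-shifted
stationary signal is just the time-shifted (and for band power, nearly
constant) modulus; under it, antiphase groups are inseparable and the
package's own recovery tests fail by construction. The complex-transform
metric keeps timing information, matches the behavior of the upstream
clustering routines used in this field (which operate on the wavelet array,
not the power), and reduces to spectral distance when phases agree. The
power-based metric remains available (`on = "power"`), and the metric used
is recorded on the distance matrix.

The distance matrix is embedded by PCA (rows as features, centered,
unscaled; all components with eigenvalue > 10⁻¹⁰ kept — the number of
informative components is data-dependent and the paper trail gives no
fixed count), clustered by complete linkage, and annotated with multiscale
bootstrap support: feature columns are resampled at relative sizes
0.5…1.4, 1000 times each; per node the signed-root model
`z(r) = v√r + c/√r` is fitted to Φ⁻¹(1 − BP(r)) by weighted least squares
and AU = 1 − Φ(v − c). Nodes recovered always (never) get AU 1 (0) without
fitting; cluster identity under resampling means the same leaf set.

## Expression pipeline

Counts are TMM-normalised (edgeR's trimmed-mean-of-M implementation: 30%
trim on M, 5% on A, precision weights, 75th-percentile reference) and
expressed as log2(CPM + 0.5) against effective library sizes; a gene is
kept when CPM > 1 in at least 3 samples of some condition. Note that with
non-unit TMM factors a column of pre-log CPM sums to 10⁶/f rather than
10⁶ — that is the point of the correction, not a defect.

The per-condition screen folds the two sampled 24-h cycles (times mod 24),
treating the second cycle as replication — standard for 48-h single-period
designs — and runs the umbrella screen per gene, sharing one rank-null
table across all genes. Two corrected p-values are reported. The
*calibrated* familywise p (`p_fw`) drives the `rhythmic` flag at 0.01: it
is exactly uniform under the null, so the flag's error rates are
interpretable. The *conservative* shape-Bonferroni p (`p_adj`) exists for
the classification step: the rule "exclude genes marginally significant
(p < 0.1) in the other condition" was designed around the conservative
corrected p-values of the published screening tools, for which the null
exclusion rate is a few percent. Applying it to an exactly uniform p would
discard 10% of genuinely condition-specific genes by construction and
systematically bias the class counts; using the conservative bound for the
exclusion (and only there) preserves the rule's intended semantics. Both
columns are plain data; users who prefer a single convention can threshold
either.

Classification: `shared` = rhythmic in both conditions; condition-specific
= rhythmic in one, not even marginally significant in the other;
`indeterminate` = rhythmic in one, marginal in the other; `arrhythmic`
otherwise. The classes partition the gene universe. Phase shifts for
shared genes come from the joint cosinor comparison between conditions;
`Δφ_temp = wrap(Δφ_light − offset)` with offset 12 h for the
sensory-conflict design, and a gene is `temperature_tracking` when it
shifts 10–12 h against the light cycle (significant at 0.01) with no
significant residual shift against the temperature cycle. Amplitude
comparisons use paired Wilcoxon tests on per-gene cosinor amplitudes (log2
scale) for shared genes and unpaired tests for specific sets. Phases
feeding distribution tests and enrichment come from the cosinor fits; the
umbrella peak estimate is reported alongside.

## Sliding-window enrichment

For each 4-h window start (0…23, windows half-open `[start, start+4)` on
the phase circle) every functional term with ≥ 5 genes is tested one-sided
for over-representation of in-window genes by Fisher's exact test, with BH
adjustment across terms within the window (not across windows — each
window's adjusted p stands alone). The hourly score averages
−log10(adjusted p) over the three windows strictly containing the hour in
their interior — starts t−3, t−2, t−1 — and an hour is enriched when the
score exceeds −log10(0.05). Window membership at the boundary (a phase of
exactly 4.0 is *not* in `[0,4)`) and the three-window convention follow the
worked arithmetic that defines the score. Peaks of circularly contiguous
enriched runs take the earliest hour on ties.

## Synthetic data: what it emulates and what it does not

The behavior generator produces bout-structured nocturnal locomotion: bout
onsets follow an inhomogeneous Poisson process with rate
λ(t) = λ₀(1 + m·cos(2π(t − φ)/24)) (thinning algorithm), exponential bout
durations (mean 30 s), within-bout frame steps of at least the configured
speed with a slowly wandering heading, reflection into a square arena,
tracking dropouts with likelihood drawn below 0.90, and jump artifacts
displacing the recorded position by > 2 cm. Defaults emulate the study
conditions the pipeline targets: groups of 24 animals, 3-day recordings at
2 fps, peak activity at ZT18, and a 3.5-cm arena (a well of a 6-well
plate). Arrhythmic animals get the flat rate λ₀.

The expression generator draws negative-binomial counts with mean
μ_g(t) = exp(m_g + a_g·cos(2π(t − φ_g)/24)) and per-sample library scalers;
defaults follow the sequencing design (13 time points every 4 h over 48 h,
3 replicates, two conditions). Rhythmic genes draw phases from a von Mises
law; a configurable fraction of shared genes carries a +12-h phase in the
second condition, and a configurable fraction is rhythmic in only one
condition (needed to plant classification structure). Amplitudes default
to a_g ∈ [ln2/2, ln2] (2- to 4-fold peak-to-trough). The noise-free mean
matrix is returned alongside the counts so parameter-recovery checks have
an exact reference. One practical caution the generator exposed: if *all*
genes are rhythmic with concentrated phases, library totals oscillate and
CPM normalisation subtracts that common mode, biasing phases — a real
compositional effect of globally rhythmic transcriptomes, avoided in the
calibration runs by spreading phases around the clock.

Simulation-based tests therefore establish calibration and recovery under
bout-structured, stationary, NB-distributed conditions with known truth.
They do not establish robustness to non-stationary baselines, arena edge
preferences, tracking identity swaps, batch effects, or transcriptome-wide
compositional rhythms; those require real data.

## Problem sizes and reproducibility

Study-scale problem sizes used by the test-suite and the acceptance script
were chosen to be informative while remaining desk-computable: 500 null
series for type-I calibration (199 permutations each), 100 replicates for
phase/period recovery, 200-gene matrices (several, pooled) for screen and
classification operating characteristics, 100 seeds for cluster-class
recovery, 1000 bootstrap replicates per scale for AU support, and 10⁵
draws for Monte-Carlo reference nulls. Every stochastic stage takes an
explicit seed, draws from its own seeded stream, restores the caller's RNG
state, and writes byte-identical output on rerun.
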