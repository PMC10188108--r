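#' TMM-normalise a count matrix to log2 counts per million
#'
#' Filters low-expressed genes (kept when CPM > 1 in at least
#' `min_samples` samples within some condition), computes trimmed-mean-of-M
#' scale factors (30% trim on M, 5% on A, precision weights; the reference
#' library is the one whose 75th count percentile is closest to the mean of
#' those percentiles), and returns \eqn{\log_2(\mathrm{CPM} + 0.5)} against
#' the TMM-effective library sizes. Columns of the pre-log CPM matrix sum to
#' \eqn{10^6 / f_j} for a library with TMM factor \eqn{f_j} (exactly
#' \eqn{10^6} when all factors are 1).
#'
#' @param counts Non-negative integer matrix, genes x samples, with row and
#'   column names.
#' @param design Sample table with `sample_id` matching the columns plus at
#'   least `condition`, `time_h` (or `zt_h`) and `replicate`.
#' @param filter Apply the low-count filter (default TRUE).
#' @param min_samples Minimum samples above CPM 1 within a condition.
#' @return An object of class `expression_matrix`: list with `values`
#'   (log2-CPM matrix), `design`, `norm_factors`, `kept_genes`.
#' @export
normalize_counts <- function(counts, design, filter = TRUE, min_samples = 3) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must be non-negative integers.")
  }
  if (any(colSums(counts) == 0)) abort("zero-count library.")
  stopifnot("sample_id" %in% names(design),
            all(colnames(counts) == design$sample_id))
  if (filter) {
    cpm0 <- sweep(counts, 2, colSums(counts), `/`) * 1e6
    keep <- vapply(seq_len(nrow(counts)), function(g) {
      any(tapply(cpm0[g, ] > 1, design$condition, sum) >= min_samples)
    }, logical(1))
    counts <- counts[keep, , drop = FALSE]
  } else {
    keep <- rep(TRUE, nrow(counts))
  }
  dge <- edgeR::calcNormFactors(edgeR::DGEList(counts), method = "TMM")
  eff_lib <- dge$samples$lib.size * dge$samples$norm.factors
  cpm <- sweep(counts, 2, eff_lib, `/`) * 1e6
  structure(
    list(values = log2(cpm + 0.5), design = as_tibble(design),
         norm_factors = setNames(dge$samples$norm.factors, colnames(counts)),
         kept_genes = rownames(counts)),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("Normalised expression matrix: %d genes x %d samples (log2 CPM)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

em_condition_series <- function(em, condition, gene) {
  sel <- em$design$condition == condition
  tt <- em$design$time_h %||% em$design$zt_h
  tibble(time_h = tt[sel], value = em$values[gene, sel])
}

#' Screen every gene of one condition for 24-h rhythmicity
#'
#' Runs the umbrella screen ([umbrella_rhythm_test()]) on each gene's
#' log2-CPM series within one condition, folding the two sampled cycles onto
#' a single 24-h period so the second cycle acts as replication. Two
#' corrected p-values are reported per gene: `p_fw`, the exact familywise
#' (min-p) corrected p from the shared permutation table, and `p_adj`, the
#' Bonferroni bound over candidate shapes that the published screening tools
#' report. The `rhythmic` flag uses the calibrated `p_fw` at `p_rhythmic`;
#' the conservative `p_adj` is the right quantity for "not even marginally
#' significant" exclusion rules (see [classify_genes()]).
#'
#' @param em An `expression_matrix` from [normalize_counts()].
#' @param condition Condition label to screen.
#' @param p_rhythmic Rhythmicity threshold on `p_fw` (default 0.01).
#' @param period,asym_step_h Passed to [umbrella_rhythm_test()].
#' @return Tibble: `gene_id`, `p_raw`, `p_fw`, `p_adj`, `statistic`,
#'   `phase_h`, `amplitude`, `rhythmic`.
#' @export
screen_rhythmicity <- function(em, condition, p_rhythmic = 0.01, period = 24,
                               asym_step_h = 4) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!all(c("condition", "replicate") %in% names(em$design)) ||
      is.null(em$design$time_h %||% em$design$zt_h)) {
    abort("design must provide condition, time and replicate fields.")
  }
  sel <- em$design$condition == condition
  if (sum(sel) < 12) abort("need at least 12 samples in the condition.")
  tt <- (em$design$time_h %||% em$design$zt_h)[sel]
  res <- purrr::map_dfr(rownames(em$values), function(g) {
    r <- umbrella_rhythm_test(tibble(time_h = tt, value = em$values[g, sel]),
                              period = period, asym_step_h = asym_step_h)
    tibble(gene_id = g, p_raw = r$p_value, p_fw = r$p_adj,
           p_adj = min(1, r$p_value * (attr(r, "n_shapes") %||% 1)),
           statistic = r$statistic, phase_h = r$phase_h,
           amplitude = r$amplitude)
  })
  res$rhythmic <- res$p_fw < p_rhythmic
  res
}

#' Classify genes as shared, condition-specific or arrhythmic
#'
#' A gene is `shared` when rhythmic (calibrated familywise p < `p_rhythmic`)
#' in both conditions; condition-specific when rhythmic in one condition and
#' not even marginally significant in the other (conservative
#' shape-Bonferroni p >= `p_exclude`, matching the published analysis'
#' exclusion rule); genes rhythmic in one condition but marginal in the
#' other are `indeterminate`; the rest are `arrhythmic`. The classes
#' partition the gene universe.
#'
#' The rhythmicity test uses the `p_fw` column when present (falling back
#' to `p_adj`); the exclusion test uses `p_adj`.
#'
#' @param results_a,results_b Screens from [screen_rhythmicity()] for the
#'   two conditions (same gene universe).
#' @param p_rhythmic Rhythmicity threshold (default 0.01).
#' @param p_exclude Marginal-significance exclusion threshold (default 0.1).
#' @return Tibble: `gene_id`, `p_a`, `p_b` (rhythmicity p's),
#'   `class` with levels `shared`, `align_specific`, `sc_specific`,
#'   `indeterminate`, `arrhythmic`.
#' @export
classify_genes <- function(results_a, results_b, p_rhythmic = 0.01,
                           p_exclude = 0.1) {
  stopifnot(setequal(results_a$gene_id, results_b$gene_id))
  pick <- function(res) {
    tibble(gene_id = res$gene_id,
           p = if ("p_fw" %in% names(res)) res$p_fw else res$p_adj,
           p_marg = res$p_adj)
  }
  a <- pick(results_a); b <- pick(results_b)
  d <- left_join(a |> select("gene_id", p_a = "p", pm_a = "p_marg"),
                 b |> select("gene_id", p_b = "p", pm_b = "p_marg"),
                 by = "gene_id")
  d |>
    mutate(class = dplyr::case_when(
      .data$p_a < p_rhythmic & .data$p_b < p_rhythmic ~ "shared",
      .data$p_a < p_rhythmic & .data$pm_b >= p_exclude ~ "align_specific",
      .data$p_b < p_rhythmic & .data$pm_a >= p_exclude ~ "sc_specific",
      .data$p_a < p_rhythmic | .data$p_b < p_rhythmic ~ "indeterminate",
      TRUE ~ "arrhythmic"
    )) |>
    select("gene_id", "p_a", "p_b", "class")
}

#' Per-gene phase shifts between conditions, relative to light and temperature
#'
#' For genes rhythmic in both conditions, fits the joint cosinor comparison
#' between conditions. The phase shift on the lights-on clock
#' (`delta_phase_light_h`) is the condition-B minus condition-A acrophase
#' difference wrapped to (-12, 12\]; the shift relative to the temperature
#' cycle subtracts the zeitgeber offset (`offset_h`, 12 for the sensory-
#' conflict design). A gene is flagged `temperature_tracking` when it shifts
#' by 10-12 h against the light cycle (significant at `p_shift`) but shows
#' no significant shift against the temperature cycle.
#'
#' @param em An `expression_matrix` containing both conditions.
#' @param genes Genes to analyse (must be shared-rhythmic if
#'   `classification` is given).
#' @param classification Optional output of [classify_genes()]; when
#'   supplied, requesting a non-shared gene is an error.
#' @param offset_h Temperature-cycle delay relative to light, hours.
#' @param p_shift Significance threshold for the shift tests (default 0.01).
#' @param period Rhythm period, hours.
#' @return Tibble: `gene_id`, `delta_phase_light_h`, `delta_phase_temp_h`,
#'   `p_phase_light`, `p_phase_temp`, `amplitude_a`, `amplitude_b`,
#'   `phase_a`, `phase_b`, `temperature_tracking`.
#' @export
phase_shift_analysis <- function(em, genes, classification = NULL,
                                 offset_h = 12, p_shift = 0.01, period = 24) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!is.null(classification)) {
    cls <- classification$class[match(genes, classification$gene_id)]
    if (any(cls != "shared")) {
      abort("phase-shift analysis is defined for shared rhythmic genes only.")
    }
  }
  conds <- unique(em$design$condition)
  stopifnot(length(conds) == 2)
  tt <- em$design$time_h %||% em$design$zt_h
  purrr::map_dfr(genes, function(g) {
    d <- tibble(time_h = tt, value = em$values[g, ],
                group = factor(em$design$condition, levels = conds))
    cc <- cosinor_group_comparison(d, period = period)
    dphi_l <- cc$delta_phase_h
    dphi_t <- wrap_signed(dphi_l - offset_h, period)
    p_t <- if (cc$phase_defined && cc$se_phase > 0) {
      2 * pnorm(-abs(dphi_t / cc$se_phase))
    } else NA_real_
    tibble(gene_id = g,
           delta_phase_light_h = dphi_l,
           delta_phase_temp_h = dphi_t,
           p_phase_light = cc$p_phase,
           p_phase_temp = p_t,
           amplitude_a = cc$amplitude[1], amplitude_b = cc$amplitude[2],
           phase_a = cc$acrophase_h[1], phase_b = cc$acrophase_h[2],
           temperature_tracking =
             !is.na(cc$p_phase) & abs(dphi_l) >= 10 & abs(dphi_l) <= 12 &
             cc$p_phase < p_shift & !is.na(p_t) & p_t >= p_shift)
  })
}

#' Compare rhythm amplitudes (or expression levels) between conditions
#'
#' For shared rhythmic genes: paired Wilcoxon signed-rank test on per-gene
#' amplitudes in the two conditions, with the median percent change. For
#' condition-specific gene sets: unpaired Wilcoxon rank-sum test on the
#' supplied per-gene values (e.g. mean expression).
#'
#' @param data For `type = "paired"`: columns `amplitude_a`, `amplitude_b`.
#'   For `type = "unpaired"`: columns `value`, `set` (two levels).
#' @param type `"paired"` or `"unpaired"`.
#' @return One-row tibble: `p_value`, `median_pct_change` (paired only),
#'   `n` (or `n1`/`n2`).
#' @export
compare_amplitudes <- function(data, type = c("paired", "unpaired")) {
  type <- match.arg(type)
  if (type == "paired") {
    stopifnot(all(c("amplitude_a", "amplitude_b") %in% names(data)))
    if (nrow(data) < 2) abort("need at least 2 genes for a paired comparison.")
    wt <- suppressWarnings(wilcox.test(data$amplitude_b, data$amplitude_a,
                                       paired = TRUE))
    tibble(p_value = wt$p.value,
           median_pct_change =
             100 * median((data$amplitude_b - data$amplitude_a) /
                            data$amplitude_a),
           n = nrow(data))
  } else {
    stopifnot(all(c("value", "set") %in% names(data)))
    sets <- unique(data$set)
    if (length(sets) != 2) abort("`set` must have exactly two levels.")
    a <- data$value[data$set == sets[1]]
    b <- data$value[data$set == sets[2]]
    if (length(a) < 2 || length(b) < 2) {
      abort("each set needs at least 2 genes.")
    }
    wt <- suppressWarnings(wilcox.test(a, b))
    tibble(p_value = wt$p.value, median_pct_change = NA_real_,
           n = length(a) + length(b))
  }
}

#' Uniformity and homogeneity tests for two phase distributions
#'
#' Rayleigh tests on the raw phases (unimodal departure from uniformity) and
#' on doubled phases (axial transform, sensitive to bimodal distributions
#' with antipodal peaks), plus the Monte-Carlo circular homogeneity test
#' between the two samples.
#'
#' @param phases_a,phases_b Phase samples in hours (each n >= 10).
#' @param n_mc Monte-Carlo replications for the homogeneity test.
#' @param seed Seed.
#' @return Tibble with one row per test: `test`, `statistic`, `p_value`.
#' @export
phase_distribution_tests <- function(phases_a, phases_b, n_mc = 10000,
                                     seed = 1) {
  if (length(phases_a) < 10 || length(phases_b) < 10) {
    abort("both phase samples need at least 10 values.")
  }
  dbl <- function(p) wrap_hours(2 * p)
  ra <- rayleigh_test(phases_a, method = "approximation")
  rad <- rayleigh_test(dbl(phases_a), method = "approximation")
  rb <- rayleigh_test(phases_b, method = "approximation")
  rbd <- rayleigh_test(dbl(phases_b), method = "approximation")
  hom <- circular_homogeneity_test(phases_a, phases_b, n_mc = n_mc,
                                   seed = seed)
  tibble(
    test = c("rayleigh_a", "rayleigh_axial_a", "rayleigh_b",
             "rayleigh_axial_b", "homogeneity"),
    statistic = c(ra$statistic, rad$statistic, rb$statistic, rbd$statistic,
                  hom$statistic),
    p_value = c(ra$p_value, rad$p_value, rb$p_value, rbd$p_value,
                hom$p_value)
  )
}

#' Cosinor phases of a gene set in one condition
#'
#' Convenience wrapper fitting [cosinor_fit()] per gene on one condition's
#' samples; used to feed phase distributions and enrichment analyses.
#'
#' @param em An `expression_matrix`.
#' @param condition Condition label.
#' @param genes Gene ids (default: all genes).
#' @param period Rhythm period.
#' @return Tibble: `gene_id`, `phase_h`, `amplitude`, `mesor`.
#' @export
gene_cosinor_phases <- function(em, condition, genes = NULL, period = 24) {
  stopifnot(inherits(em, "expression_matrix"))
  genes <- genes %||% rownames(em$values)
  purrr::map_dfr(genes, function(g) {
    fit <- cosinor_fit(em_condition_series(em, condition, g), period = period)
    tibble(gene_id = g, phase_h = fit$acrophase_h, amplitude = fit$amplitude,
           mesor = fit$mesor)
  })
}
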