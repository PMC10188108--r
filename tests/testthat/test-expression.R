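sim_small <- function(seed = 71, n_genes = 40, ...) {
  simulate_expression(expression_sim_config(seed = seed, n_genes = n_genes,
                                            ...))
}

test_that("TMM normalisation handles proportional and composed libraries", {
  sim <- sim_small()
  counts <- sim$counts

  # two identical libraries: both factors 1
  cc <- counts[, 1:2]; cc[, 2] <- cc[, 1]
  colnames(cc) <- c("s1", "s2")
  em <- normalize_counts(cc, tibble::tibble(sample_id = c("s1", "s2"),
                                            condition = "A",
                                            time_h = c(0, 4),
                                            replicate = 1:2),
                         filter = FALSE)
  expect_equal(unname(em$norm_factors), c(1, 1), tolerance = 1e-12)

  # doubling a library changes depth, not composition: TMM factor stays 1
  cc2 <- cbind(s1 = counts[, 1], s2 = 2 * counts[, 1])
  em2 <- normalize_counts(cc2, tibble::tibble(sample_id = c("s1", "s2"),
                                              condition = "A",
                                              time_h = c(0, 4),
                                              replicate = 1:2),
                          filter = FALSE)
  expect_equal(unname(em2$norm_factors), c(1, 1), tolerance = 1e-9)
  # and the pre-log CPM columns sum to exactly 1e6
  cpm <- 2^em2$values - 0.5
  expect_equal(unname(colSums(cpm)), c(1e6, 1e6), tolerance = 1e-6)

  expect_error(normalize_counts(cbind(a = c(0, 0), b = c(1, 2)),
                                tibble::tibble(sample_id = c("a", "b"),
                                               condition = "A",
                                               time_h = 0:1,
                                               replicate = 1:2)),
               "zero-count")
  expect_error(normalize_counts(matrix(-1), tibble::tibble(sample_id = "a")),
               "non-negative")
})

test_that("TMM factor for a distorted library matches a brute-force trimmed mean", {
  set.seed(72)
  n <- 2000
  base <- rnbinom(n, mu = 200, size = 5) + 1
  infl <- base
  hot <- sample(n, n * 0.05)
  infl[hot] <- infl[hot] * 10
  counts <- cbind(ref = base, hot = infl)
  em <- normalize_counts(counts,
                         tibble::tibble(sample_id = c("ref", "hot"),
                                        condition = "A", time_h = c(0, 4),
                                        replicate = 1:2),
                         filter = FALSE)
  f_hot <- em$norm_factors["hot"] / em$norm_factors["ref"]
  # the inflated library's effective size must grow, i.e. its scale factor
  # shrinks below 1, by exactly the trimmed mean of M values
  expect_lt(f_hot, 1)

  # brute-force doubly trimmed weighted mean of M values (ref library = 1st)
  p1 <- base / sum(base); p2 <- infl / sum(infl)
  keep <- p1 > 0 & p2 > 0
  M <- log2(p2 / p1)[keep]; A <- (log2(p2) + log2(p1))[keep] / 2
  w <- (1 - p2) / (sum(infl) * p2) + (1 - p1) / (sum(base) * p1)
  w <- 1 / w[keep]
  loM <- quantile(M, 0.3); hiM <- quantile(M, 0.7)
  loA <- quantile(A, 0.05); hiA <- quantile(A, 0.95)
  sel <- M >= loM & M <= hiM & A >= loA & A <= hiA
  f_brute <- 2^(sum(w[sel] * M[sel]) / sum(w[sel]))
  expect_equal(unname(f_hot), unname(f_brute), tolerance = 0.02)
})

test_that("the rhythmicity screen finds planted genes and their phases", {
  sim <- sim_small(seed = 73, n_genes = 50, rhythmic_fraction = 0.4,
                   dispersion = 0.02, phase_kappa = 0,
                   amplitude_range = c(log(2), log(2)))
  em <- normalize_counts(sim$counts, sim$design, filter = FALSE)
  scr <- screen_rhythmicity(em, "Aligned")
  truth <- sim$truth[match(scr$gene_id, sim$truth$gene_id), ]
  expect_gte(mean(scr$rhythmic[truth$rhythmic_A]), 0.9)
  expect_lte(mean(scr$rhythmic[!truth$rhythmic_A]), 0.05)

  # peak-time estimates land within the 4-h sampling resolution
  hit <- truth$rhythmic_A & scr$rhythmic
  dphi <- abs(wrap_signed(scr$phase_h[hit] - truth$phase_A[hit]))
  expect_lte(median(dphi), 2)

  expect_error(screen_rhythmicity(em, "Aligned", period = 24,
                                  asym_step_h = 4) -> ok, NA)
  bad <- em; bad$design$condition <- NULL
  expect_error(screen_rhythmicity(bad, "Aligned"), "design")
})

test_that("gene classification follows the exclusion rule and partitions", {
  mk <- function(p) tibble::tibble(gene_id = paste0("g", seq_along(p)),
                                   p_adj = p)
  res <- classify_genes(mk(c(0.005, 0.005, 0.005, 0.5, 0.05)),
                        mk(c(0.5, 0.05, 0.005, 0.005, 0.5)))
  expect_equal(res$class,
               c("align_specific", "indeterminate", "shared",
                 "sc_specific", "arrhythmic"))
  # classes partition the gene universe
  expect_false(any(is.na(res$class)))
  expect_equal(nrow(res), 5)
})

test_that("phase-shift analysis flags temperature tracking", {
  # phases spread over the clock (kappa 0) so the library totals carry no
  # common rhythmic mode for CPM normalisation to subtract
  sim <- sim_small(seed = 74, n_genes = 60, rhythmic_fraction = 1,
                   shift_fraction = 0.5, dispersion = 0.1, phase_kappa = 0,
                   amplitude_range = c(log(2), log(2)))
  em <- normalize_counts(sim$counts, sim$design, filter = FALSE)
  ps <- phase_shift_analysis(em, rownames(em$values))
  truth <- sim$truth[match(ps$gene_id, sim$truth$gene_id), ]
  expect_gte(mean(ps$temperature_tracking[truth$shifted_12h]), 0.85)
  expect_lte(mean(ps$temperature_tracking[!truth$shifted_12h]), 0.1)
  flagged <- ps$temperature_tracking
  expect_lt(abs(median(abs(ps$delta_phase_light_h[flagged])) - 12), 0.5)

  cls <- tibble::tibble(gene_id = ps$gene_id,
                        class = c("arrhythmic",
                                  rep("shared", nrow(ps) - 1)))
  expect_error(phase_shift_analysis(em, ps$gene_id[1], classification = cls),
               "shared")
})

test_that("amplitude comparisons report direction and refuse tiny sets", {
  set.seed(75)
  a <- runif(400, 0.5, 2)
  d <- tibble::tibble(amplitude_a = a,
                      amplitude_b = 0.9 * a * exp(rnorm(400, 0, 0.05)))
  res <- compare_amplitudes(d, type = "paired")
  expect_lt(res$p_value, 0.01)
  expect_gt(res$median_pct_change, -13)
  expect_lt(res$median_pct_change, -7)

  un <- tibble::tibble(value = c(rnorm(30, 5), rnorm(30, 6)),
                       set = rep(c("x", "y"), each = 30))
  expect_lt(compare_amplitudes(un, type = "unpaired")$p_value, 0.05)

  expect_error(compare_amplitudes(d[1, ], type = "paired"), "at least 2")
  expect_error(compare_amplitudes(tibble::tibble(value = 1, set = "x"),
                                  type = "unpaired"), "two levels")
})

test_that("phase distribution tests detect bimodality and rotation", {
  set.seed(76)
  bimodal <- c(simulate_phases(100, 4, 5, seed = 1),
               simulate_phases(100, 16, 5, seed = 2))
  unif <- simulate_phases(200, 0, 0, seed = 3)
  res <- phase_distribution_tests(bimodal, unif, n_mc = 500, seed = 1)
  raw_p <- res$p_value[res$test == "rayleigh_a"]
  axial_p <- res$p_value[res$test == "rayleigh_axial_a"]
  expect_lt(axial_p, 0.001)
  expect_gt(raw_p, axial_p)

  rot <- (bimodal + 6) %% 24
  res2 <- phase_distribution_tests(bimodal, rot, n_mc = 999, seed = 1)
  expect_lt(res2$p_value[res2$test == "homogeneity"], 0.05)

  expect_error(phase_distribution_tests(1:5, 1:20), "at least 10")
})
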