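#' Per-window over-representation test of functional terms
#'
#' For one 4-h sliding window on the phase circle, tests each functional
#' term for over-representation of member genes with peak phase inside the
#' window (half-open `[start, start + width)`, mod 24), using a one-sided
#' Fisher's exact test on the 2x2 in-term x in-window table. P-values are
#' Benjamini-Hochberg adjusted across terms within the window. Terms with
#' fewer than `min_term_size` genes in the phase table are dropped.
#'
#' @param phases Tibble with `gene_id` and `phase_h` (one row per gene).
#' @param membership Tibble with `gene_id`, `term_id`.
#' @param window_start Window start, ZT hours.
#' @param width_h Window width, hours (default 4).
#' @param min_term_size Minimum genes per term (default 5).
#' @return Tibble: `term_id`, `window_start`, `n_in_window`, `n_term`,
#'   `p_raw`, `p_adj`.
#' @export
window_term_test <- function(phases, membership, window_start, width_h = 4,
                             min_term_size = 5) {
  stopifnot(all(c("gene_id", "phase_h") %in% names(phases)),
            all(c("gene_id", "term_id") %in% names(membership)))
  rel <- wrap_hours(phases$phase_h - window_start)
  in_win <- rel < width_h
  mem <- membership |> filter(.data$gene_id %in% phases$gene_id)
  term_sizes <- table(mem$term_id)
  terms <- names(term_sizes)[term_sizes >= min_term_size]
  n_genes <- nrow(phases)
  n_win <- sum(in_win)
  win_genes <- phases$gene_id[in_win]
  res <- purrr::map_dfr(terms, function(tm) {
    tg <- mem$gene_id[mem$term_id == tm]
    a <- sum(tg %in% win_genes)               # in term, in window
    b <- length(tg) - a                       # in term, out of window
    c_ <- n_win - a                           # out of term, in window
    d <- n_genes - length(tg) - c_
    p <- if (n_win == 0) 1 else
      fisher.test(matrix(c(a, b, c_, d), 2), alternative = "greater")$p.value
    tibble(term_id = tm, window_start = window_start,
           n_in_window = a, n_term = length(tg), p_raw = p)
  })
  res$p_adj <- p.adjust(res$p_raw, "BH")
  res
}

#' Run the window test at every hourly window start
#'
#' @inheritParams window_term_test
#' @return Stacked tibble over `window_start = 0 ... 23`.
#' @export
sliding_window_tests <- function(phases, membership, width_h = 4,
                                 min_term_size = 5) {
  purrr::map_dfr(0:23, function(w) {
    window_term_test(phases, membership, w, width_h = width_h,
                     min_term_size = min_term_size)
  })
}

#' Hourly enrichment score track from per-window adjusted p-values
#'
#' The score of a term at hour \eqn{t} averages the \eqn{-\log_{10}}
#' adjusted p-values of the three sliding windows strictly containing
#' \eqn{t} in their interior, i.e. the windows starting at \eqn{t-3},
#' \eqn{t-2} and \eqn{t-1} (mod 24) for 4-h windows — the score at ZT3
#' averages windows ZT0-4, ZT1-5 and ZT2-6. A term counts as enriched at
#' \eqn{t} when the score exceeds \eqn{-\log_{10}(0.05)}.
#'
#' @param window_results Output of [sliding_window_tests()] (all 24 window
#'   starts present for every term).
#' @param alpha Enrichment threshold on the averaged adjusted p (default 0.05).
#' @return An `enrichment_track` tibble: `term_id`, `zt_h` (0-23), `score`,
#'   `enriched`.
#' @export
enrichment_score_track <- function(window_results, alpha = 0.05) {
  stopifnot(all(c("term_id", "window_start", "p_adj") %in%
                  names(window_results)))
  by_term <- split(window_results, window_results$term_id)
  out <- purrr::map_dfr(by_term, function(df) {
    if (!setequal(df$window_start, 0:23)) {
      abort(sprintf("term %s is missing window starts.", df$term_id[1]))
    }
    lp <- -log10(df$p_adj[match(0:23, df$window_start)])
    score <- vapply(0:23, function(t) {
      mean(lp[(c(t - 3, t - 2, t - 1) %% 24) + 1])
    }, numeric(1))
    tibble(term_id = df$term_id[1], zt_h = 0:23, score = score,
           enriched = score > -log10(alpha))
  })
  class(out) <- c("enrichment_track", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' Peak hours of enriched terms
#'
#' Reduces each term's contiguous runs of enriched hours (circular over the
#' 24-h clock) to the hour of maximal score; ties go to the earliest hour of
#' the run.
#'
#' @param track An `enrichment_track` from [enrichment_score_track()].
#' @return Tibble: `term_id`, `peak_zt_h`, `peak_score` (empty when nothing
#'   is enriched).
#' @export
enrichment_peaks <- function(track) {
  stopifnot(all(c("term_id", "zt_h", "score", "enriched") %in% names(track)))
  purrr::map_dfr(split(track, track$term_id), function(df) {
    df <- df[order(df$zt_h), ]
    e <- df$enriched
    if (!any(e)) return(tibble())
    # circular runs: rotate so a non-enriched hour (if any) comes first
    start <- if (all(e)) 1L else which(!e)[1]
    ord <- ((start - 1 + 0:23) %% 24) + 1
    r <- rle(e[ord])
    ends <- cumsum(r$lengths); begins <- ends - r$lengths + 1
    purrr::map_dfr(which(r$values), function(i) {
      idx <- ord[begins[i]:ends[i]]
      best <- idx[which.max(df$score[idx])]
      tibble(term_id = df$term_id[1], peak_zt_h = df$zt_h[best],
             peak_score = df$score[best])
    })
  })
}
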