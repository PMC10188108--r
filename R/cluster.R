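# Leaf sets (as sorted integer vectors) of every internal node of an hclust.
hclust_node_sets <- function(hc) {
  n <- nrow(hc$merge) + 1
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[i, ]
    get <- function(k) if (k < 0) -k else sets[[k]]
    sets[[i]] <- sort(c(get(kids[1]), get(kids[2])))
  }
  sets
}

node_keys <- function(sets) vapply(sets, paste, character(1), collapse = ",")

#' Complete-linkage clustering with multiscale-bootstrap AU support
#'
#' Hierarchical clustering (complete linkage on Euclidean distances) of
#' embedded series, with cluster uncertainty quantified by multiscale
#' bootstrap: feature columns are resampled with replacement at relative
#' sizes `scales` (default 0.5 ... 1.4 times the number of features),
#' `n_boot` times each. For every internal node of the observed tree the
#' bootstrap probability \eqn{BP(r)} is the fraction of resampled trees
#' containing the same leaf set; the signed-root model \eqn{z(r) = v\sqrt{r}
#' + c/\sqrt{r}} is fitted to \eqn{\Phi^{-1}(1 - BP(r))} by weighted least
#' squares and the approximately unbiased support is \eqn{AU = 1 - \Phi(v -
#' c)}. Nodes recovered always (never) across all scales get AU 1 (0)
#' without fitting.
#'
#' @param coords Numeric matrix, series x features (e.g. from [pca_embed()]);
#'   >= 4 rows.
#' @param n_boot Bootstrap replicates per scale (default 1000).
#' @param seed Integer seed.
#' @param scales Relative resampling sizes.
#' @return An object of class `cluster_result`: `hclust` (the observed
#'   tree), `nodes` tibble (`node`, `members`, `bp`, `au`, `v`, `c`),
#'   `n_boot`, `scales`.
#' @export
hcluster_au <- function(coords, n_boot = 1000, seed = 1,
                        scales = seq(0.5, 1.4, by = 0.1)) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 4) abort("need at least 4 observations.")
  p <- ncol(coords)
  hc <- hclust(dist(coords), method = "complete")
  sets <- hclust_node_sets(hc)
  keys <- node_keys(sets)
  if (p < 2) {
    nodes <- tibble(node = seq_along(sets),
                    members = vapply(sets, function(s)
                      paste(hc$labels[s] %||% s, collapse = ","), character(1)),
                    bp = NA_real_, au = NA_real_, v = NA_real_, c = NA_real_)
    return(structure(list(hclust = hc, nodes = nodes, n_boot = n_boot,
                          scales = scales), class = "cluster_result"))
  }
  counts <- matrix(0, length(sets), length(scales))
  with_seed(seed, {
    for (si in seq_along(scales)) {
      m <- max(2L, round(scales[si] * p))
      for (b in seq_len(n_boot)) {
        cols <- sample.int(p, m, replace = TRUE)
        hb <- hclust(dist(coords[, cols, drop = FALSE]), method = "complete")
        kb <- node_keys(hclust_node_sets(hb))
        counts[, si] <- counts[, si] + (keys %in% kb)
      }
    }
  })
  bp_mat <- counts / n_boot
  rho <- vapply(scales, function(r) max(2L, round(r * p)) / p, numeric(1))
  fit_au <- function(bp) {
    if (all(bp >= 1)) return(c(au = 1, v = NA, c = NA))
    if (all(bp <= 0)) return(c(au = 0, v = NA, c = NA))
    use <- bp > 0 & bp < 1
    if (sum(use) < 2) {
      return(c(au = bp[which.min(abs(rho - 1))], v = NA, c = NA))
    }
    z <- qnorm(1 - bp[use])
    X <- cbind(sqrt(rho[use]), 1 / sqrt(rho[use]))
    w <- n_boot * dnorm(z)^2 / (bp[use] * (1 - bp[use]))
    vc <- tryCatch(solve(crossprod(X * sqrt(w)), crossprod(X * sqrt(w), z * sqrt(w))),
                   error = function(e) NULL)
    if (is.null(vc)) return(c(au = bp[which.min(abs(rho - 1))], v = NA, c = NA))
    c(au = 1 - pnorm(vc[1] - vc[2]), v = vc[1], c = vc[2])
  }
  au_fit <- t(apply(bp_mat, 1, fit_au))
  labels <- hc$labels %||% as.character(seq_len(nrow(coords)))
  nodes <- tibble(
    node = seq_along(sets),
    members = vapply(sets, function(s) paste(labels[s], collapse = ","),
                     character(1)),
    bp = bp_mat[, which.min(abs(rho - 1))],
    au = au_fit[, "au"], v = au_fit[, "v"], c = au_fit[, "c"]
  )
  structure(list(hclust = hc, nodes = nodes, n_boot = n_boot,
                 scales = scales),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Complete-linkage clustering of %d series; %d bootstrap replicates x %d scales\n",
              nrow(x$hclust$merge) + 1, x$n_boot, length(x$scales)))
  print(x$nodes, n = Inf)
  invisible(x)
}

#' Cut a clustering result into k clusters
#'
#' @param x A `cluster_result`.
#' @param k Number of clusters.
#' @return Named integer vector of cluster memberships.
#' @export
cut_clusters <- function(x, k) {
  stopifnot(inherits(x, "cluster_result"))
  cutree(x$hclust, k = k)
}

#' Tidy a clustering result
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return The per-node support tibble.
#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) x$nodes

#' @rdname tidy.cluster_result
#' @method glance cluster_result
#' @export
glance.cluster_result <- function(x, ...) {
  tibble(n_series = nrow(x$hclust$merge) + 1, n_boot = x$n_boot,
         n_scales = length(x$scales),
         min_au = min(x$nodes$au, na.rm = TRUE),
         max_au = max(x$nodes$au, na.rm = TRUE))
}

#' Export an AU-annotated tree in Newick format
#'
#' Writes the complete-linkage tree with AU/BP support values as internal
#' node labels (format `au|bp`), deterministically.
#'
#' @param x A `cluster_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cluster_newick <- function(x, path) {
  stopifnot(inherits(x, "cluster_result"))
  hc <- x$hclust
  labels <- hc$labels %||% as.character(seq_len(nrow(hc$merge) + 1))
  rec <- function(i) {
    kids <- hc$merge[i, ]
    part <- function(k) if (k < 0) labels[-k] else rec(k)
    sup <- sprintf("%.3f|%.3f", x$nodes$au[i], x$nodes$bp[i])
    sprintf("(%s,%s)%s:%g", part(kids[1]), part(kids[2]), sup, hc$height[i])
  }
  writeLines(paste0(rec(nrow(hc$merge)), ";"), path)
  invisible(path)
}
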