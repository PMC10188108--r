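#' Write a track in the three-header-row pose CSV dialect
#'
#' Writes one animal's track in the CSV layout emitted by markerless-tracking
#' tools: a `scorer` row, a `bodyparts` row, a `coords` row, then one row per
#' frame with frame index and `x`, `y`, `likelihood` columns for the single
#' bodypart.
#'
#' @param track Tibble with columns `t`, `x`, `y`, `likelihood` (one animal).
#' @param path Output file.
#' @param scorer,bodypart Labels for the header rows.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(track, path, scorer = "sim", bodypart = "center") {
  stopifnot(all(c("x", "y", "likelihood") %in% names(track)))
  header <- c(
    paste(c("scorer", rep(scorer, 3)), collapse = ","),
    paste(c("bodyparts", rep(bodypart, 3)), collapse = ","),
    "coords,x,y,likelihood"
  )
  body <- paste(seq_len(nrow(track)) - 1,
                format(track$x, trim = TRUE, digits = 15),
                format(track$y, trim = TRUE, digits = 15),
                format(track$likelihood, trim = TRUE, digits = 15),
                sep = ",")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a three-header-row pose CSV into a track
#'
#' Parses the pose CSV dialect written by [write_pose_csv()] (scorer /
#' bodyparts / coords header rows, one bodypart). Frames with an empty
#' coordinate cell get likelihood 0 so that track cleaning interpolates them.
#'
#' @param path Input file.
#' @param fps Frames per second used to reconstruct frame times (default 2).
#' @param animal_id Label for the `animal_id` column; default: file name.
#' @param zt_offset_h ZT hour at the start of the recording.
#' @return A track tibble (`animal_id`, `t`, `x`, `y`, `likelihood`) with
#'   attributes `fps` and `zt_offset_h`.
#' @export
read_pose_csv <- function(path, fps = 2, animal_id = NULL, zt_offset_h = 0) {
  lines <- readLines(path)
  if (length(lines) < 4) {
    abort("pose CSV too short: expected 3 header rows plus data.")
  }
  hdr <- strsplit(lines[1:3], ",", fixed = TRUE)
  tags <- vapply(hdr, `[`, character(1), 1)
  expected <- c("scorer", "bodyparts", "coords")
  bad <- which(tags != expected)
  if (length(bad) > 0) {
    abort(sprintf("malformed pose CSV header: row %d should start with '%s', found '%s'.",
                  bad[1], expected[bad[1]], tags[bad[1]]))
  }
  bodyparts <- unique(hdr[[2]][-1])
  if (length(bodyparts) != 1) {
    abort("pose CSV must contain exactly one bodypart.")
  }
  coords <- hdr[[3]][-1]
  if (!all(c("x", "y", "likelihood") %in% coords)) {
    abort("malformed pose CSV header: 'coords' row must name x, y and likelihood columns.")
  }
  ix <- which(coords == "x")[1] + 1
  iy <- which(coords == "y")[1] + 1
  il <- which(coords == "likelihood")[1] + 1
  cells <- strsplit(lines[-(1:3)], ",", fixed = TRUE)
  grab <- function(i) {
    vapply(cells, function(r) {
      v <- if (length(r) >= i) r[[i]] else ""
      if (v == "") NA_real_ else as.numeric(v)
    }, numeric(1))
  }
  x <- grab(ix); y <- grab(iy); lik <- grab(il)
  lik[is.na(x) | is.na(y) | is.na(lik)] <- 0
  out <- tibble(
    animal_id = animal_id %||% basename(path),
    t = (seq_along(x) - 1) / fps,
    x = x, y = y, likelihood = lik
  )
  attr(out, "fps") <- fps
  attr(out, "zt_offset_h") <- zt_offset_h
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read tab-separated pipeline tables
#'
#' Thin TSV helpers used by every stage: counts matrices (genes x samples,
#' with a `gene_id` first column), sample-design tables, activity series,
#' per-gene results. Writing is deterministic (no timestamps, fixed digits)
#' so reruns with the same seed are byte-identical.
#'
#' @param x Data frame (or matrix with row names for `write_counts_tsv`).
#' @param path File path.
#' @return `path` (writers, invisibly) or a tibble/matrix (readers).
#' @name zeitconflict-io
NULL

#' @rdname zeitconflict-io
#' @export
write_tsv_table <- function(x, path) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, trim = TRUE, digits = 15))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname zeitconflict-io
#' @export
write_counts_tsv <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname zeitconflict-io
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname zeitconflict-io
#' @export
read_tsv_table <- function(path) {
  as_tibble(utils::read.delim(path, check.names = FALSE))
}
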