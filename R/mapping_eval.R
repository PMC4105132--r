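PSL_COLS <- c("matches", "mismatches", "rep_matches", "n_bases",
              "q_gap_count", "q_gap_bases", "t_gap_count", "t_gap_bases",
              "strand", "query_id", "query_length", "q_start", "q_end",
              "target_id", "target_length", "t_start", "t_end",
              "block_count", "block_sizes", "q_starts", "t_starts")

#' Parse a PSL alignment table
#'
#' Reads the 21-column tabular format produced by blat. The optional
#' 5-line `psLayout` header is detected and skipped. Coordinates follow
#' the PSL convention (0-based, half-open).
#'
#' @param path Path to a PSL file.
#' @return Tibble with one row per alignment; numeric columns typed,
#'   block lists (`block_sizes`, `q_starts`, `t_starts`) kept as
#'   comma-separated strings.
#' @export
parse_psl <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  offset <- 0L
  if (length(lines) > 0 && startsWith(lines[[1]], "psLayout")) {
    offset <- 5L               # psLayout header is five lines incl. the dashes
    lines <- lines[-seq_len(min(5L, length(lines)))]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(as_tibble(setNames(rep(list(character()), 21), PSL_COLS)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 21L)) {
    bad <- which(nf != 21L)[1]
    abort(sprintf("parse error in %s at line %d: expected 21 PSL columns, found %d",
                  path, bad + offset, nf[bad]))
  }
  m <- matrix(unlist(fields), ncol = 21L, byrow = TRUE)
  colnames(m) <- PSL_COLS
  out <- as_tibble(m)
  num_cols <- setdiff(PSL_COLS, c("strand", "query_id", "target_id",
                                  "block_sizes", "q_starts", "t_starts"))
  out[num_cols] <- lapply(out[num_cols], function(x) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) abort(sprintf("parse error in %s: non-numeric PSL field", path))
    v
  })
  out
}

#' Keep the longest alignment per query
#'
#' When a query has several alignments, only the one with the most
#' matching bases is kept; ties are broken by the larger target span and
#' then by input order (first seen wins).
#'
#' @param alignments Alignment tibble (from [parse_psl()] or with at
#'   least `query_id`, `matches`, `t_start`, `t_end`).
#' @return One row per `query_id`, a subset of the input.
#' @export
dedup_longest <- function(alignments) {
  if (nrow(alignments) == 0) return(alignments)
  span <- alignments$t_end - alignments$t_start
  alignments |>
    mutate(.span = span, .ord = row_number()) |>
    group_by(.data$query_id) |>
    arrange(dplyr::desc(.data$matches), dplyr::desc(.data$.span), .data$.ord,
            .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    arrange(.data$.ord) |>
    select(-".span", -".ord")
}

#' Alignment coverage (match-to-length ratio)
#'
#' @param alignments Alignment tibble with `matches` and `query_length`.
#' @return Numeric vector of `matches / query_length`, one per row.
#' @export
coverage <- function(alignments) {
  if (any(alignments$query_length <= 0)) abort("`query_length` must be > 0")
  alignments$matches / alignments$query_length
}

#' Summarise genome mapping of an assembly
#'
#' Evaluates how an assembled transcript set maps onto a reference
#' genome from its (deduplicated) alignments: mapped fraction,
#' single-block versus multi-block split, the number of queries covered
#' over more than 90% of their length (strict `>`), and histograms of
#' block counts and coverage deciles. The top coverage bin `[0.9, 1.0]`
#' is closed. [dedup_longest()] is applied internally.
#'
#' @param queries Sequence tibble of all queries (mapped or not).
#' @param alignments Alignment tibble.
#' @return One-row tibble of class `mapping_summary` with counts and two
#'   list-columns, `block_histogram` and `coverage_histogram`.
#' @export
mapping_summary <- function(queries, alignments) {
  check_seq_tbl(queries, "queries")
  unknown <- setdiff(unique(alignments$query_id), queries$id)
  if (length(unknown) > 0) {
    abort(sprintf("alignment references unknown query id(s): %s",
                  paste(utils::head(unknown, 3), collapse = ", ")))
  }
  best <- dedup_longest(alignments)
  n_mapped <- nrow(best)
  cov <- if (n_mapped > 0) coverage(best) else numeric()
  decile <- pmin(floor(cov * 10), 9)   # decile bins, [0.9, 1.0] closed
  bin_labels <- c(sprintf("[%.1f,%.1f)", 0:8 / 10, 1:9 / 10), "[0.9,1.0]")
  cov_hist <- tibble(
    bin = factor(bin_labels, levels = bin_labels),
    n = as.integer(tabulate(decile + 1, nbins = 10))
  )
  blk_hist <- if (n_mapped > 0) {
    dplyr::count(tibble(block_count = as.integer(best$block_count)),
                 .data$block_count, name = "n")
  } else {
    tibble(block_count = integer(), n = integer())
  }
  out <- tibble(
    n_queries = nrow(queries),
    n_mapped = n_mapped,
    mapped_fraction = if (nrow(queries) > 0) n_mapped / nrow(queries) else 0,
    n_single_block = sum(best$block_count == 1),
    n_multi_block = sum(best$block_count >= 2),
    n_cov_ge_090 = sum(cov > 0.90),
    block_histogram = list(blk_hist),
    coverage_histogram = list(cov_hist)
  )
  class(out) <- c("mapping_summary", class(out))
  out
}

#' @param object A `mapping_summary`.
#' @param which Which panel to draw: coverage deciles or block counts.
#' @param ... Ignored.
#' @rdname mapping_summary
#' @exportS3Method ggplot2::autoplot
autoplot.mapping_summary <- function(object, which = c("coverage", "blocks"), ...) {
  which <- match.arg(which)
  if (which == "coverage") {
    ggplot2::ggplot(object$coverage_histogram[[1]],
                    ggplot2::aes(x = .data$bin, y = .data$n)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = "coverage (match-to-length)", y = "unigenes") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  } else {
    ggplot2::ggplot(object$block_histogram[[1]],
                    ggplot2::aes(x = .data$block_count, y = .data$n)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = "alignment blocks", y = "unigenes") +
      ggplot2::theme_minimal()
  }
}
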