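DEFAULT_SSR_THRESHOLDS <- c(`2` = 6L, `3` = 5L, `4` = 4L, `5` = 4L, `6` = 4L)

# Minimal period of a motif: smallest divisor d of its length such that
# the motif is a repetition of its first d characters.
minimal_period <- function(motif) {
  m <- nchar(motif)
  for (d in seq_len(m)) {
    if (m %% d == 0 &&
        strrep(substr(motif, 1, d), m / d) == motif) return(d)
  }
  m
}

# All maximal perfect tandem runs of period m in one sequence.
# Uses the shift-match trick: position i extends a period-m run iff
# seq[i] == seq[i + m]; a TRUE-run of length t starting at i spans a
# matched stretch of t + m characters, i.e. floor((t + m) / m) repeats.
runs_of_period <- function(chars, m) {
  L <- length(chars)
  if (L < 2 * m) return(NULL)
  e <- chars[seq_len(L - m)] == chars[(m + 1):L]
  r <- rle(e)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) return(NULL)
  i <- starts[keep]
  t <- r$lengths[keep]
  reps <- (t + m) %/% m
  list(start = i, reps = reps)
}

#' Find perfect microsatellites in sequences
#'
#' SSRIT-style scan for perfect (uninterrupted) tandem repeats of 2-6 nt
#' motifs. Maximal runs are reported left to right; runs below the
#' per-motif-length repeat threshold are ignored; mononucleotide runs
#' are never reported; motifs that are repetitions of a shorter motif
#' collapse to the shortest period (an `ATAT x 3` run is an `AT x 6`
#' run); and overlapping reports are suppressed greedily from the left
#' (at equal starts the longer span, then the shorter motif, wins).
#' Motifs containing `N` are not considered.
#'
#' @param records Sequence tibble.
#' @param thresholds Named integer vector of minimum repeat numbers for
#'   motif lengths `2:6` (default `c(6, 5, 4, 4, 4)`).
#' @return Tibble `seq_id`, `motif`, `canonical` (smallest cyclic
#'   rotation), `repeats`, `start`, `end` (1-based inclusive), sorted by
#'   sequence and position; hits within a sequence never overlap and
#'   satisfy `end - start + 1 == nchar(motif) * repeats`.
#' @export
find_ssrs <- function(records, thresholds = DEFAULT_SSR_THRESHOLDS) {
  check_seq_tbl(records)
  if (!all(as.character(2:6) %in% names(thresholds))) {
    abort("`thresholds` must be named with motif lengths \"2\"..\"6\"")
  }
  empty <- tibble(seq_id = character(), motif = character(),
                  canonical = character(), repeats = integer(),
                  start = integer(), end = integer())
  out <- purrr::map(seq_len(nrow(records)), function(idx) {
    seq <- records$seq[[idx]]
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    cand <- list()
    for (m in 2:6) {
      rr <- runs_of_period(chars, m)
      if (is.null(rr)) next
      ok <- rr$reps >= thresholds[[as.character(m)]]
      if (!any(ok)) next
      start <- rr$start[ok]
      reps <- rr$reps[ok]
      motif <- substr(rep(seq, length(start)), start, start + m - 1L)
      prim <- !grepl("N", motif, fixed = TRUE) &
        vapply(motif, minimal_period, integer(1), USE.NAMES = FALSE) == m
      if (!any(prim)) next
      cand[[length(cand) + 1L]] <- tibble(
        motif = motif[prim], repeats = as.integer(reps[prim]),
        start = as.integer(start[prim]),
        end = as.integer(start[prim] + m * reps[prim] - 1L)
      )
    }
    if (length(cand) == 0) return(NULL)
    cand <- bind_rows(cand)
    cand <- cand[order(cand$start, -(cand$end - cand$start), nchar(cand$motif)), ]
    # greedy left-to-right suppression of overlaps
    keep <- logical(nrow(cand))
    last_end <- 0L
    for (j in seq_len(nrow(cand))) {
      if (cand$start[j] > last_end) {
        keep[j] <- TRUE
        last_end <- cand$end[j]
      }
    }
    cand <- cand[keep, ]
    cand$seq_id <- records$id[[idx]]
    cand
  })
  out <- purrr::compact(out)
  if (length(out) == 0) return(empty)
  hits <- bind_rows(out)
  hits$canonical <- vapply(hits$motif, canonical_motif, character(1),
                           USE.NAMES = FALSE)
  select(hits, "seq_id", "motif", "canonical", "repeats", "start", "end")
}

#' Canonical form of an SSR motif
#'
#' The lexicographically smallest cyclic rotation; reverse complements
#' are deliberately not folded together.
#'
#' @param motif A 2-6 nt motif.
#' @return The canonical rotation.
#' @export
#' @examples
#' canonical_motif("TA")   # "AT"
#' canonical_motif("GCA")  # "AGC"
canonical_motif <- function(motif) {
  m <- nchar(motif)
  if (m < 2 || m > 6) abort("`motif` must be 2-6 nt")
  doubled <- paste0(motif, motif)
  min(substring(doubled, seq_len(m), seq_len(m) + m - 1L))
}

#' Scan a unigene set for SSR markers and summarise
#'
#' Restricts the scan to sequences strictly longer than `min_seq_nt`
#' (transcriptome SSR surveys conventionally screen unigenes > 1 kb),
#' detects SSRs with [find_ssrs()], and tabulates marker-survey
#' summaries: sequences with (and with more than one) SSR, motif-kind
#' counts under three definitions (raw motif string, canonical rotation,
#' and motif-by-repeat-count pair), the per-kilobase frequency, and the
#' motif-length-by-repeat-number matrix with repeat bins
#' 4, 5, ..., 10, >10.
#'
#' @param records Sequence tibble of the full unigene set.
#' @param min_seq_nt Strict length floor for screening (default 1000).
#' @param thresholds See [find_ssrs()].
#' @param frequency_denominator `"all"` (default) computes one SSR per X
#'   kb over the full unigene set's nucleotides; `"screened"` uses only
#'   the screened (> `min_seq_nt`) sequences.
#' @return Object of class `ssr_result`: list with `hits`, a one-row
#'   `summary` tibble and the `by_class` matrix tibble. [tidy()] returns
#'   the hits, [glance()] the summary.
#' @export
ssr_scan <- function(records, min_seq_nt = 1000L,
                     thresholds = DEFAULT_SSR_THRESHOLDS,
                     frequency_denominator = c("all", "screened")) {
  check_seq_tbl(records)
  frequency_denominator <- match.arg(frequency_denominator)
  screened <- dplyr::filter(records, nchar(.data$seq) > min_seq_nt)
  hits <- find_ssrs(screened, thresholds)

  denom_nt <- if (frequency_denominator == "all") {
    sum(nchar(records$seq))
  } else {
    sum(nchar(screened$seq))
  }
  per_seq <- table(hits$seq_id)
  class_names <- c(`2` = "Di", `3` = "Tri", `4` = "Tetra",
                   `5` = "Penta", `6` = "Hexa")
  rep_bins <- c(as.character(4:10), ">10")
  by_class <- tidyr::expand_grid(
    motif_class = factor(unname(class_names), levels = unname(class_names)),
    repeat_bin = factor(rep_bins, levels = rep_bins)
  )
  if (nrow(hits) > 0) {
    obs <- tibble(
      motif_class = factor(class_names[as.character(nchar(hits$motif))],
                           levels = unname(class_names)),
      repeat_bin = factor(ifelse(hits$repeats > 10, ">10",
                                 as.character(hits$repeats)),
                          levels = rep_bins)
    ) |> dplyr::count(.data$motif_class, .data$repeat_bin, name = "n")
    by_class <- left_join(by_class, obs, by = c("motif_class", "repeat_bin")) |>
      mutate(n = dplyr::coalesce(.data$n, 0L))
  } else {
    by_class$n <- 0L
  }

  summary <- tibble(
    n_sequences_screened = nrow(screened),
    n_sequences_with_ssr = length(per_seq),
    n_ssrs = nrow(hits),
    n_kinds_motif = dplyr::n_distinct(hits$motif),
    n_kinds_canonical = dplyr::n_distinct(hits$canonical),
    n_kinds_motif_repeat = nrow(dplyr::distinct(hits[c("motif", "repeats")])),
    n_sequences_multi = sum(per_seq > 1),
    screened_nt = sum(nchar(screened$seq)),
    total_nt = sum(nchar(records$seq)),
    frequency_kb = if (nrow(hits) > 0) (denom_nt / 1000) / nrow(hits) else NA_real_
  )
  structure(list(hits = hits, summary = summary, by_class = by_class),
            class = "ssr_result")
}

#' @export
print.ssr_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<ssr_result> %d SSRs in %d of %d screened sequences\n",
              s$n_ssrs, s$n_sequences_with_ssr, s$n_sequences_screened))
  if (!is.na(s$frequency_kb)) {
    cat(sprintf("  frequency: 1 per %.1f kb\n", s$frequency_kb))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ssr_result <- function(x, ...) x$hits

#' @exportS3Method generics::glance
glance.ssr_result <- function(x, ...) x$summary

#' @param object An `ssr_result`.
#' @param ... Ignored.
#' @rdname ssr_scan
#' @exportS3Method ggplot2::autoplot
autoplot.ssr_result <- function(object, ...) {
  ggplot2::ggplot(object$by_class,
                  ggplot2::aes(x = .data$motif_class, y = .data$n,
                               fill = .data$repeat_bin)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_viridis_d(name = "repeats") +
    ggplot2::labs(x = "motif length class", y = "SSRs") +
    ggplot2::theme_minimal()
}
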