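#' Trim an adapter from the 3' end of reads
#'
#' Looks for the leftmost position where a prefix of the adapter matches
#' the read exactly; the match must either reach the read's 3' end or
#' contain the full adapter, and must be at least `min_overlap` bases
#' long. The match and everything 3' of it are removed, qualities in
#' step. Reads without a qualifying match are returned unchanged.
#'
#' Matching is exact; no mismatches are tolerated.
#'
#' @param reads Read tibble (`id`, `bases`, `quals`).
#' @param adapter Adapter sequence (nonempty nucleotide string).
#' @param min_overlap Minimum adapter prefix length to trigger trimming
#'   (default 5).
#' @return The read tibble with trimmed `bases`/`quals`.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 5L) {
  check_read_tbl(reads)
  if (!is.character(adapter) || length(adapter) != 1 || !nzchar(adapter)) {
    abort("`adapter` must be a nonempty string")
  }
  adapter <- toupper(adapter)
  alen <- nchar(adapter)
  cut_at <- vapply(reads$bases, function(b) {
    L <- nchar(b)
    for (p in seq_len(L)) {
      ov <- min(L - p + 1L, alen)
      if (ov < min_overlap) break
      if (ov < alen && p + ov - 1L < L) next  # partial match must reach 3' end
      if (substr(b, p, p + ov - 1L) == substr(adapter, 1L, ov)) return(p - 1L)
    }
    L
  }, integer(1), USE.NAMES = FALSE)
  reads$bases <- substr(reads$bases, 1L, cut_at)
  reads$quals <- lapply(seq_len(nrow(reads)), function(i) {
    reads$quals[[i]][seq_len(cut_at[i])]
  })
  reads
}

#' Fraction of ambiguous (N) bases per read
#'
#' @param reads Read tibble.
#' @return Numeric vector, one fraction per read.
#' @export
n_fraction <- function(reads) {
  check_read_tbl(reads)
  len <- nchar(reads$bases)
  if (any(len == 0)) abort("cannot compute N fraction of an empty read")
  stringr::str_count(reads$bases, "N") / len
}

#' Fraction of low-quality bases per read
#'
#' @param reads Read tibble.
#' @param q_threshold Phred score below which a base counts as low
#'   quality (strict `<`; default 20).
#' @return Numeric vector, one fraction per read.
#' @export
low_qual_fraction <- function(reads, q_threshold = 20L) {
  check_read_tbl(reads)
  len <- nchar(reads$bases)
  if (any(len == 0)) abort("cannot compute quality fraction of an empty read")
  vapply(reads$quals, function(q) mean(q < q_threshold), numeric(1))
}

#' Clean raw reads with N-content and quality rules
#'
#' A read is discarded iff its N fraction exceeds `n_max` or its fraction
#' of bases with quality below 20 exceeds `lowq_max`; both comparisons
#' are strict, so a 90-nt read with exactly 9 bases under Q20 (10%) is
#' kept while one with 10 such bases is removed. In paired mode a pair is
#' dropped when either mate fails, keeping the two files synchronized.
#' If an adapter is supplied, reads are adapter-trimmed first; a read
#' trimmed to zero length counts as failing.
#'
#' @param reads Read tibble (mate 1 in paired mode).
#' @param mates Optional mate-2 read tibble of the same height.
#' @param n_max Maximum tolerated N fraction (default 0.05).
#' @param lowq_max Maximum tolerated fraction of bases with Q < 20
#'   (default 0.10).
#' @param adapter Optional adapter sequence to trim before filtering.
#' @param min_overlap Minimum adapter overlap, see [trim_adapter()].
#' @return An object of class `read_qc`: a list with the surviving
#'   `reads` (and `mates`), the logical `keep` vector over input rows,
#'   and a one-row `report` tibble (`n_raw`, `n_clean`, `clean_nt`,
#'   `q20_pct`, `gc_pct`, `n_pct`). Use [tidy()] for per-read detail and
#'   [glance()] for the report.
#' @export
clean_reads <- function(reads, mates = NULL, n_max = 0.05, lowq_max = 0.10,
                        adapter = NULL, min_overlap = 5L) {
  check_read_tbl(reads)
  if (n_max < 0 || n_max > 1 || lowq_max < 0 || lowq_max > 1) {
    abort("`n_max` and `lowq_max` must lie in [0, 1]")
  }
  if (!is.null(mates)) {
    check_read_tbl(mates, "mates")
    if (nrow(mates) != nrow(reads)) {
      abort("paired input is out of sync: `reads` and `mates` differ in length")
    }
  }
  if (!is.null(adapter)) {
    reads <- trim_adapter(reads, adapter, min_overlap)
    if (!is.null(mates)) mates <- trim_adapter(mates, adapter, min_overlap)
  }

  fractions <- function(x) {
    len <- nchar(x$bases)
    nf <- ifelse(len == 0, 1, stringr::str_count(x$bases, "N") / pmax(len, 1))
    lq <- vapply(seq_len(nrow(x)), function(i) {
      if (len[i] == 0) return(1)
      mean(x$quals[[i]] < 20L)
    }, numeric(1))
    tibble(id = x$id, n_fraction = nf, low_qual_fraction = lq,
           fail = nf > n_max | lq > lowq_max)
  }
  detail <- fractions(reads)
  detail$mate <- 1L
  if (!is.null(mates)) {
    d2 <- fractions(mates)
    d2$mate <- 2L
    fail <- detail$fail | d2$fail
    detail <- bind_rows(detail, d2)
  } else {
    fail <- detail$fail
  }
  keep <- !fail
  detail$kept <- rep(keep, times = 1L + !is.null(mates))

  survivors <- reads[keep, , drop = FALSE]
  surv_all <- if (is.null(mates)) survivors else
    bind_rows(survivors, mates[keep, , drop = FALSE])
  n_raw <- nrow(reads) * (1L + !is.null(mates))
  report <- if (nrow(surv_all) > 0) {
    qc_summary(surv_all)
  } else {
    tibble(n_raw = 0L, n_clean = 0L, clean_nt = 0L,
           q20_pct = NA_real_, gc_pct = NA_real_, n_pct = NA_real_)
  }
  report$n_raw <- n_raw
  report$n_clean <- nrow(surv_all)

  structure(
    list(reads = survivors,
         mates = if (is.null(mates)) NULL else mates[keep, , drop = FALSE],
         keep = keep,
         detail = detail,
         report = report),
    class = "read_qc"
  )
}

#' Summary statistics of a read set
#'
#' Q20% is the percentage of bases with Phred quality >= 20; GC% and N%
#' are base-composition percentages over all bases.
#'
#' @param reads Read tibble.
#' @return One-row tibble: `n_raw`, `n_clean`, `clean_nt`, `q20_pct`,
#'   `gc_pct`, `n_pct`.
#' @export
qc_summary <- function(reads) {
  check_read_tbl(reads)
  if (nrow(reads) == 0) abort("cannot summarise an empty read set")
  total_nt <- sum(nchar(reads$bases))
  q20 <- sum(vapply(reads$quals, function(q) sum(q >= 20L), numeric(1)))
  tibble(
    n_raw = nrow(reads),
    n_clean = nrow(reads),
    clean_nt = total_nt,
    q20_pct = 100 * q20 / total_nt,
    gc_pct = 100 * sum(stringr::str_count(reads$bases, "[GC]")) / total_nt,
    n_pct = 100 * sum(stringr::str_count(reads$bases, "N")) / total_nt
  )
}

#' @export
print.read_qc <- function(x, ...) {
  cat(sprintf("<read_qc> %d of %d reads kept\n", x$report$n_clean, x$report$n_raw))
  print(x$report)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.read_qc <- function(x, ...) x$detail

#' @exportS3Method generics::glance
glance.read_qc <- function(x, ...) x$report
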