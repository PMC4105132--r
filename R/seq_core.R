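#' Drop sequences shorter than a minimum length
#'
#' Assembled transcripts below a length floor are discarded before any
#' downstream characterization; the conventional unigene floor is 200 nt.
#' The boundary is kept: only sequences strictly shorter than `min_nt`
#' are removed.
#'
#' @param records Sequence tibble (`id`, `seq`, ...).
#' @param min_nt Minimum retained length in nucleotides (default 200).
#' @return The input tibble restricted to rows with `nchar(seq) >= min_nt`,
#'   order preserved.
#' @export
filter_min_length <- function(records, min_nt = 200L) {
  check_seq_tbl(records)
  if (min_nt < 1) abort("`min_nt` must be >= 1")
  dplyr::filter(records, nchar(.data$seq) >= min_nt)
}

#' Assembly-level summary statistics
#'
#' Computes the usual single-row description of an assembly: sequence
#' count, total and mean length, N50 and GC fraction. N50 is the length
#' `L` at which the cumulative length of sequences sorted in descending
#' order first reaches half the total. The GC denominator excludes `N`
#' bases.
#'
#' @param records Sequence tibble.
#' @return One-row tibble: `n_sequences`, `total_nt`, `mean_length`,
#'   `n50`, `gc_fraction`.
#' @export
#' @examples
#' seqs <- tibble::tibble(id = c("a", "b"), seq = c("GGCC", "ATAT"))
#' assembly_stats(seqs)
assembly_stats <- function(records) {
  check_seq_tbl(records)
  if (nrow(records) == 0) abort("cannot summarise an empty assembly")
  len <- nchar(records$seq)
  total <- sum(len)
  gc <- sum(stringr::str_count(records$seq, "[GC]"))
  non_n <- total - sum(stringr::str_count(records$seq, "N"))
  tibble(
    n_sequences = nrow(records),
    total_nt = total,
    mean_length = total / nrow(records),
    n50 = n50(len),
    gc_fraction = gc / non_n
  )
}

#' N50 of a set of lengths
#'
#' @param lengths Positive integer vector of sequence lengths.
#' @return The N50 length.
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) abort("`lengths` must be non-empty")
  sorted <- sort(lengths, decreasing = TRUE)
  sorted[which(cumsum(sorted) >= sum(sorted) / 2)[1]]
}

#' Label unigenes as clusters or singletons
#'
#' Groups sequences connected by pairwise similarity strictly above
#' `threshold` into clusters (connected components) and labels components
#' of size >= 2 `CL1, CL2, ...` in order of first appearance in
#' `records`; all remaining sequences are singletons labelled
#' `Unigene1, Unigene2, ...` in record order.
#'
#' @param records Sequence tibble.
#' @param similarity_pairs Data frame with columns `id_a`, `id_b`,
#'   `identity` (fractions in `[0, 1]`).
#' @param threshold Similarity above which two sequences join one cluster
#'   (strict `>`; default 0.70).
#' @return Tibble `id`, `kind` (`"cluster"` or `"singleton"`), `label`,
#'   in record order.
#' @export
cluster_label <- function(records, similarity_pairs, threshold = 0.70) {
  check_seq_tbl(records)
  stopifnot(all(c("id_a", "id_b", "identity") %in% names(similarity_pairs)))
  if (any(similarity_pairs$identity < 0 | similarity_pairs$identity > 1)) {
    abort("pair identities must lie in [0, 1]")
  }
  ids <- records$id
  unknown <- setdiff(c(similarity_pairs$id_a, similarity_pairs$id_b), ids)
  if (length(unknown) > 0) {
    abort(sprintf("similarity pair references unknown id(s): %s",
                  paste(utils::head(unknown, 3), collapse = ", ")))
  }
  keep <- similarity_pairs$identity > threshold

  # union-find over record indices
  parent <- seq_along(ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ia <- match(similarity_pairs$id_a[keep], ids)
  ib <- match(similarity_pairs$id_b[keep], ids)
  for (k in seq_along(ia)) {
    ra <- find(ia[k]); rb <- find(ib[k])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_along(ids), find, integer(1))
  size <- table(root)
  clustered <- as.vector(size[as.character(root)] >= 2)

  label <- character(length(ids))
  kind <- ifelse(clustered, "cluster", "singleton")
  cl_roots <- unique(root[clustered])          # order of first appearance
  label[clustered] <- paste0("CL", match(root[clustered], cl_roots))
  label[!clustered] <- paste0("Unigene", seq_len(sum(!clustered)))
  tibble(id = ids, kind = kind, label = label)
}
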