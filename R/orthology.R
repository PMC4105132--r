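#' Filter peptide sequences by minimum length
#'
#' Short peptides give unreliable similarity search results, so proteome
#' sets are restricted to sequences of at least `min_aa` residues before
#' homology analysis. The boundary is inclusive: a 50-residue peptide is
#' kept under the default.
#'
#' @param peptides Sequence tibble of amino-acid sequences.
#' @param min_aa Minimum length in residues (default 50).
#' @return The input restricted to `nchar(seq) >= min_aa`.
#' @export
filter_peptides <- function(peptides, min_aa = 50L) {
  check_seq_tbl(peptides, "peptides")
  dplyr::filter(peptides, nchar(.data$seq) >= min_aa)
}

#' Queries with at least one significant hit
#'
#' One-directional homology: the set of query ids having any hit at or
#' below the E-value cutoff.
#'
#' @param hits Hit tibble (see [parse_blast_tab()]).
#' @param e_max E-value cutoff, inclusive (default `1e-5`).
#' @return Sorted character vector of unique query ids.
#' @export
one_directional <- function(hits, e_max = 1e-5) {
  sort(unique(hits$query_id[hits$evalue <= e_max]))
}

#' Reciprocal best hits between two sequence sets
#'
#' A pair `(a, b)` is reported iff `b` is the best hit of `a` in the
#' A-to-B search and `a` is the best hit of `b` in the B-to-A search,
#' with best hits resolved exactly as in [best_hit()] (highest bit
#' score, then lowest E-value, then input order). Such pairs are the
#' usual proxy for putative 1:1 orthologs; by construction each id
#' occurs in at most one pair.
#'
#' @param hits_ab Hit tibble of the A-to-B search.
#' @param hits_ba Hit tibble of the B-to-A search.
#' @param e_max E-value cutoff, inclusive (default `1e-5`).
#' @return Tibble `id_a`, `id_b`, sorted by `id_a`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, e_max = 1e-5) {
  fwd <- best_hit(hits_ab, e_max)
  rev <- best_hit(hits_ba, e_max)
  if (nrow(fwd) == 0 || nrow(rev) == 0) {
    return(tibble(id_a = character(), id_b = character()))
  }
  pairs <- inner_join(
    select(fwd, id_a = "query_id", id_b = "subject_id"),
    select(rev, id_b = "query_id", id_a = "subject_id"),
    by = c("id_a", "id_b")
  )
  arrange(pairs, .data$id_a)
}
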