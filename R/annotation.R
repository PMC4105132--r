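BLAST_COLS <- c("query_id", "subject_id", "pct_identity", "align_length",
                "mismatches", "gap_opens", "q_start", "q_end",
                "s_start", "s_end", "evalue", "bit_score")

#' Parse a 12-column BLAST tabular file
#'
#' Reads the standard `-outfmt 6` dialect (query, subject, identity,
#' alignment length, mismatches, gap opens, query/subject coordinates,
#' E-value, bit score). Comment lines starting with `#` are skipped.
#' Query coordinates are 1-based inclusive; `q_start > q_end` signals a
#' minus-strand (reverse-frame) alignment.
#'
#' @param path Path to a tab-separated hit file.
#' @return Tibble with one typed row per hit.
#' @export
parse_blast_tab <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(as_tibble(setNames(rep(list(character()), 12), BLAST_COLS)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1]
    abort(sprintf("parse error in %s at line %d: expected 12 columns, found %d",
                  path, lineno[bad], nf[bad]))
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  colnames(m) <- BLAST_COLS
  out <- as_tibble(m)
  num_cols <- setdiff(BLAST_COLS, c("query_id", "subject_id"))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      abort(sprintf("parse error in %s at line %d: non-numeric `%s`",
                    path, lineno[bad], col))
    }
    out[[col]] <- v
  }
  out
}

#' Best hit per query
#'
#' Drops hits with E-value above `e_max` (the cutoff is inclusive:
#' exactly `e_max` is kept), then retains for each query the hit with
#' the highest bit score; ties go to the lower E-value, then to input
#' order.
#'
#' @param hits Hit tibble (see [parse_blast_tab()]).
#' @param e_max E-value cutoff (default `1e-5`).
#' @return Tibble with one row per annotated query.
#' @export
best_hit <- function(hits, e_max = 1e-5) {
  qualifying <- dplyr::filter(hits, .data$evalue <= e_max)
  if (nrow(qualifying) == 0) return(qualifying)
  qualifying |>
    mutate(.ord = row_number()) |>
    group_by(.data$query_id) |>
    arrange(dplyr::desc(.data$bit_score), .data$evalue, .data$.ord,
            .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    arrange(.data$.ord) |>
    select(-".ord")
}

#' Merge per-database best hits under a priority order
#'
#' Each query is annotated by the first database in `priority` that has
#' a qualifying best hit for it; later databases never override earlier
#' ones. [best_hit()] is applied to each table, so raw hit tables may be
#' passed directly.
#'
#' @param per_db Named list of hit tibbles, e.g.
#'   `list(Nr = ..., SwissProt = ..., KEGG = ..., COG = ...)`.
#' @param priority Database names in decreasing priority; must all be
#'   names of `per_db`.
#' @param e_max E-value cutoff passed to [best_hit()].
#' @return Tibble of winning hits with a `source_db` column.
#' @export
merge_priority <- function(per_db,
                           priority = c("Nr", "SwissProt", "KEGG", "COG"),
                           e_max = 1e-5) {
  missing_db <- setdiff(priority, names(per_db))
  if (length(missing_db) > 0) {
    abort(sprintf("unknown database(s) in `priority`: %s",
                  paste(missing_db, collapse = ", ")))
  }
  taken <- character()
  out <- list()
  for (db in priority) {
    best <- best_hit(per_db[[db]], e_max)
    best <- dplyr::filter(best, !(.data$query_id %in% taken))
    if (nrow(best) > 0) {
      best$source_db <- db
      out[[db]] <- best
      taken <- c(taken, best$query_id)
    }
  }
  if (length(out) == 0) {
    empty <- as_tibble(setNames(rep(list(character()), 12), BLAST_COLS))
    empty$source_db <- character()
    return(empty)
  }
  bind_rows(out)
}

#' Extract coding regions from best translated hits
#'
#' Orientation comes from the query coordinates (`q_start > q_end` means
#' minus strand). The aligned interval is taken on the oriented strand,
#' anchored at its start codon position (translated searches report
#' alignments at codon boundaries) and trimmed at the 3' end to a whole
#' number of codons.
#'
#' @param records Sequence tibble of the unigenes.
#' @param hits Tibble of best hits, one per query (e.g. from
#'   [merge_priority()]); a `source_db` column is carried through if
#'   present.
#' @return Annotation tibble: `query_id`, `source_db`, `orientation`
#'   (`"+"`/`"-"`), `cds_start`, `cds_end` (1-based inclusive on the
#'   oriented strand) and `cds_seq` (length divisible by 3).
#' @export
extract_cds <- function(records, hits) {
  check_seq_tbl(records)
  if (anyDuplicated(hits$query_id)) {
    abort("`hits` must contain at most one hit per query (see best_hit())")
  }
  unknown <- setdiff(hits$query_id, records$id)
  if (length(unknown) > 0) {
    abort(sprintf("hit references unknown unigene(s): %s",
                  paste(utils::head(unknown, 3), collapse = ", ")))
  }
  if (nrow(hits) == 0) {
    return(tibble(query_id = character(), source_db = character(),
                  orientation = character(), cds_start = integer(),
                  cds_end = integer(), cds_seq = character()))
  }
  src <- if ("source_db" %in% names(hits)) hits$source_db else
    rep("blast", nrow(hits))
  seqs <- records$seq[match(hits$query_id, records$id)]
  L <- nchar(seqs)
  minus <- hits$q_start > hits$q_end
  orientation <- ifelse(minus, "-", "+")
  oriented <- ifelse(minus, revcomp(seqs), seqs)
  s <- ifelse(minus, L - hits$q_start + 1, hits$q_start)
  e <- ifelse(minus, L - hits$q_end + 1, hits$q_end)
  if (any(s < 1 | e > L)) abort("hit coordinates fall outside the unigene")
  n_codons <- (e - s + 1) %/% 3
  if (any(n_codons < 1)) {
    abort(sprintf("aligned interval shorter than one codon for query '%s'",
                  hits$query_id[which(n_codons < 1)[1]]))
  }
  cds_end <- s + 3 * n_codons - 1
  tibble(
    query_id = hits$query_id,
    source_db = src,
    orientation = orientation,
    cds_start = as.integer(s),
    cds_end = as.integer(cds_end),
    cds_seq = substr(oriented, s, cds_end)
  )
}

#' Longest open reading frame across six frames
#'
#' Deterministic fallback used to orient and annotate unigenes without
#' any database hit: every maximal stop-free codon run in the six
#' reading frames (bounded by stop codons or the sequence ends) is
#' considered, and the longest is reported when strictly longer than
#' `min_nt`. Ties prefer the plus strand, then the lower frame offset,
#' then the earlier start. Results carry `source_db = "fallback"`.
#'
#' @param records Sequence tibble.
#' @param min_nt Minimum ORF length in nucleotides, strict (default 150).
#' @return Annotation tibble as in [extract_cds()]; unigenes without a
#'   qualifying ORF are absent.
#' @export
longest_orf <- function(records, min_nt = 150L) {
  check_seq_tbl(records)
  one <- function(seq) {
    best <- NULL
    for (strand in c("+", "-")) {
      sseq <- if (strand == "+") seq else revcomp(seq)
      L <- nchar(sseq)
      for (off in 0:2) {
        n_cod <- (L - off) %/% 3L
        if (n_cod < 1) next
        starts <- off + 3L * (seq_len(n_cod) - 1L) + 1L
        codons <- substring(sseq, starts, starts + 2L)
        is_stop <- codons %in% STOP_CODONS
        # maximal stop-free runs
        r <- rle(!is_stop)
        ends_idx <- cumsum(r$lengths)
        starts_idx <- ends_idx - r$lengths + 1L
        for (k in which(r$values)) {
          len_nt <- 3L * r$lengths[k]
          cand_start <- starts[starts_idx[k]]
          if (is.null(best) || len_nt > best$len) {
            best <- list(len = len_nt, strand = strand,
                         start = cand_start, end = cand_start + len_nt - 1L,
                         seq = substr(sseq, cand_start, cand_start + len_nt - 1L))
          }
        }
      }
    }
    best
  }
  out <- purrr::map(seq_len(nrow(records)), function(i) {
    b <- one(records$seq[[i]])
    if (is.null(b) || b$len <= min_nt) return(NULL)
    tibble(query_id = records$id[[i]], source_db = "fallback",
           orientation = b$strand, cds_start = b$start, cds_end = b$end,
           cds_seq = b$seq)
  })
  out <- purrr::compact(out)
  if (length(out) == 0) {
    return(tibble(query_id = character(), source_db = character(),
                  orientation = character(), cds_start = integer(),
                  cds_end = integer(), cds_seq = character()))
  }
  bind_rows(out)
}

#' Annotate unigenes from several databases with an ORF fallback
#'
#' Convenience wrapper: merges per-database hits under the priority
#' order, extracts coding regions from the winning hits, and runs the
#' longest-ORF fallback on the remaining unigenes.
#'
#' @inheritParams merge_priority
#' @param records Sequence tibble of the unigenes.
#' @param fallback Run [longest_orf()] on unannotated unigenes?
#' @param min_orf_nt Strict ORF length floor for the fallback.
#' @return Annotation tibble (see [extract_cds()]).
#' @export
annotate_unigenes <- function(records, per_db,
                              priority = c("Nr", "SwissProt", "KEGG", "COG"),
                              e_max = 1e-5, fallback = TRUE,
                              min_orf_nt = 150L) {
  merged <- merge_priority(per_db, priority, e_max)
  ann <- extract_cds(records, merged)
  if (fallback) {
    rest <- dplyr::filter(records, !(.data$id %in% ann$query_id))
    ann <- bind_rows(ann, longest_orf(rest, min_orf_nt))
  }
  ann
}

#' Per-database annotation counts and their union
#'
#' @param sets Named list of character vectors of annotated query ids
#'   (one vector per database).
#' @return Tibble with one row per database plus a final `union` row
#'   counting queries annotated by at least one database.
#' @export
annotation_summary <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("`sets` must be a named list of id vectors")
  }
  per_db <- tibble(
    db = names(sets),
    n_annotated = unname(vapply(sets, function(x) length(unique(x)), integer(1)))
  )
  bind_rows(per_db,
            tibble(db = "union",
                   n_annotated = length(unique(unlist(sets, use.names = FALSE)))))
}
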