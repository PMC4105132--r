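# Independent oracles, coded directly from the definitions and kept
# deliberately separate from the package's implementations.

# --- N50: explicit scan of descending cumulative sums ------------------
n50_oracle <- function(lengths) {
  sorted <- sort(lengths, decreasing = TRUE)
  half <- sum(lengths) / 2
  acc <- 0
  for (L in sorted) {
    acc <- acc + L
    if (acc >= half) return(L)
  }
}

# --- Wright's Nc, hard-coded synonymous families -----------------------
# Families written out by hand (standard nuclear code) so the oracle does
# not share the package's Biostrings-derived tables.
ORACLE_FAMILIES <- list(
  `2` = list(Phe = c("TTT", "TTC"), Tyr = c("TAT", "TAC"),
             His = c("CAT", "CAC"), Gln = c("CAA", "CAG"),
             Asn = c("AAT", "AAC"), Lys = c("AAA", "AAG"),
             Asp = c("GAT", "GAC"), Glu = c("GAA", "GAG"),
             Cys = c("TGT", "TGC")),
  `3` = list(Ile = c("ATT", "ATC", "ATA")),
  `4` = list(Val = c("GTT", "GTC", "GTA", "GTG"),
             Pro = c("CCT", "CCC", "CCA", "CCG"),
             Thr = c("ACT", "ACC", "ACA", "ACG"),
             Ala = c("GCT", "GCC", "GCA", "GCG"),
             Gly = c("GGT", "GGC", "GGA", "GGG")),
  `6` = list(Leu = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
             Ser = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
             Arg = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"))
)

nc_oracle <- function(cds) {
  n_cod <- nchar(cds) %/% 3
  codons <- substring(cds, 3 * seq_len(n_cod) - 2, 3 * seq_len(n_cod))
  f_bar <- c(`2` = NA_real_, `3` = NA_real_, `4` = NA_real_, `6` = NA_real_)
  n_class <- c(`2` = 0, `3` = 0, `4` = 0, `6` = 0)
  for (k in names(ORACLE_FAMILIES)) {
    fs <- c()
    for (fam in ORACLE_FAMILIES[[k]]) {
      x <- vapply(fam, function(cod) sum(codons == cod), numeric(1))
      n <- sum(x)
      n_class[k] <- n_class[k] + n
      if (n >= 2) {
        p <- x / n
        fs <- c(fs, (n * sum(p^2) - 1) / (n - 1))
      }
    }
    if (length(fs) > 0) f_bar[k] <- mean(fs)
  }
  if (any(is.na(f_bar))) {
    ok <- !is.na(f_bar)
    f_bar[!ok] <- sum(f_bar[ok] * n_class[ok]) / sum(n_class[ok])
  }
  nc <- 2 + 9 / f_bar[["2"]] + 1 / f_bar[["3"]] + 5 / f_bar[["4"]] + 3 / f_bar[["6"]]
  min(max(nc, 20), 61)
}

# --- SSR detection: brute-force enumeration ----------------------------
# Every (position, motif length) pair is tested by repeated substring
# comparison; left-maximal runs at/above threshold with a primitive
# motif survive, then the same greedy left-to-right overlap suppression
# is applied by explicit loop.
ssr_oracle <- function(seq, thresholds = c(`2` = 6, `3` = 5, `4` = 4,
                                           `5` = 4, `6` = 4)) {
  L <- nchar(seq)
  rows <- list()
  for (m in 2:6) {
    thr <- thresholds[[as.character(m)]]
    if (L < m * thr) next
    for (i in seq_len(L - m * thr + 1)) {
      motif <- substr(seq, i, i + m - 1)
      if (grepl("N", motif, fixed = TRUE)) next
      # primitive motif: no proper divisor period
      primitive <- TRUE
      for (d in seq_len(m - 1)) {
        if (m %% d == 0 &&
            paste(rep(substr(motif, 1, d), m / d), collapse = "") == motif) {
          primitive <- FALSE
          break
        }
      }
      if (!primitive) next
      # left-maximal: no identical motif copy immediately before
      if (i > m && substr(seq, i - m, i - 1) == motif) next
      r <- 1
      while (i + (r + 1) * m - 1 <= L &&
             substr(seq, i + r * m, i + (r + 1) * m - 1) == motif) {
        r <- r + 1
      }
      if (r >= thr) {
        rows[[length(rows) + 1]] <-
          data.frame(motif = motif, repeats = r, start = i,
                     end = i + r * m - 1, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(motif = character(), repeats = integer(),
                      start = integer(), end = integer()))
  }
  cand <- do.call(rbind, rows)
  cand <- cand[order(cand$start, -(cand$end - cand$start), nchar(cand$motif)), ]
  out <- list()
  last_end <- 0
  for (j in seq_len(nrow(cand))) {
    if (cand$start[j] > last_end) {
      out[[length(out) + 1]] <- cand[j, ]
      last_end <- cand$end[j]
    }
  }
  do.call(rbind, out)
}

# --- Reciprocal best hits: exhaustive base-R search --------------------
rbh_oracle <- function(hits_ab, hits_ba, e_max = 1e-5) {
  best_of <- function(h) {
    h <- h[h$evalue <= e_max, , drop = FALSE]
    out <- list()
    for (q in unique(h$query_id)) {
      sub <- h[h$query_id == q, , drop = FALSE]
      ord <- order(-sub$bit_score, sub$evalue, seq_len(nrow(sub)))
      out[[q]] <- sub$subject_id[ord[1]]
    }
    out
  }
  fa <- best_of(as.data.frame(hits_ab))
  fb <- best_of(as.data.frame(hits_ba))
  pairs <- list()
  for (a in names(fa)) {
    b <- fa[[a]]
    if (!is.null(fb[[b]]) && fb[[b]] == a) {
      pairs[[length(pairs) + 1]] <- data.frame(id_a = a, id_b = b)
    }
  }
  if (length(pairs) == 0) {
    return(data.frame(id_a = character(), id_b = character()))
  }
  out <- do.call(rbind, pairs)
  out[order(out$id_a), , drop = FALSE]
}

# --- misc helpers ------------------------------------------------------
random_seq <- function(L, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

seq_tbl <- function(...) {
  s <- c(...)
  tibble::tibble(id = if (is.null(names(s))) paste0("s", seq_along(s)) else names(s),
                 seq = unname(s))
}

read_tbl <- function(bases, quals = NULL, prefix = "r") {
  if (is.null(quals)) quals <- lapply(nchar(bases), function(L) rep(35L, L))
  if (!is.list(quals)) quals <- list(quals)
  tibble::tibble(id = paste0(prefix, seq_along(bases)),
                 bases = bases, quals = quals)
}

# naive exact k-mer overlap identity, used only to fabricate similarity
# pairs for clustering tests
kmer_identity <- function(a, b, k = 8) {
  kmers <- function(s) {
    if (nchar(s) < k) return(character())
    unique(substring(s, seq_len(nchar(s) - k + 1), k:nchar(s)))
  }
  ka <- kmers(a); kb <- kmers(b)
  if (length(ka) == 0 || length(kb) == 0) return(0)
  length(intersect(ka, kb)) / min(length(ka), length(kb))
}
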