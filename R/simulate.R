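# Seeded generators for every input the pipeline consumes, each with a
# machine-readable truth table. Every generator draws from its own RNG
# scope (withr::with_seed), so identical arguments give identical output
# regardless of the caller's RNG state.

random_dna <- function(n, len, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(len, function(L) {
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

#' Generate a synthetic transcriptome
#'
#' Sequence lengths are drawn from a log-normal tuned to the requested
#' mean (assembled unigene sets typically have means around 571 nt with
#' a long right tail) and floored at `min_length`; bases are i.i.d. with
#' the requested GC content (default 0.5126).
#'
#' @param n Number of sequences.
#' @param mean_length Target mean length in nt (default 571).
#' @param sdlog Log-scale standard deviation of the length distribution
#'   (default 0.7).
#' @param gc Target GC fraction (default 0.5126).
#' @param min_length Length floor in nt (default 200).
#' @param seed Integer seed; identical seeds give identical output.
#' @return Sequence tibble (`id`, `seq`, `description`).
#' @export
gen_transcriptome <- function(n = 1000L, mean_length = 571, sdlog = 0.7,
                              gc = 0.5126, min_length = 200L, seed = 1L) {
  if (n < 1 || mean_length <= 0 || gc <= 0 || gc >= 1 || sdlog <= 0) {
    abort("invalid generator parameters")
  }
  withr::with_seed(seed, {
    len <- pmax(min_length,
                round(rlnorm(n, meanlog = log(mean_length) - sdlog^2 / 2,
                             sdlog = sdlog)))
    tibble(
      id = sprintf("Unigene%d", seq_len(n)),
      seq = random_dna(n, len, gc),
      description = "synthetic transcript"
    )
  })
}

#' Plant perfect SSRs into sequences with exact ground truth
#'
#' Inserts perfect tandem repeats at random positions, overwriting the
#' host sequence in place (length preserved). One guard base on each
#' flank is rewritten so the planted run can neither extend nor change
#' phase, making the recorded repeat count exact. Host sequences that
#' already contain a detectable SSR are re-drawn from the background
#' before planting so the truth table is the complete hit list.
#'
#' @param records Sequence tibble to plant into.
#' @param plan Data frame with columns `motif`, `repeats`, `count` (how
#'   many runs of that motif/repeat combination to plant).
#' @param seed Integer seed.
#' @param thresholds Detection thresholds used for the background sweep
#'   (see [find_ssrs()]).
#' @return List with `records` (modified tibble) and `truth` (tibble
#'   `seq_id`, `motif`, `repeats`, `start`, `end`).
#' @export
plant_ssrs <- function(records, plan, seed = 1L,
                       thresholds = DEFAULT_SSR_THRESHOLDS) {
  check_seq_tbl(records)
  stopifnot(all(c("motif", "repeats", "count") %in% names(plan)))
  withr::with_seed(seed, {
    seqs <- records$seq
    gc_bg <- mean(gc_content(seqs))
    # scrub accidental background SSRs so planted truth is exhaustive
    for (attempt in 1:25) {
      bg <- find_ssrs(tibble(id = records$id, seq = seqs), thresholds)
      if (nrow(bg) == 0) break
      for (k in seq_len(nrow(bg))) {
        i <- match(bg$seq_id[k], records$id)
        w <- bg$end[k] - bg$start[k] + 1L
        substr(seqs[i], bg$start[k], bg$end[k]) <- random_dna(1, w, gc_bg)
      }
    }

    jobs <- plan[rep(seq_len(nrow(plan)), plan$count), c("motif", "repeats")]
    jobs$motif <- toupper(jobs$motif)
    occupied <- lapply(seq_along(seqs), function(i) integer())
    truth <- list()
    for (k in seq_len(nrow(jobs))) {
      motif <- jobs$motif[k]
      reps <- jobs$repeats[k]
      m <- nchar(motif)
      run_len <- m * reps
      placed <- FALSE
      for (try in 1:200) {
        i <- sample(length(seqs), 1)
        L <- nchar(seqs[i])
        if (L < run_len + 4L) next
        start <- sample(seq(2L, L - run_len), 1)
        span <- seq(start - 1L, start + run_len)   # run plus guard bases
        if (length(intersect(span, occupied[[i]])) > 0) next
        run <- strrep(motif, reps)
        last <- substr(motif, m, m)
        first <- substr(motif, 1, 1)
        guard_l <- sample(setdiff(c("A", "C", "G", "T"), last), 1)
        guard_r <- sample(setdiff(c("A", "C", "G", "T"), first), 1)
        substr(seqs[i], start - 1L, start + run_len) <-
          paste0(guard_l, run, guard_r)
        occupied[[i]] <- c(occupied[[i]], span)
        truth[[length(truth) + 1L]] <- tibble(
          seq_id = records$id[i], motif = motif, repeats = as.integer(reps),
          start = as.integer(start), end = as.integer(start + run_len - 1L)
        )
        placed <- TRUE
        break
      }
      if (!placed) {
        abort(sprintf("could not place %s x %d: sequences too short or too full",
                      motif, reps))
      }
    }
    records$seq <- seqs
    list(records = records,
         truth = if (length(truth) > 0) bind_rows(truth) else
           tibble(seq_id = character(), motif = character(),
                  repeats = integer(), start = integer(), end = integer()))
  })
}

# Third-position G/C indicator per codon, used to tune GC3.
codon_gc3_flag <- function(codons) substr(codons, 3, 3) %in% c("G", "C")

#' Generate coding sequences with controlled GC3 and bias strength
#'
#' Amino acids cycle through the 18 degenerate families (balanced
#' counts, shuffled order), and each synonymous codon is drawn from a
#' family-level distribution that interpolates between composition-driven
#' usage (bias 0: third-position weights `gc3_target` for G/C-ending
#' codons, `1 - gc3_target` otherwise) and exclusive use of one
#' preferred codon per family (bias 1). Preferred codons are the
#' alphabetically first G/C-ending codon of each family, so strong bias
#' also raises GC3 — the coupling seen in compositionally biased
#' genomes.
#'
#' @param n_genes Number of genes.
#' @param codons_per_gene Codons per gene.
#' @param gc3_target Target third-position GC fraction in `(0, 1)`.
#' @param bias_strength Scalar or per-gene vector in `[0, 1]`.
#' @param seed Integer seed.
#' @return List with `cds` (sequence tibble) and `truth` (tibble `id`,
#'   `gc3_target`, `bias`, `n_codons`).
#' @export
gen_cds_set <- function(n_genes = 200L, codons_per_gene = 500L,
                        gc3_target = 0.5, bias_strength = 0, seed = 1L) {
  if (gc3_target <= 0 || gc3_target >= 1) abort("`gc3_target` must be in (0, 1)")
  if (any(bias_strength < 0 | bias_strength > 1)) {
    abort("`bias_strength` must lie in [0, 1]")
  }
  bias <- rep_len(bias_strength, n_genes)
  degen <- names(FAMILY_SIZE)[FAMILY_SIZE >= 2]
  fams <- CODON_FAMILIES[degen]
  preferred <- vapply(fams, function(cod) {
    gcod <- sort(cod[codon_gc3_flag(cod)])
    if (length(gcod) > 0) gcod[1] else sort(cod)[1]
  }, character(1))
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n_genes), function(g) {
      aa <- sample(rep_len(degen, codons_per_gene))
      cods <- character(codons_per_gene)
      for (a in degen) {
        pos <- which(aa == a)
        if (length(pos) == 0) next
        fam <- fams[[a]]
        w3 <- ifelse(codon_gc3_flag(fam), gc3_target, 1 - gc3_target)
        w <- (1 - bias[g]) * w3 / sum(w3) + bias[g] * (fam == preferred[[a]])
        cods[pos] <- sample(fam, length(pos), replace = TRUE, prob = w)
      }
      paste(cods, collapse = "")
    }, character(1))
    cds <- tibble(id = sprintf("gene%d", seq_len(n_genes)), seq = seqs,
                  description = "synthetic CDS")
    truth <- tibble(id = cds$id, gc3_target = gc3_target, bias = bias,
                    n_codons = codons_per_gene)
    list(cds = cds, truth = truth)
  })
}

#' Generate paired reads with planted QC failures
#'
#' Samples paired 90-nt reads from the given transcripts (fragments on
#' the forward strand; mate 2 is the reverse complement of the fragment
#' end). A configured fraction of pairs is made to fail each cleaning
#' rule — too many `N` bases in mate 1, or too many sub-Q20 bases — with
#' a clear margin, and an optional boundary class sits exactly at the
#' 10% low-quality limit (and therefore passes). Passing reads carry no
#' `N` and qualities of at least 20.
#'
#' @param records Sequence tibble of transcripts.
#' @param n_pairs Number of read pairs.
#' @param read_length Read length in nt (default 90).
#' @param fail_n_rate Fraction of pairs failing the N rule.
#' @param fail_q_rate Fraction of pairs failing the quality rule.
#' @param boundary_rate Fraction of pairs sitting exactly at the 10%
#'   low-quality boundary (labelled pass).
#' @param seed Integer seed.
#' @return List with `reads`, `mates` (read tibbles) and `truth`
#'   (tibble `pair_id`, `label`, `pass`).
#' @export
gen_reads <- function(records, n_pairs = 1000L, read_length = 90L,
                      fail_n_rate = 0.05, fail_q_rate = 0.05,
                      boundary_rate = 0.02, seed = 1L) {
  check_seq_tbl(records)
  if (fail_n_rate + fail_q_rate + boundary_rate > 1) {
    abort("failure rates must sum to at most 1")
  }
  long_enough <- records[nchar(records$seq) >= read_length + 10L, ]
  if (nrow(long_enough) == 0) {
    abort("no transcript is long enough to sample reads from")
  }
  if (nrow(long_enough) < nrow(records)) {
    warn(sprintf("%d transcript(s) shorter than read_length skipped",
                 nrow(records) - nrow(long_enough)))
  }
  withr::with_seed(seed, {
    weights <- nchar(long_enough$seq)
    src <- sample(nrow(long_enough), n_pairs, replace = TRUE, prob = weights)
    frag_len <- pmin(nchar(long_enough$seq)[src],
                     read_length + sample(0:160, n_pairs, replace = TRUE))
    start <- vapply(seq_len(n_pairs), function(i) {
      sample(nchar(long_enough$seq)[src[i]] - frag_len[i] + 1L, 1)
    }, integer(1))
    frag <- substr(long_enough$seq[src], start, start + frag_len - 1L)
    r1 <- substr(frag, 1L, read_length)
    r2 <- revcomp(substr(frag, frag_len - read_length + 1L, frag_len))

    n_fail_n <- round(fail_n_rate * n_pairs)
    n_fail_q <- round(fail_q_rate * n_pairs)
    n_bound <- round(boundary_rate * n_pairs)
    label <- rep("pass", n_pairs)
    idx <- sample(n_pairs)
    label[idx[seq_len(n_fail_n)]] <- "fail_n"
    label[idx[n_fail_n + seq_len(n_fail_q)]] <- "fail_q"
    label[idx[n_fail_n + n_fail_q + seq_len(n_bound)]] <- "boundary"

    good_quals <- function() sample(30:40, read_length, replace = TRUE)
    quals1 <- lapply(seq_len(n_pairs), function(i) good_quals())
    quals2 <- lapply(seq_len(n_pairs), function(i) good_quals())
    n_over <- ceiling(0.05 * read_length) + 1L   # clearly over 5%
    q_over <- floor(0.10 * read_length) + 1L     # clearly over 10%
    q_exact <- floor(0.10 * read_length)         # exactly at 10%
    for (i in which(label == "fail_n")) {
      pos <- sample(read_length, n_over)
      s <- strsplit(r1[i], "")[[1]]; s[pos] <- "N"
      r1[i] <- paste(s, collapse = "")
    }
    for (i in which(label == "fail_q")) {
      pos <- sample(read_length, q_over)
      quals1[[i]][pos] <- sample(2:19, q_over, replace = TRUE)
    }
    for (i in which(label == "boundary")) {
      pos <- sample(read_length, q_exact)
      quals1[[i]][pos] <- sample(2:19, q_exact, replace = TRUE)
    }

    pair_id <- sprintf("read%d", seq_len(n_pairs))
    list(
      reads = tibble(id = paste0(pair_id, "/1"), bases = r1, quals = quals1),
      mates = tibble(id = paste0(pair_id, "/2"), bases = r2, quals = quals2),
      truth = tibble(pair_id = pair_id, label = label,
                     pass = label %in% c("pass", "boundary"))
    )
  })
}

#' Generate reciprocal hit tables with planted 1:1 orthologs
#'
#' Builds two BLAST-tabular-shaped hit tibbles between sequence sets
#' `a1..a_n` and `b1..b_n`. Planted ortholog pairs receive top-scoring
#' reciprocal hits (bit score ~300, optionally jittered by
#' `score_noise`); decoy hits to random partners score far lower, so at
#' zero noise reciprocal-best-hit search recovers exactly the planted
#' pairs.
#'
#' @param n_a,n_b Set sizes.
#' @param n_orthologs Number of planted 1:1 pairs
#'   (`<= min(n_a, n_b)`).
#' @param score_noise Standard deviation of Gaussian jitter on planted
#'   bit scores.
#' @param decoy_rate Expected number of decoy hits per sequence.
#' @param seed Integer seed.
#' @return List with `hits_ab`, `hits_ba` and `truth` (tibble `id_a`,
#'   `id_b`).
#' @export
gen_ortholog_tables <- function(n_a = 100L, n_b = 100L, n_orthologs = 50L,
                                score_noise = 0, decoy_rate = 0.5, seed = 1L) {
  if (n_orthologs > min(n_a, n_b)) abort("`n_orthologs` exceeds the set sizes")
  if (decoy_rate < 0 || score_noise < 0) abort("rates must be non-negative")
  ids_a <- sprintf("a%d", seq_len(n_a))
  ids_b <- sprintf("b%d", seq_len(n_b))
  hit_row <- function(q, s, bit) {
    tibble(query_id = q, subject_id = s, pct_identity = 90, align_length = 200,
           mismatches = 20, gap_opens = 0, q_start = 1, q_end = 600,
           s_start = 1, s_end = 200, evalue = 2^(-bit / 2), bit_score = bit)
  }
  withr::with_seed(seed, {
    truth <- tibble(id_a = ids_a[seq_len(n_orthologs)],
                    id_b = ids_b[seq_len(n_orthologs)])
    bit_ab <- 300 + rnorm(n_orthologs, sd = score_noise)
    bit_ba <- 300 + rnorm(n_orthologs, sd = score_noise)
    ab <- hit_row(truth$id_a, truth$id_b, bit_ab)
    ba <- hit_row(truth$id_b, truth$id_a, bit_ba)
    n_dec_ab <- rpois(1, decoy_rate * n_a)
    n_dec_ba <- rpois(1, decoy_rate * n_b)
    if (n_dec_ab > 0) {
      ab <- bind_rows(ab, hit_row(sample(ids_a, n_dec_ab, replace = TRUE),
                                  sample(ids_b, n_dec_ab, replace = TRUE),
                                  runif(n_dec_ab, 60, 150)))
    }
    if (n_dec_ba > 0) {
      ba <- bind_rows(ba, hit_row(sample(ids_b, n_dec_ba, replace = TRUE),
                                  sample(ids_a, n_dec_ba, replace = TRUE),
                                  runif(n_dec_ba, 60, 150)))
    }
    list(hits_ab = ab, hits_ba = ba, truth = truth)
  })
}

#' Generate expression records coupled to codon bias
#'
#' Fragment counts are Poisson draws whose log10 mean is linearly
#' coupled to each gene's true bias strength (`coupling` in `[-1, 1]`;
#' 0 means independence), plus log-normal gene-level noise. Together
#' with [gen_cds_set()] this creates data where codon bias and
#' expression co-vary to a known degree.
#'
#' @param cds_truth Truth tibble from [gen_cds_set()] (`id`, `bias`,
#'   `n_codons`).
#' @param coupling Strength of the bias-expression link in `[-1, 1]`.
#' @param log_mean Baseline log10 mean fragment count (default 2).
#' @param log_sd Log10-scale gene noise (default 0.4).
#' @param seed Integer seed.
#' @return Expression tibble: `id`, `fragment_count`, `length`.
#' @export
gen_expression <- function(cds_truth, coupling = 0, log_mean = 2,
                           log_sd = 0.4, seed = 1L) {
  stopifnot(all(c("id", "bias", "n_codons") %in% names(cds_truth)))
  if (coupling < -1 || coupling > 1) abort("`coupling` must lie in [-1, 1]")
  withr::with_seed(seed, {
    b <- cds_truth$bias
    b_scaled <- if (stats::sd(b) > 0) (b - mean(b)) / stats::sd(b) else b * 0
    log_lambda <- log_mean + coupling * b_scaled + rnorm(length(b), sd = log_sd)
    tibble(
      id = cds_truth$id,
      fragment_count = rpois(length(b), 10^log_lambda),
      length = 3L * cds_truth$n_codons
    )
  })
}
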