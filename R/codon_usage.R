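#' Count codons of a coding sequence
#'
#' Counts frame-0 triplets of one CDS. A trailing partial codon and any
#' codon containing `N` are not counted but reported in the `n_skipped`
#' attribute. Stop codons are counted (they are part of the 64-codon
#' table) but excluded from all downstream bias statistics.
#'
#' @param cds A single nucleotide string.
#' @return Tibble of 64 rows (`codon`, `amino_acid`, `count`) with
#'   attributes `n_codons` (total counted, including stops) and
#'   `n_skipped`.
#' @export
#' @examples
#' count_codons("ATGGAAGAAGAG")
count_codons <- function(cds) {
  if (!is.character(cds) || length(cds) != 1) abort("`cds` must be a single string")
  cods <- codon_vector(toupper(cds))
  valid <- cods %in% CODON_TABLE$codon
  counts <- table(factor(cods[valid], levels = CODON_TABLE$codon))
  out <- tibble(
    codon = CODON_TABLE$codon,
    amino_acid = CODON_TABLE$amino_acid,
    count = as.integer(counts)
  )
  attr(out, "n_codons") <- sum(out$count)
  attr(out, "n_skipped") <- (sum(!valid)) + (nchar(cds) %% 3 > 0)
  out
}

# Accept either a count table from count_codons() or a named count
# vector; return counts aligned to CODON_TABLE order.
as_codon_counts <- function(counts) {
  if (is.data.frame(counts)) {
    stopifnot(all(c("codon", "count") %in% names(counts)))
    v <- counts$count[match(CODON_TABLE$codon, counts$codon)]
  } else {
    v <- counts[CODON_TABLE$codon]
  }
  v[is.na(v)] <- 0
  stats::setNames(as.numeric(v), CODON_TABLE$codon)
}

#' Relative synonymous codon usage
#'
#' RSCU of a codon is its observed count divided by the count expected
#' if all codons of its synonymous family were used equally:
#' `RSCU_i = X_i / (sum(X) / k)` for a `k`-fold family. Values sum to
#' `k` within each family. Stop codons and families with zero total get
#' `NA`.
#'
#' @param counts A codon count table ([count_codons()]) or named vector.
#' @return Tibble `codon`, `amino_acid`, `count`, `rscu`.
#' @export
rscu <- function(counts) {
  v <- as_codon_counts(counts)
  if (sum(v) == 0) abort("no codons counted")
  out <- tibble(codon = CODON_TABLE$codon,
                amino_acid = CODON_TABLE$amino_acid,
                count = unname(v))
  out |>
    group_by(.data$amino_acid) |>
    mutate(rscu = dplyr::if_else(
      .data$amino_acid == "*" | sum(.data$count) == 0,
      NA_real_,
      .data$count / (sum(.data$count) / dplyr::n())
    )) |>
    ungroup()
}

#' GC content at the third codon position
#'
#' Fraction of complete codons whose third base is G or C; codons
#' containing `N` are excluded from both numerator and denominator.
#'
#' @param cds One or more nucleotide strings.
#' @return Numeric vector of GC3 fractions.
#' @export
gc3 <- function(cds) {
  vapply(cds, function(s) {
    cods <- codon_vector(toupper(s))
    cods <- cods[cods %in% CODON_TABLE$codon]
    if (length(cods) == 0) abort("no complete N-free codon in `cds`")
    mean(substr(cods, 3, 3) %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' GC content of a sequence (N excluded)
#' @param seq One or more nucleotide strings.
#' @return Numeric vector of GC fractions over non-N bases.
#' @export
gc_content <- function(seq) {
  gc <- stringr::str_count(toupper(seq), "[GC]")
  at <- stringr::str_count(toupper(seq), "[AT]")
  gc / (gc + at)
}

# Per-amino-acid homozygosity estimates.
#   corrected:  F = (n * sum(p^2) - 1) / (n - 1), needs n >= 2 (Wright 1990)
#   population: F = sum(p^2), needs n >= 1
family_homozygosity <- function(v, method) {
  vapply(names(CODON_FAMILIES), function(aa) {
    x <- v[CODON_FAMILIES[[aa]]]
    n <- sum(x)
    if (method == "corrected") {
      if (n < 2) return(NA_real_)
      (n * sum((x / n)^2) - 1) / (n - 1)
    } else {
      if (n < 1) return(NA_real_)
      sum((x / n)^2)
    }
  }, numeric(1))
}

#' Wright's effective number of codons (Nc)
#'
#' Gene-level codon bias summary ranging from 20 (one codon per amino
#' acid) to 61 (uniform synonymous usage). Per amino acid, the
#' homozygosity is estimated as `F = (n * sum(p^2) - 1) / (n - 1)`
#' (`n` = codons observed for that amino acid); estimates are averaged
#' within each degeneracy class (2-, 3-, 4- and 6-fold, with the
#' six-fold families Leu/Ser/Arg kept as their own class), and
#'
#' `Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`.
#'
#' Amino acids observed fewer than 2 times are omitted from their class
#' mean; a class with no computable member falls back to the
#' count-weighted mean of the other classes' homozygosities. The result
#' is clamped to `[20, 61]` (the finite-sample estimator can stray
#' outside the theoretical range).
#'
#' @param counts A codon count table or named count vector.
#' @param homozygosity `"corrected"` (Wright's `(n-1)`-denominator
#'   estimator, the default) or `"population"` (`sum(p^2)`, useful for
#'   evaluating analytic limits).
#' @param clamp Clamp the result to `[20, 61]`? Default `TRUE`.
#' @return A single Nc value.
#' @export
effective_number_of_codons <- function(counts,
                                       homozygosity = c("corrected", "population"),
                                       clamp = TRUE) {
  homozygosity <- match.arg(homozygosity)
  v <- as_codon_counts(counts)
  v[STOP_CODONS] <- 0                      # stops never enter bias statistics
  f_hat <- family_homozygosity(v, homozygosity)
  fam_n <- vapply(CODON_FAMILIES, function(cod) sum(v[cod]), numeric(1))

  classes <- c("2", "3", "4", "6")
  f_bar <- numeric(length(classes))
  n_class <- numeric(length(classes))
  names(f_bar) <- names(n_class) <- classes
  for (k in classes) {
    aas <- DEGENERACY_CLASSES[[k]]
    ok <- aas[!is.na(f_hat[aas])]
    f_bar[k] <- if (length(ok) > 0) mean(f_hat[ok]) else NA_real_
    n_class[k] <- sum(fam_n[aas])
  }
  if (all(is.na(f_bar))) {
    abort("too few codons: no degeneracy class has a computable homozygosity")
  }
  if (anyNA(f_bar)) {
    # count-weighted fallback across the computable classes
    ok <- !is.na(f_bar)
    fallback <- sum(f_bar[ok] * n_class[ok]) / sum(n_class[ok])
    f_bar[!ok] <- fallback
  }
  nc <- 2 + 9 / f_bar["2"] + 1 / f_bar["3"] + 5 / f_bar["4"] + 3 / f_bar["6"]
  nc <- unname(nc)
  if (clamp) nc <- min(max(nc, 20), 61)
  nc
}

#' Expected Nc under random codon usage at a given GC3
#'
#' Wright's reference curve for the Nc plot: if synonymous codon choice
#' is driven only by the third-position G+C content `s`,
#' `Nc(s) = 2 + s + 29 / (s^2 + (1 - s)^2)`. Genes falling well below
#' this curve are biased beyond what composition alone explains.
#'
#' @param s GC3 fraction(s), strictly inside `(0, 1)`.
#' @return Expected Nc value(s).
#' @export
expected_nc <- function(s) {
  if (any(s <= 0 | s >= 1)) abort("`s` must lie strictly inside (0, 1)")
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' Codon bias index (CBI)
#'
#' Bennetzen-Hall index: the excess use of a set of "optimal" codons
#' over the uniform-usage expectation,
#' `CBI = (N_opt - N_ran) / (N_tot - N_ran)`, where `N_opt` counts
#' codons from the optimal set, `N_tot` counts all codons of degenerate
#' (k >= 2) families, and `N_ran = sum(n_family / k)` is the optimal
#' count expected under uniform usage. 1 means only optimal codons;
#' 0 means uniform usage; negative values mean optimal codons are
#' avoided.
#'
#' @param counts A codon count table or named count vector.
#' @param optimal_codons Character vector with exactly one codon per
#'   degenerate family (see [select_optimal_codons()]).
#' @return A single CBI value, or `NA` when `N_tot == N_ran`.
#' @export
codon_bias_index <- function(counts, optimal_codons) {
  v <- as_codon_counts(counts)
  v[STOP_CODONS] <- 0
  check_optimal_set(optimal_codons)
  degen <- names(FAMILY_SIZE)[FAMILY_SIZE >= 2]
  n_tot <- 0; n_ran <- 0
  for (aa in degen) {
    fam <- CODON_FAMILIES[[aa]]
    n_fam <- sum(v[fam])
    n_tot <- n_tot + n_fam
    n_ran <- n_ran + n_fam / length(fam)
  }
  n_opt <- sum(v[optimal_codons])
  if (n_tot == n_ran) return(NA_real_)
  (n_opt - n_ran) / (n_tot - n_ran)
}

check_optimal_set <- function(optimal_codons) {
  degen <- names(FAMILY_SIZE)[FAMILY_SIZE >= 2]
  aa <- CODON_TABLE$amino_acid[match(optimal_codons, CODON_TABLE$codon)]
  if (anyNA(aa) || any(aa == "*")) abort("`optimal_codons` contains invalid codons")
  if (!setequal(aa, degen) || anyDuplicated(aa)) {
    abort("`optimal_codons` must contain exactly one codon per degenerate family")
  }
  invisible(optimal_codons)
}

#' Select optimal codons from highly expressed genes
#'
#' Pools codon counts over the most expressed genes (`top_fraction` of
#' the shared ids, ranked by `fpkm` if present, else by
#' `fragment_count`) and declares, in each degenerate family, the most
#' frequent codon optimal; ties resolve alphabetically.
#'
#' @param cds Sequence tibble of coding sequences (`id`, `seq`).
#' @param expression Expression tibble with `id` and `fpkm` or
#'   `fragment_count`.
#' @param top_fraction Fraction of genes to pool (default 0.10).
#' @return Character vector of optimal codons, one per degenerate
#'   family.
#' @export
select_optimal_codons <- function(cds, expression, top_fraction = 0.10) {
  check_seq_tbl(cds, "cds")
  shared <- intersect(cds$id, expression$id)
  if (length(shared) == 0) abort("`cds` and `expression` share no ids")
  rank_by <- if ("fpkm" %in% names(expression)) "fpkm" else "fragment_count"
  expr <- expression[expression$id %in% shared, ]
  expr <- expr[order(-expr[[rank_by]]), ]
  n_top <- max(1L, ceiling(top_fraction * nrow(expr)))
  top_ids <- expr$id[seq_len(n_top)]
  pooled <- colSums(do.call(rbind, lapply(
    cds$seq[cds$id %in% top_ids],
    function(s) as_codon_counts(count_codons(s))
  )))
  degen <- names(FAMILY_SIZE)[FAMILY_SIZE >= 2]
  vapply(degen, function(aa) {
    fam <- sort(CODON_FAMILIES[[aa]])   # alphabetical tie-break
    fam[which.max(pooled[fam])]
  }, character(1), USE.NAMES = FALSE)
}

#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM = 1e9 * fragment_count / (length * total_fragments)`: linear in
#' the fragment count and inverse-linear in both transcript length and
#' sequencing depth.
#'
#' @param fragment_count Fragment counts (vectorized).
#' @param length Transcript lengths in nt.
#' @param total_fragments Total mapped fragments in the library.
#' @return FPKM values.
#' @export
fpkm <- function(fragment_count, length, total_fragments) {
  if (any(length <= 0)) abort("`length` must be > 0")
  if (any(total_fragments <= 0)) abort("`total_fragments` must be > 0")
  1e9 * fragment_count / (length * total_fragments)
}

#' Pearson correlation with a t-test p-value
#'
#' Product-moment correlation; the two-sided p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero
#'   variance.
#' @return One-row tibble: `r`, `p_value`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 3) abort("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("correlation undefined for a constant vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Per-gene codon bias statistics and their link to expression
#'
#' The full bias-versus-expression analysis: ORFs strictly longer than
#' `min_orf_nt` get per-gene GC, GC3, Nc and CBI; expression is
#' converted to `log10(FPKM)`; and the Pearson correlation between CBI
#' and `log10(FPKM)` is computed over the usable genes. Genes with zero
#' fragment counts (log undefined) or undefined bias statistics are
#' flagged (`used = FALSE`), never silently dropped.
#'
#' @param cds Sequence tibble of coding sequences.
#' @param expression Tibble with `id`, `fragment_count` and optionally
#'   `length` (defaults to the CDS length) — or a precomputed `fpkm`
#'   column.
#' @param optimal_codons Optional optimal-codon set for CBI; derived
#'   with [select_optimal_codons()] when `NULL`.
#' @param min_orf_nt Strict ORF length floor in nt (default 150).
#' @param top_fraction Passed to [select_optimal_codons()].
#' @return Object of class `bias_expression`: list with `genes` (per-gene
#'   tibble), `correlation` (one-row tibble from [pearson()]),
#'   `optimal_codons` and `n_flagged`. [tidy()] returns the gene table,
#'   [glance()] the correlation.
#' @export
bias_expression_analysis <- function(cds, expression, optimal_codons = NULL,
                                     min_orf_nt = 150L, top_fraction = 0.10) {
  check_seq_tbl(cds, "cds")
  cds <- dplyr::filter(cds, nchar(.data$seq) > min_orf_nt)
  if (nrow(cds) == 0) abort("no ORF longer than `min_orf_nt`")
  expr <- as_tibble(expression)
  if (!"fpkm" %in% names(expr)) {
    if (!all(c("id", "fragment_count") %in% names(expr))) {
      abort("`expression` needs `fpkm` or `id` + `fragment_count` columns")
    }
    if (!"length" %in% names(expr)) {
      expr$length <- nchar(cds$seq[match(expr$id, cds$id)])
    }
    total <- sum(expr$fragment_count)
    known <- !is.na(expr$length) & expr$length > 0
    expr$fpkm <- NA_real_
    expr$fpkm[known] <- fpkm(expr$fragment_count[known], expr$length[known], total)
  }
  if (is.null(optimal_codons)) {
    optimal_codons <- select_optimal_codons(cds, expr, top_fraction)
  } else {
    check_optimal_set(optimal_codons)
  }

  genes <- dplyr::inner_join(cds, select(expr, "id", "fpkm"), by = "id")
  if (nrow(genes) == 0) abort("`cds` and `expression` share no ids")
  stats_tbl <- purrr::map(genes$seq, function(s) {
    ct <- count_codons(s)
    tibble(
      n_codons = attr(ct, "n_codons"),
      gc = gc_content(s),
      gc3 = gc3(s),
      nc = effective_number_of_codons(ct),
      cbi = codon_bias_index(ct, optimal_codons)
    )
  }) |> bind_rows()
  genes <- bind_cols(select(genes, "id", "fpkm"), stats_tbl) |>
    mutate(
      log10_fpkm = dplyr::if_else(.data$fpkm > 0, log10(.data$fpkm), NA_real_),
      used = !is.na(.data$log10_fpkm) & !is.na(.data$cbi) & !is.na(.data$nc)
    )
  usable <- dplyr::filter(genes, .data$used)
  if (nrow(usable) < 3) abort("fewer than 3 usable genes; correlation undefined")
  corr <- pearson(usable$cbi, usable$log10_fpkm)

  structure(
    list(genes = genes, correlation = corr,
         optimal_codons = optimal_codons,
         n_flagged = sum(!genes$used)),
    class = "bias_expression"
  )
}

#' @export
print.bias_expression <- function(x, ...) {
  cat(sprintf("<bias_expression> %d genes (%d flagged unusable)\n",
              nrow(x$genes), x$n_flagged))
  cat(sprintf("  Pearson CBI ~ log10(FPKM): r = %.4f, p = %.3g (n = %d)\n",
              x$correlation$r, x$correlation$p_value, x$correlation$n))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bias_expression <- function(x, ...) x$genes

#' @exportS3Method generics::glance
glance.bias_expression <- function(x, ...) {
  bind_cols(x$correlation,
            tibble(n_genes = nrow(x$genes), n_flagged = x$n_flagged))
}

#' @param object A `bias_expression` fit.
#' @param ... Ignored.
#' @rdname bias_expression_analysis
#' @exportS3Method ggplot2::autoplot
autoplot.bias_expression <- function(object, ...) {
  df <- dplyr::filter(object$genes, .data$used)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log10_fpkm, y = .data$cbi)) +
    ggplot2::geom_point(alpha = 0.4, colour = "steelblue") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "firebrick") +
    ggplot2::labs(x = expression(log[10] ~ FPKM), y = "codon bias index") +
    ggplot2::theme_minimal()
}

#' Nc plot: effective number of codons against GC3
#'
#' Draws per-gene Nc versus GC3 with the expected curve under random
#' usage overlaid; genes sitting well below the curve are biased beyond
#' composition.
#'
#' @param genes Tibble with `gc3` and `nc` columns (e.g.
#'   `tidy(bias_expression_analysis(...))`).
#' @return A ggplot object.
#' @export
plot_nc_gc3 <- function(genes) {
  stopifnot(all(c("gc3", "nc") %in% names(genes)))
  curve_df <- tibble(s = seq(0.01, 0.99, by = 0.01))
  curve_df$nc <- expected_nc(curve_df$s)
  ggplot2::ggplot(genes, ggplot2::aes(x = .data$gc3, y = .data$nc)) +
    ggplot2::geom_point(alpha = 0.4, colour = "steelblue") +
    ggplot2::geom_line(data = curve_df,
                       ggplot2::aes(x = .data$s, y = .data$nc),
                       colour = "deeppink", linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(20, 61)) +
    ggplot2::labs(x = "GC3", y = "effective number of codons (Nc)") +
    ggplot2::theme_minimal()
}
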