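test_that("count_codons handles frame-0 triplets, partials and N codons", {
  ct <- count_codons("ATGGCC")
  expect_equal(ct$count[ct$codon == "ATG"], 1)
  expect_equal(ct$count[ct$codon == "GCC"], 1)
  expect_equal(attr(ct, "n_codons"), 2)
  expect_equal(attr(ct, "n_skipped"), 0)

  ct2 <- count_codons("ATGGC")
  expect_equal(attr(ct2, "n_codons"), 1)
  expect_equal(attr(ct2, "n_skipped"), 1)

  ct3 <- count_codons("ATGNNA")
  expect_equal(attr(ct3, "n_codons"), 1)
  expect_equal(attr(ct3, "n_skipped"), 1)
})

test_that("rscu follows the definition and sums to family size", {
  # Glu family {GAA:3, GAG:1}: RSCU = 3/((3+1)/2) and 1/((3+1)/2)
  r <- rscu(c(GAA = 3, GAG = 1))
  expect_equal(r$rscu[r$codon == "GAA"], 1.5)
  expect_equal(r$rscu[r$codon == "GAG"], 0.5)

  # perfectly uniform usage -> all defined values are 1
  uniform <- setNames(rep(1, 61), setdiff(CODON_TABLE$codon,
                                          c("TAA", "TAG", "TGA")))
  r2 <- rscu(uniform)
  expect_true(all(abs(r2$rscu[r2$amino_acid != "*"] - 1) < 1e-12))

  # exclusive codon in a 4-fold family -> RSCU 4
  r3 <- rscu(c(GGG = 7))
  expect_equal(r3$rscu[r3$codon == "GGG"], 4)
  expect_true(is.na(r3$rscu[r3$codon == "TAA"]))
})

test_that("per-family RSCU sums equal family size on random inputs", {
  set.seed(51)
  for (i in 1:20) {
    cds <- paste(sample(CODON_TABLE$codon, 300, TRUE), collapse = "")
    r <- rscu(count_codons(cds))
    sums <- r |>
      dplyr::filter(.data$amino_acid != "*", !is.na(.data$rscu)) |>
      dplyr::group_by(.data$amino_acid) |>
      dplyr::summarise(s = sum(.data$rscu), k = dplyr::n())
    expect_equal(sums$s, as.numeric(sums$k))
  }
})

test_that("rscu agrees with seqinr's independent implementation", {
  skip_if_not_installed("seqinr")
  set.seed(52)
  cds <- paste(sample(setdiff(CODON_TABLE$codon, c("TAA", "TAG", "TGA")),
                      600, TRUE), collapse = "")
  ours <- rscu(count_codons(cds))
  theirs <- seqinr::uco(seqinr::s2c(tolower(cds)), index = "rscu")
  names(theirs) <- toupper(names(theirs))
  for (cod in names(theirs)) {
    if (cod %in% c("TAA", "TAG", "TGA")) next
    if (is.na(theirs[[cod]])) next
    expect_equal(ours$rscu[ours$codon == cod], unname(theirs[[cod]]),
                 tolerance = 1e-9)
  }
})

test_that("gc3 and gc_content count what they claim", {
  expect_equal(gc3("ATGGGG"), 1)
  expect_equal(gc3("GGAGGT"), 0)
  expect_equal(gc3("GGCGGA"), 0.5)
  expect_equal(gc3("GGCNNNGGA"), 0.5)    # N codon excluded
  expect_error(gc3("AT"), "no complete")
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("ATGCN"), 0.5)
})

test_that("Nc hits its analytic limits", {
  # one fixed codon per amino acid, each seen 5 times -> maximal bias, 20
  one_per_aa <- vapply(CODON_FAMILIES, function(f) f[1], character(1))
  cds_biased <- paste(rep(one_per_aa, each = 5), collapse = "")
  expect_equal(effective_number_of_codons(count_codons(cds_biased)), 20)

  # exactly uniform synonymous usage, population homozygosity -> 61
  uniform_cds <- paste(rep(unlist(CODON_FAMILIES), 10), collapse = "")
  expect_equal(
    effective_number_of_codons(count_codons(uniform_cds),
                               homozygosity = "population"),
    61
  )
  # with the finite-sample correction the same input clamps to 61
  expect_equal(effective_number_of_codons(count_codons(uniform_cds)), 61)
})

test_that("Nc matches the independent direct-from-definition oracle", {
  set.seed(53)
  sense <- setdiff(CODON_TABLE$codon, c("TAA", "TAG", "TGA"))
  for (i in 1:30) {
    w <- rexp(61)                       # random biased usage
    cds <- paste(sample(sense, 2000, TRUE, prob = w), collapse = "")
    expect_equal(effective_number_of_codons(count_codons(cds)),
                 nc_oracle(cds), tolerance = 1e-9)
  }
})

test_that("Nc sparse-family fallback engages for short ORFs", {
  # only 2-fold and 4-fold families present; 3- and 6-fold classes fall
  # back to the count-weighted mean and Nc stays finite
  cds <- paste(c(rep("GAA", 3), rep("GAG", 2), rep("GCT", 3), rep("GCC", 2)),
               collapse = "")
  nc <- effective_number_of_codons(count_codons(cds))
  expect_true(is.finite(nc))
  expect_gte(nc, 20)
  expect_lte(nc, 61)
  expect_error(effective_number_of_codons(count_codons("ATG")), "too few")
})

test_that("the expected Nc-GC3 curve has its known shape", {
  expect_equal(expected_nc(0.5), 60.5)
  expect_equal(expected_nc(1e-6), 31, tolerance = 1e-4)
  s <- runif(20, 0.05, 0.95)
  expect_equal(expected_nc(s), expected_nc(1 - s) - (1 - 2 * s))  # symmetry + s term
  expect_error(expected_nc(0), "strictly inside")
  expect_error(expected_nc(1.2), "strictly inside")
})

test_that("CBI spans its analytic anchor points", {
  degen <- names(FAMILY_SIZE)[FAMILY_SIZE >= 2]
  optimal <- vapply(CODON_FAMILIES[degen], function(f) sort(f)[1], character(1))
  # only optimal codons -> 1
  cds_opt <- paste(rep(optimal, each = 4), collapse = "")
  expect_equal(codon_bias_index(count_codons(cds_opt), optimal), 1)
  # exactly uniform usage -> 0
  uniform <- paste(rep(unlist(CODON_FAMILIES[degen]), 2), collapse = "")
  expect_equal(codon_bias_index(count_codons(uniform), optimal), 0)
  # avoiding all optimal codons in 2-fold families only -> hand arithmetic
  two_fold <- names(FAMILY_SIZE)[FAMILY_SIZE == 2]
  non_opt <- vapply(CODON_FAMILIES[two_fold],
                    function(f) setdiff(f, sort(f)[1])[1], character(1))
  cds_avoid <- paste(rep(non_opt, each = 2), collapse = "")
  n_tot <- 2 * length(non_opt)
  n_ran <- n_tot / 2
  expect_equal(codon_bias_index(count_codons(cds_avoid), optimal),
               (0 - n_ran) / (n_tot - n_ran))
  expect_error(codon_bias_index(count_codons(cds_opt), c("ATG")), "optimal")
})

test_that("select_optimal_codons pools the top-expressed genes", {
  set.seed(54)
  sim <- gen_cds_set(n_genes = 60, codons_per_gene = 300, gc3_target = 0.5,
                     bias_strength = c(rep(0.9, 6), rep(0, 54)), seed = 7)
  expr <- tibble::tibble(id = sim$cds$id,
                         fpkm = c(rep(1000, 6), rep(1, 54)))
  opt <- select_optimal_codons(sim$cds, expr, top_fraction = 0.1)
  # high-expression genes prefer the generator's G/C-ending codons
  gc_ending <- substr(opt, 3, 3) %in% c("G", "C")
  expect_true(mean(gc_ending) > 0.9)
  expect_error(select_optimal_codons(sim$cds,
                                     tibble::tibble(id = "zz", fpkm = 1)),
               "share no ids")
  # top_fraction = 1 pools everything; a single gene uses its own codons
  opt_all <- select_optimal_codons(sim$cds, expr, top_fraction = 1)
  expect_equal(length(opt_all), 18)
})

test_that("fpkm follows its formula and scaling identities", {
  expect_equal(fpkm(10, 1000, 1e6), 10)
  expect_equal(fpkm(0, 500, 1e6), 0)
  set.seed(55)
  fc <- sample(1:1000, 20); len <- sample(200:5000, 20); tot <- 2e6
  expect_equal(fpkm(2 * fc, len, tot), 2 * fpkm(fc, len, tot))
  expect_equal(fpkm(fc, 2 * len, tot), fpkm(fc, len, tot) / 2)
  expect_equal(fpkm(fc, len, 2 * tot), fpkm(fc, len, tot) / 2)
  expect_error(fpkm(1, 0, 1e6), "> 0")
})

test_that("pearson matches direct formulas and flags degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  # orthogonalized vector -> r = 0 to machine precision
  set.seed(56)
  a <- rnorm(50); a <- a - mean(a)
  b <- rnorm(50); b <- b - mean(b)
  b_perp <- b - sum(a * b) / sum(a * a) * a   # centered and orthogonal to a
  expect_lt(abs(pearson(a, b_perp)$r), 1e-12)
  # n = 5 toy vectors against the closed-form t test
  y <- c(2, 1, 4, 3, 6)
  p <- pearson(x, y)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_stat <- r_direct * sqrt((5 - 2) / (1 - r_direct^2))
  expect_equal(p$r, r_direct)
  expect_equal(p$p_value, 2 * stats::pt(-abs(t_stat), df = 3))
  expect_error(pearson(x, rep(1, 5)), "constant")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("bias_expression_analysis couples bias to expression when planted", {
  sim <- gen_cds_set(n_genes = 150, codons_per_gene = 200, gc3_target = 0.5,
                     bias_strength = runif(150), seed = 61)
  expr <- gen_expression(sim$truth, coupling = 0.8, seed = 62)
  fit <- bias_expression_analysis(sim$cds, expr)
  expect_s3_class(fit, "bias_expression")
  expect_gt(fit$correlation$r, 0)
  expect_lt(fit$correlation$p_value, 0.01)
  genes <- tidy(fit)
  expect_true(all(c("id", "nc", "gc3", "cbi", "log10_fpkm", "used") %in%
                    names(genes)))
  expect_equal(nrow(genes), 150)
  g <- glance(fit)
  expect_equal(g$n_genes, 150)

  # order invariance of the per-gene statistics
  fit2 <- bias_expression_analysis(sim$cds[sample(150), ], expr,
                                   optimal_codons = fit$optimal_codons)
  merged <- dplyr::inner_join(tidy(fit), tidy(fit2), by = "id")
  expect_equal(merged$nc.x, merged$nc.y)
  expect_equal(merged$cbi.x, merged$cbi.y)
})

test_that("uncoupled expression gives a near-zero correlation", {
  sim <- gen_cds_set(n_genes = 150, codons_per_gene = 200, gc3_target = 0.5,
                     bias_strength = runif(150), seed = 63)
  expr <- gen_expression(sim$truth, coupling = 0, seed = 64)
  fit <- bias_expression_analysis(sim$cds, expr)
  expect_lt(abs(fit$correlation$r), 0.25)
  # single usable gene -> correlation undefined
  expect_error(
    bias_expression_analysis(sim$cds[1, ], expr[1, ]),
    "fewer than 3|share no ids|no ORF"
  )
})

test_that("zero-count genes are flagged, not dropped", {
  sim <- gen_cds_set(n_genes = 20, codons_per_gene = 100, gc3_target = 0.5,
                     bias_strength = 0.3, seed = 65)
  expr <- gen_expression(sim$truth, coupling = 0, seed = 66)
  expr$fragment_count[1:3] <- 0
  fit <- bias_expression_analysis(sim$cds, expr)
  genes <- tidy(fit)
  expect_equal(sum(!genes$used), 3)
  expect_equal(nrow(genes), 20)
  expect_equal(fit$correlation$n, 17)
})
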