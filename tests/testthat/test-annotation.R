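blast_row <- function(q, s, bit, evalue, q_start = 1, q_end = 300) {
  paste(c(q, s, 90, 100, 10, 0, q_start, q_end, 1, 100, evalue, bit),
        collapse = "\t")
}

test_that("parse_blast_tab reads 12 columns and skips comments", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# BLASTX 2.x", blast_row("u1", "p1", 120, 1e-30),
               blast_row("u2", "p2", 80, 1e-8, q_start = 300, q_end = 100)), tf)
  hits <- parse_blast_tab(tf)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$bit_score, c(120, 80))
  expect_true(hits$q_start[2] > hits$q_end[2])   # minus orientation signal

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(rep("x", 11), collapse = "\t"), bad)
  expect_error(parse_blast_tab(bad), "12 columns")

  bad2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(blast_row("u1", "p1", "notanumber", 1e-5), bad2)
  expect_error(parse_blast_tab(bad2), "non-numeric")
})

test_that("best_hit keeps the top bit score with the inclusive E-value cutoff", {
  hits <- tibble::tibble(
    query_id = c("u1", "u1", "u2", "u3", "u3"),
    subject_id = c("a", "b", "c", "d", "e"),
    evalue = c(1e-30, 1e-20, 1e-4, 1e-5, 1e-10),
    bit_score = c(90, 120, 200, 50, 50)
  )
  best <- best_hit(hits)
  expect_equal(best$subject_id[best$query_id == "u1"], "b")  # 120 > 90
  expect_false("u2" %in% best$query_id)                       # 1e-4 > 1e-5
  expect_true("u3" %in% best$query_id)                        # 1e-5 kept (<=)
  # bit tie resolved by lower evalue
  expect_equal(best$subject_id[best$query_id == "u3"], "e")
})

test_that("merge_priority annotates by the first database in order", {
  mk <- function(q, s) tibble::tibble(query_id = q, subject_id = s,
                                      evalue = 1e-20, bit_score = 100)
  per_db <- list(Nr = mk("u1", "nr1"),
                 SwissProt = mk(c("u1", "u2"), c("sp1", "sp2")),
                 KEGG = mk(c("u2", "u3"), c("kg2", "kg3")),
                 COG = mk("u3", "cog3"))
  merged <- merge_priority(per_db)
  expect_equal(merged$source_db[merged$query_id == "u1"], "Nr")
  expect_equal(merged$source_db[merged$query_id == "u2"], "SwissProt")
  expect_equal(merged$source_db[merged$query_id == "u3"], "KEGG")
  expect_error(merge_priority(per_db, priority = c("Nr", "Banana")), "unknown")

  # changing priority changes attribution, never the annotated set
  merged2 <- merge_priority(per_db, priority = c("COG", "KEGG", "SwissProt", "Nr"))
  expect_setequal(merged$query_id, merged2$query_id)
  expect_equal(merged2$source_db[merged2$query_id == "u1"], "SwissProt")
})

test_that("extract_cds recovers a planted CDS on both strands", {
  set.seed(41)
  # build a unigene around a known 100-codon CDS
  peptide_codons <- sample(setdiff(CODON_TABLE$codon, c("TAA", "TAG", "TGA")),
                           100, replace = TRUE)
  cds <- paste(peptide_codons, collapse = "")
  flank5 <- random_seq(9)       # CDS starts at nt 10, frame 1
  flank3 <- random_seq(50)
  uni <- paste0(flank5, cds, flank3)
  recs <- tibble::tibble(id = "u1", seq = uni)
  hit <- tibble::tibble(query_id = "u1", source_db = "Nr",
                        q_start = 10, q_end = 10 + 300 - 1, evalue = 1e-30,
                        bit_score = 200)
  ann <- extract_cds(recs, hit)
  expect_equal(ann$orientation, "+")
  expect_equal(ann$cds_seq, cds)
  expect_equal(nchar(ann$cds_seq) %% 3, 0)

  # same CDS on the reverse strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(uni)))
  recs_m <- tibble::tibble(id = "u1", seq = rc)
  L <- nchar(rc)
  hit_m <- tibble::tibble(query_id = "u1", source_db = "Nr",
                          q_start = L - 10 + 1, q_end = L - (10 + 300 - 1) + 1,
                          evalue = 1e-30, bit_score = 200)
  ann_m <- extract_cds(recs_m, hit_m)
  expect_equal(ann_m$orientation, "-")
  expect_equal(ann_m$cds_seq, cds)

  # translations agree (no internal stops planted)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(ann$cds_seq)))
  aa_m <- as.character(Biostrings::translate(Biostrings::DNAString(ann_m$cds_seq)))
  expect_equal(aa, aa_m)
})

test_that("extract_cds trims partial codons and rejects sub-codon hits", {
  set.seed(42)
  recs <- tibble::tibble(id = "u1", seq = random_seq(200))
  hit <- tibble::tibble(query_id = "u1", q_start = 10, q_end = 20,
                        evalue = 1e-9, bit_score = 50)
  ann <- extract_cds(recs, hit)   # 11 nt -> 9 nt (3 codons)
  expect_equal(ann$cds_end - ann$cds_start + 1, 9)
  expect_equal(ann$source_db, "blast")

  tiny <- tibble::tibble(query_id = "u1", q_start = 10, q_end = 11,
                         evalue = 1e-9, bit_score = 50)
  expect_error(extract_cds(recs, tiny), "shorter than one codon")
})

# direct six-frame enumeration used as the longest_orf oracle
orf_oracle <- function(seq) {
  stops <- c("TAA", "TAG", "TGA")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  best <- 0
  for (s in c(seq, rc)) {
    for (off in 0:2) {
      n_cod <- (nchar(s) - off) %/% 3
      if (n_cod < 1) next
      run <- 0
      for (j in seq_len(n_cod)) {
        cod <- substr(s, off + 3 * j - 2, off + 3 * j)
        if (cod %in% stops) run <- 0 else run <- run + 1
        best <- max(best, 3 * run)
      }
    }
  }
  best
}

test_that("longest_orf agrees with a brute-force 6-frame enumeration", {
  set.seed(43)
  for (i in 1:25) {
    recs <- tibble::tibble(id = "x", seq = random_seq(sample(160:900, 1)))
    ann <- longest_orf(recs, min_nt = 0)
    expected <- orf_oracle(recs$seq)
    if (nrow(ann) == 0) {
      expect_equal(expected, 0)
    } else {
      expect_equal(nchar(ann$cds_seq), expected)
      # reported ORF is stop-free and matches its coordinates
      expect_equal(ann$cds_end - ann$cds_start + 1, nchar(ann$cds_seq))
      cods <- substring(ann$cds_seq, seq(1, nchar(ann$cds_seq), 3),
                        seq(3, nchar(ann$cds_seq), 3))
      expect_false(any(cods %in% c("TAA", "TAG", "TGA")))
    }
  }
})

test_that("longest_orf applies the strict 150-nt floor and reports strand", {
  set.seed(44)
  # unbroken 300-nt frame on the minus strand, forward riddled with stops
  clean <- paste(rep("GCT", 100), collapse = "")
  host <- paste0("TAATAGTGA", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(clean))), "TAGTAA")
  ann <- longest_orf(tibble::tibble(id = "m", seq = host))
  expect_equal(nrow(ann), 1)
  expect_equal(ann$orientation, "-")
  expect_equal(ann$source_db, "fallback")
  expect_true(nchar(ann$cds_seq) >= 300)

  # the floor is strict: an ORF of exactly min_nt is not reported
  r <- tibble::tibble(id = "s", seq = random_seq(400))
  o <- orf_oracle(r$seq)
  expect_equal(nrow(longest_orf(r, min_nt = o)), 0)
  expect_equal(nrow(longest_orf(r, min_nt = o - 1)), 1)
})

test_that("annotate_unigenes combines priority hits with the ORF fallback", {
  set.seed(45)
  cds <- paste(rep("GAAGCTCTG", 30), collapse = "")   # 270 nt stop-free
  u1 <- paste0(random_seq(9), cds, random_seq(30))
  u2 <- paste0("TAA", cds, "TAA")                      # no hit, clean ORF
  recs <- tibble::tibble(id = c("u1", "u2"), seq = c(u1, u2))
  per_db <- list(Nr = tibble::tibble(query_id = "u1", subject_id = "p",
                                     q_start = 10, q_end = 10 + 270 - 1,
                                     evalue = 1e-30, bit_score = 300),
                 SwissProt = tibble::tibble(query_id = character(),
                                            subject_id = character(),
                                            q_start = numeric(), q_end = numeric(),
                                            evalue = numeric(), bit_score = numeric()))
  ann <- annotate_unigenes(recs, per_db, priority = c("Nr", "SwissProt"))
  expect_setequal(ann$query_id, c("u1", "u2"))
  expect_equal(ann$source_db[ann$query_id == "u1"], "Nr")
  expect_equal(ann$source_db[ann$query_id == "u2"], "fallback")
})

test_that("annotation_summary counts per-database and union sets", {
  s <- annotation_summary(list(Nr = c("a", "b"), Nt = c("b", "c")))
  expect_equal(s$n_annotated[s$db == "Nr"], 2)
  expect_equal(s$n_annotated[s$db == "union"], 3)
  s2 <- annotation_summary(list(Nr = c("a", "b"), GO = character()))
  expect_equal(s2$n_annotated[s2$db == "union"], 2)
  s3 <- annotation_summary(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(s3$n_annotated[s3$db == "union"], 2)
})
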