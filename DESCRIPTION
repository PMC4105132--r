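Package: transchar
Title: Downstream Characterization of De Novo Transcriptome Assemblies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tidy tools for the downstream characterization of de novo
    transcriptome assemblies: raw-read cleaning with N-content and
    base-quality rules, assembly statistics (N50, mean length, GC),
    genome-mapping evaluation from PSL alignment tables, merging of
    tabular similarity-search results under a database priority order
    with coding-region extraction and a longest-ORF fallback,
    reciprocal-best-hit orthology, a codon-usage-bias engine (RSCU, GC3,
    Wright's effective number of codons, codon bias index, FPKM and the
    bias-expression correlation), and SSRIT-style microsatellite mining
    with repeat-number thresholds.  Seeded synthetic-data generators
    fabricate every input with machine-readable ground truth so the
    whole pipeline can be exercised end-to-end against known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    rlang,
    stats,
    utils,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    igraph,
    jsonlite,
    patchwork,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
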