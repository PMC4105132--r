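---
title: "Characterizing a de novo transcriptome assembly: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a de novo transcriptome assembly: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transchar)
library(dplyr)
```

`transchar` implements the downstream characterization stages that follow a
de novo transcriptome assembly — the kind of survey routinely run on a
non-model insect transcriptome: read cleaning, assembly statistics, genome
mapping evaluation, annotation-driven CDS extraction, reciprocal-best-hit
orthology, codon usage bias, and microsatellite (SSR) mining. This vignette
explains the models and rules behind each stage, the parameters that matter,
the design choices we made where convention is ambiguous, and what the
synthetic-data generators do and do not emulate.

## Read cleaning

Raw paired-end reads are filtered by two rules applied per read:

* discard when the fraction of ambiguous `N` bases **exceeds** 5%
  (`n_max = 0.05`), and
* discard when the fraction of bases with Phred quality below 20 **exceeds**
  10% (`lowq_max = 0.10`).

Both comparisons are deliberately strict inequalities: a 90-nt read with
exactly 9 sub-Q20 bases (10%) survives, one with 10 is removed. Keeping the
boundary on the survival side makes the rules exactly testable and matches
the plain reading of "more than 10%" / "larger than 5%". In paired mode a
pair is dropped when either mate fails, which keeps the two files
synchronized; pair handling is a choice of ours since single-end filtering
is also supported. Quality encoding defaults to Phred+33 (Sanger /
Illumina 1.8+), with Phred+64 available for legacy data.

Adapter removal is exact-match trimming: the leftmost position where a
prefix of the adapter (≥ 5 nt) matches the read — reaching either the
read's 3' end or the full adapter — is cut together with everything
downstream. We chose exact matching over a mismatch-tolerant aligner
because the stage must exist, be deterministic and be fully testable; users
with heavily erroneous adapters should pre-trim with a dedicated tool such
as fastp.

## Assembly statistics and clustering

`assembly_stats()` reports the classic single-row description: count, total
and mean length, N50 and GC. N50 is defined as the length at which the
descending cumulative length first reaches half the total; when the half
falls exactly on a boundary the sequence that *reaches* it supplies the
N50 (the conventional definition). The GC denominator excludes `N` bases — a
choice that is inert on cleaned data, where the `N` percentage is ~0.

Unigene sets are conventionally split into *clusters* (`CL1, CL2, ...`) of
sequences whose pairwise similarity is strictly above 70%, and *singletons*
(`Unigene1, ...`). How those similarities are obtained is an assembler /
aligner concern, so `cluster_label()` takes precomputed pairs and performs
union-find over the strict-threshold graph; the test-suite drives it with a
naive k-mer-overlap identity estimate.

## Mapping evaluation

Alignments of unigenes against a reference genome arrive as 21-column PSL
tables. Following the convention that only a query's *longest* alignment
represents it, `dedup_longest()` keeps the record with the most matching
bases (ties: larger target span, then first seen). Coverage is the
match-to-length ratio. The summary reports the mapped fraction, the
single-block versus multi-block split (one block suggesting a single exon),
the count of queries with coverage strictly above 90%, and decile
histograms. Coverage bins are `[0, 0.1), ..., [0.9, 1.0]` with the top bin
closed, so full-length alignments are counted rather than lost to an
open boundary.

## Annotation and CDS extraction

Per-database similarity searches (12-column tabular) are reduced to one
best hit per query — highest bit score, then lowest E-value, then input
order; the E-value cutoff `1e-5` is inclusive. When several protein
databases annotate the same unigene, a fixed priority order
(Nr → SwissProt → KEGG → COG) decides which hit sets the orientation and
coding region; changing the order can only change attribution, never the
annotated set, and nucleotide-database hits count toward annotation totals
but never orient a sequence.

CDS extraction takes exactly the aligned query interval on the oriented
strand, anchored at its start (translated searches report codon-boundary
alignments) and trimmed at the 3' end to whole codons. We deliberately do
**not** extend to the nearest start/stop codons: the minimal interval is
reproducible, whereas extension rules vary between annotation pipelines.

Unigenes with no database hit fall back to `longest_orf()`: the longest
stop-free codon run over all six frames, bounded by stop codons or sequence
ends, reported when strictly longer than 150 nt and labelled
`source_db = "fallback"`. This replaces trained gene-prediction models
(ESTScan-style) with a deterministic, self-contained rule that preserves
the pipeline role — orienting and annotating BLAST-negative unigenes. The
150-nt floor is strict (`>`), consistent with the other boundary choices.

## Orthology

Proteome sets are first filtered to peptides of at least 50 residues
(inclusive — short sequences give unreliable hits and would need different
search parameters). `one_directional()` is simply the set of queries with
any qualifying hit. `reciprocal_best_hits()` reports pairs that are each
other's best hit in both directions, using the *same* tie-breaking as
`best_hit()` so the two directions cannot disagree by implementation
accident. Ties at the top bit score are resolved by stable input order;
that is documented behaviour of this implementation, not an assertion
about any particular study. RBH output is 1:1 by construction.

## Codon usage bias

All bias statistics use the standard nuclear genetic code and exclude stop
codons. Six-fold families (Leu, Ser, Arg) are treated as their own
degeneracy class, not split 2 + 4 — the CodonW convention.

**RSCU** is observed count over uniform-family expectation; family sums
equal family size wherever defined.

**Nc** (Wright's effective number of codons) estimates per-amino-acid
homozygosity as `F = (nΣp² − 1)/(n − 1)` (the finite-sample corrected
form), averages within degeneracy classes and combines
`Nc = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆`. Three numerical choices matter for
short ORFs:

* amino acids seen fewer than twice are omitted from their class mean;
* a class with no computable member takes the count-weighted mean of the
  remaining classes' homozygosities (Wright's recommended patch); and
* results are clamped to `[20, 61]`, since the corrected estimator can
  stray above 61 on nearly uniform finite samples.

An uncorrected `homozygosity = "population"` option (`F = Σp²`) exists for
evaluating analytic limits: exactly uniform usage then yields 61 on the
nose, and one-codon-per-family usage yields 20 under either estimator.

The **expected Nc–GC3 curve**, `Nc(s) = 2 + s + 29/(s² + (1−s)²)`, is
Wright's published closed form for random usage driven only by
third-position composition; we adopt it explicitly as the reference curve
drawn by `plot_nc_gc3()`.

**CBI** uses the Bennetzen–Hall form
`(N_opt − N_ran)/(N_tot − N_ran)` with `N_ran = Σ n_family/k`. Optimal
codons default to the most frequent codon per family among the top decile
of genes by expression (`select_optimal_codons()`), with alphabetical tie
break — a transparent substitute for organism-specific preset tables,
which do not exist for most non-model species. Because the optimal set is
data-derived, CBI values (and hence the bias–expression correlation) are
comparable within a dataset but not across datasets annotated with
different optimal sets.

**FPKM** is `10⁹ · fragments/(length · total)`, and the bias–expression
link is the Pearson correlation between CBI and `log₁₀ FPKM`. Genes with
zero counts (log undefined) or undefined statistics are flagged
`used = FALSE` and excluded from the correlation, never silently dropped;
no pseudocount is added by default because the transform convention is
just "log₁₀".

## SSR mining

`find_ssrs()` reports perfect (uninterrupted) tandem repeats of 2–6-nt
motifs with minimum repeat numbers 6, 5, 4, 4, 4 for di- through
hexa-nucleotide motifs. Mononucleotide runs are never reported (homopolymer
stretches are a known sequencing artifact on short-read platforms), which
falls out naturally from requiring motifs to be *primitive* — a motif that
is a power of a shorter motif collapses to the shortest period, so
`(ATAT)₃` is `(AT)₆`. Maximal runs are taken left to right and overlapping
reports are suppressed greedily from the left; at equal starts the longer
span, then the shorter motif, wins. Detection itself uses a shift-match
run-length scan; the test suite holds it to exact set equality with a
brute-force enumerator.

`ssr_scan()` screens only unigenes strictly longer than 1 kb (the
conventional marker-survey floor) but, by default, computes the
one-SSR-per-X-kb frequency over the *full* unigene set's nucleotides —
that is how published survey tables are typically computed, with the
printed arithmetic dividing total transcriptome kilobases by SSR count; a
`frequency_denominator = "screened"` switch restricts the denominator to
screened sequences. Because "kinds of SSRs" is ambiguous, the summary
exposes three counts: distinct raw motifs, distinct canonical rotations
(`canonical_motif()`, no reverse-complement folding), and distinct
(motif, repeat-count) pairs. The repeat-number matrix bins repeats as
4, 5, ..., 10, >10 by motif-length class.

## Synthetic data: what it emulates, and what it does not

Every input the pipeline consumes can be fabricated with a seeded
generator carrying machine-readable ground truth; each call uses its own
RNG scope so outputs are byte-identical under a fixed seed.

* `gen_transcriptome()` draws lengths from a log-normal tuned to a mean of
  571 nt (floored at 200 nt) with i.i.d. bases at GC 0.5126 — the regime of
  a typical insect unigene set.
* `plant_ssrs()` overwrites host sequence in place with guard bases on both
  flanks chosen so the planted run can neither extend nor change phase,
  and re-draws background segments that happen to contain detectable SSRs,
  making the truth table the complete expected hit list.
* `gen_cds_set()` draws synonymous codons from a family distribution
  interpolating between composition-driven usage at a target GC3 (bias 0)
  and exclusive use of one preferred G/C-ending codon per family (bias 1,
  giving Nc = 20 exactly). Amino acids cycle through the 18 degenerate
  families in balanced, shuffled order, so every family is observed and
  the Nc estimator never needs its sparse fallback at the default sizes.
* `gen_reads()` samples 90-nt pairs and plants reads that clearly fail each
  cleaning rule, plus an optional class sitting exactly at the 10%
  low-quality boundary (which must survive).
* `gen_ortholog_tables()` gives planted pairs top-scoring reciprocal hits
  over lower-scoring decoys; `gen_expression()` couples Poisson–lognormal
  fragment counts to true bias strength with a dial in `[-1, 1]`.

These generators validate the *logic* of the pipeline — boundary behaviour,
truth recovery, estimator calibration — not its performance on real data.
They deliberately omit isoform structure, realistic Illumina error and
duplication profiles, expression-dependent coverage bias, interrupted or
compound SSRs, and paralog-rich orthology structure. A green suite says
the rules are implemented exactly as specified, not that the defaults are
optimal for any particular organism.

Problem sizes in the tests (for example 200 random 5-kb sequences against
the SSR oracle, 200 genes × 500 codons per GC3 setting for Nc parameter
recovery, 100 random CDSs for the Nc oracle) were chosen to make the
stochastic checks stable at comfortable margins while keeping the default
test run quick on a laptop.

## Calibration the suite enforces

Three quantitative anchors are worth stating because they pin down the
estimator conventions:

* exactly uniform synonymous usage gives Nc = 61 (population
  homozygosity) and maximal bias gives Nc = 20;
* CDS sets generated under random usage at GC3 ∈ {0.3, 0.5, 0.7} have mean
  Nc within 1.5 of `expected_nc(GC3)` — the small residual gap is real and
  comes from the isoleucine (3-fold) family, whose homozygosity under
  composition-driven usage is not exactly the curve's implied value;
* mean Nc decreases strictly along a bias sweep from 0 to 1.

## Known limitations

* PSL and BLAST tabular parsers are strict: they reject ragged rows rather
  than guessing, and report line numbers.
* The CDS extractor trusts the hit's codon anchoring; frame-shifted or
  chimeric alignments produce an in-frame *interval*, not a validated gene
  model.
* `cluster_label()` does not compute similarities; garbage pairs in,
  garbage clusters out.
* Nc is undefined below roughly 20 observed codons; such ORFs error rather
  than return a misleading number.
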