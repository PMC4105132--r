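# Standard nuclear genetic code, shared by annotation and codon-usage code.

CODON_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  tibble::tibble(codon = names(gc), amino_acid = unname(gc))
})

STOP_CODONS <- CODON_TABLE$codon[CODON_TABLE$amino_acid == "*"]

# Synonymous families of the sense codons, amino acid -> codons.
CODON_FAMILIES <- local({
  sense <- CODON_TABLE[CODON_TABLE$amino_acid != "*", ]
  split(sense$codon, sense$amino_acid)
})

FAMILY_SIZE <- vapply(CODON_FAMILIES, length, integer(1))

# Amino acids by degeneracy class; six-fold families (Leu, Ser, Arg) are
# one class of their own, not split 2+4.
DEGENERACY_CLASSES <- split(names(FAMILY_SIZE), FAMILY_SIZE)

#' Split a nucleotide string into frame-0 codons
#' @noRd
codon_vector <- function(seq) {
  n_complete <- nchar(seq) %/% 3L
  if (n_complete == 0) return(character())
  substring(seq, 3L * seq_len(n_complete) - 2L, 3L * seq_len(n_complete))
}
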