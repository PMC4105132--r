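#' Read a FASTA file into a sequence tibble
#'
#' Reads nucleotide or protein FASTA into a tibble with one row per entry,
#' preserving file order. Nucleotide sequences are uppercased and RNA `U`
#' is mapped to `T`; the resulting alphabet is restricted to `A,C,G,T,N`.
#'
#' @param path Path to a FASTA file (plain or gzipped).
#' @param type `"dna"` (default; normalizes and validates the nucleotide
#'   alphabet) or `"protein"` (uppercases only).
#' @return A tibble with columns `id`, `seq` and `description` (text after
#'   the first whitespace in the header, `NA` if none).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">u1 first", "acgtacgt", ">u2", "GGGCCC"), tf)
#' read_fasta(tf)
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  head_lines <- head_lines[nzchar(trimws(head_lines))]
  if (length(head_lines) == 0) {
    abort(sprintf("parse error in %s at line 1: empty FASTA file", path))
  }
  if (!startsWith(head_lines[[1]], ">")) {
    abort(sprintf("parse error in %s at line 1: expected FASTA header starting with '>'", path))
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), NA_character_)
  seq <- toupper(as.character(set))
  if (type == "dna") {
    seq <- chartr("U", "T", seq)
    bad <- grepl("[^ACGTN]", seq)
    if (any(bad)) {
      abort(sprintf("non-ACGTN characters in sequence '%s'", id[which(bad)[1]]))
    }
  }
  out <- tibble(id = unname(id), seq = unname(seq), description = unname(description))
  check_seq_tbl(out)
  out
}

#' Write a sequence tibble to FASTA
#'
#' @param records Tibble with `id`, `seq` and optionally `description`.
#' @param path Output path.
#' @param width Line-wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  check_seq_tbl(records)
  headers <- records$id
  if ("description" %in% names(records)) {
    has_desc <- !is.na(records$description) & nzchar(records$description)
    headers[has_desc] <- paste(records$id[has_desc], records$description[has_desc])
  }
  set <- Biostrings::BStringSet(setNames(records$seq, headers))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
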