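#' Read a FASTQ file into a read tibble
#'
#' Four-line FASTQ records (plain or gzipped) are parsed into one row per
#' read with per-base Phred scores decoded from the chosen encoding.
#'
#' @param path Path to a FASTQ file.
#' @param encoding `"phred33"` (Sanger / Illumina 1.8+, the default) or
#'   `"phred64"` (legacy Illumina 1.3-1.7).
#' @return Tibble with columns `id`, `bases` and `quals` (list column of
#'   integer Phred scores, one per base).
#' @export
read_fastq <- function(path, encoding = c("phred33", "phred64")) {
  encoding <- match.arg(encoding)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  scoring <- if (encoding == "phred33") "phred" else "illumina"
  set <- suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = scoring)
  )  # Biostrings warns when dropping its own metadata columns
  quals <- as.list(methods::as(Biostrings::quality(set), "IntegerList"))
  tibble(
    id = unname(names(set)),
    bases = unname(as.character(set)),
    quals = unname(lapply(quals, as.integer))
  )
}

#' Write a read tibble to FASTQ
#'
#' @param reads Read tibble (`id`, `bases`, `quals`).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param encoding Quality encoding, as in [read_fastq()].
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, encoding = c("phred33", "phred64")) {
  encoding <- match.arg(encoding)
  check_read_tbl(reads)
  offset <- if (encoding == "phred33") 33L else 64L
  qstr <- vapply(reads$quals, function(q) rawToChar(as.raw(q + offset)), character(1))
  set <- Biostrings::DNAStringSet(setNames(reads$bases, reads$id))
  Biostrings::writeXStringSet(
    set, path, format = "fastq",
    compress = grepl("\\.gz$", path),
    qualities = Biostrings::BStringSet(qstr)
  )
  invisible(path)
}
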