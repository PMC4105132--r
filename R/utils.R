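# Internal helpers shared across modules.

# Reverse complement of one or more ACGTN strings.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Validate a sequence table: tibble with `id` (unique, nonempty) and `seq`.
check_seq_tbl <- function(x, arg = "records") {
  if (!is.data.frame(x) || !all(c("id", "seq") %in% names(x))) {
    abort(sprintf("`%s` must be a data frame with columns `id` and `seq`", arg))
  }
  if (nrow(x) > 0) {
    if (anyNA(x$id) || any(!nzchar(x$id))) {
      abort(sprintf("`%s` has missing or empty sequence ids", arg))
    }
    if (anyDuplicated(x$id)) {
      abort(sprintf("`%s` has duplicated sequence ids", arg))
    }
  }
  invisible(x)
}

# Validate a read table: `id`, `bases`, `quals` (list of integer vectors,
# each the same length as its bases).
check_read_tbl <- function(x, arg = "reads") {
  if (!is.data.frame(x) || !all(c("id", "bases", "quals") %in% names(x))) {
    abort(sprintf("`%s` must have columns `id`, `bases` and `quals`", arg))
  }
  if (nrow(x) > 0) {
    len_ok <- vapply(seq_len(nrow(x)), function(i) {
      length(x$quals[[i]]) == nchar(x$bases[[i]])
    }, logical(1))
    if (!all(len_ok)) {
      abort(sprintf("`%s`: per-base qualities must match read length (rows %s)",
                    arg, paste(which(!len_ok)[1:min(3, sum(!len_ok))], collapse = ", ")))
    }
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
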