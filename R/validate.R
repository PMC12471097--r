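#' Validate and normalize peptide sequences
#'
#' Strips whitespace, upper-cases, and checks that every character is one of
#' the 20 canonical one-letter amino-acid codes. Ambiguity and non-standard
#' codes (B, J, O, U, X, Z), digits and gap characters are rejected with an
#' error naming the first offending position (1-based).
#'
#' @param raw Character vector of raw sequences.
#' @return Character vector of canonical upper-case sequences.
#' @examples
#' validate_sequence("ar")
#' validate_sequence("AWKLFDDGV")
#' @export
validate_sequence <- function(raw) {
  if (!is.character(raw)) {
    rlang::abort("`raw` must be a character vector of peptide sequences.")
  }
  seqs <- toupper(gsub("\\s", "", raw))
  if (any(!nzchar(seqs))) {
    rlang::abort("Empty sequence after whitespace stripping.")
  }
  bad <- stringr::str_locate(seqs, sprintf("[^%s]", paste(AA_CANONICAL, collapse = "")))[, "start"]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    rlang::abort(sprintf(
      "Non-canonical residue '%s' at position %d of sequence %d ('%s').",
      substr(seqs[i], bad[i], bad[i]), bad[i], i, seqs[i]
    ))
  }
  seqs
}

# split into single-residue character vectors (internal)
seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]
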