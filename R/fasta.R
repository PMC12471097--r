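#' Read peptides from a FASTA file
#'
#' Headers follow the `>apd_id|name|source` convention; a bare `>apd_id` is
#' accepted, in which case `name` and `source` are empty strings. Sequences
#' may be single-line or wrapped and are validated against the canonical
#' amino-acid alphabet via [validate_sequence()].
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `apd_id`, `name`, `source`, `sequence`,
#'   one row per record in file order.
#' @seealso [write_peptide_fasta()] for the inverse; the pair round-trips.
#' @export
read_peptide_fasta <- function(path) {
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) {
      rlang::abort(sprintf("Malformed FASTA file '%s': %s", path, conditionMessage(e)))
    }
  )
  if (length(set) == 0) {
    rlang::abort(sprintf("FASTA file '%s' contains no records.", path))
  }
  if (any(Biostrings::width(set) == 0)) {
    rlang::abort(sprintf(
      "FASTA record '%s' has an empty sequence.",
      names(set)[Biostrings::width(set) == 0][1]
    ))
  }
  parts <- stringr::str_split_fixed(names(set), stringr::fixed("|"), 3)
  out <- tibble::tibble(
    apd_id = stringr::str_trim(parts[, 1]),
    name = stringr::str_trim(parts[, 2]),
    source = stringr::str_trim(parts[, 3]),
    sequence = validate_sequence(unname(as.character(set)))
  )
  if (anyDuplicated(out$apd_id)) {
    rlang::abort(sprintf(
      "Duplicated record id '%s' in '%s'.",
      out$apd_id[duplicated(out$apd_id)][1], path
    ))
  }
  out
}

#' Write peptides to a FASTA file
#'
#' @param x Data frame with columns `apd_id`, `sequence` and optionally
#'   `name` and `source` (used to build `>apd_id|name|source` headers;
#'   omitted or empty fields collapse to a bare `>apd_id` header).
#' @param path Output path.
#' @param width Sequence line wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_peptide_fasta <- function(x, path, width = 60) {
  stopifnot(is.data.frame(x), all(c("apd_id", "sequence") %in% names(x)))
  nm <- if ("name" %in% names(x)) x$name else character(nrow(x))
  src <- if ("source" %in% names(x)) x$source else character(nrow(x))
  header <- ifelse(
    nzchar(nm) | nzchar(src),
    paste(x$apd_id, nm, src, sep = "|"),
    x$apd_id
  )
  if (nrow(x) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  set <- Biostrings::AAStringSet(stats::setNames(validate_sequence(x$sequence), header))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' The 57-record reference dataset of plant antimicrobial oligopeptides
#'
#' Plant antimicrobial peptides with anticancer properties, selected from the
#' Antimicrobial Peptide Database (accessions `AP00236` ... `AP05050`), as
#' published. This is the input set the whole pipeline was built around.
#'
#' @return A tibble with columns `no`, `apd_id`, `name`, `source`,
#'   `sequence`; exactly 57 rows.
#' @examples
#' reference_peptides()
#' @export
reference_peptides <- function() {
  cached("reference", {
    out <- readr::read_tsv(
      pep_asset("reference_peptides.tsv"),
      comment = "#", col_types = "icccc"
    )
    out$sequence <- validate_sequence(out$sequence)
    stopifnot(!anyDuplicated(out$apd_id))
    out
  })
}
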