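#' Find cleavage sites of one enzyme on a peptide
#'
#' Bonds are indexed 0-based: bond `i` lies between residues `i` and `i + 1`
#' (0-based), so a peptide of length `L` has bonds `0 ... L - 2`. Bond `i` is
#' cleaved iff the P1 residue is in the rule's `p1` set or the ordered
#' (P1, P1') pair is in its `pairs` set, and the P1' residue is not excluded.
#' Substrates shorter than the rule's `min_length` yield no sites.
#'
#' @param sequence A single validated peptide sequence.
#' @param rule A one-row rule tibble from [enzyme_rule()] or
#'   [load_enzyme_rules()].
#' @return Sorted integer vector of 0-based bond indices.
#' @examples
#' trypsin <- enzyme_rule("trypsin", p1 = c("K", "R"))
#' find_cleavage_sites("AWKLFDDGV", trypsin)
#' @export
find_cleavage_sites <- function(sequence, rule) {
  sequence <- validate_sequence(sequence)
  stopifnot(length(sequence) == 1, is.data.frame(rule), nrow(rule) == 1)
  n <- nchar(sequence)
  if (n < rule$min_length) return(integer(0))
  ch <- seq_chars(sequence)
  p1 <- rule$p1[[1]]
  pairs <- rule$pairs[[1]]
  excl <- rule$exclusions[[1]]
  bonds <- seq_len(n - 1) # bond b (0-based) = bonds[b + 1]... vectorized below
  left <- ch[bonds]
  right <- ch[bonds + 1]
  hit <- (left %in% p1 | paste0(left, right) %in% pairs) & !(right %in% excl)
  as.integer(bonds[hit] - 1L)
}

#' Digest one peptide with one or more enzymes acting simultaneously
#'
#' All bonds matched by any rule are cut in a single exhaustive pass (the
#' simultaneous model: no kinetics, no partial digestion, no missed
#' cleavages). Fragments are the maximal runs between cuts.
#'
#' @param sequence A single validated peptide sequence.
#' @param rules Tibble of enzyme rules (one or more rows).
#' @param parent_id Optional id recorded on the result.
#' @return A `pep_digestion` tibble with columns `fragment`, `start`, `end`
#'   (1-based inclusive coordinates on the parent) and attributes
#'   `parent_id`, `parent` and `cut_sites` (0-based bond indices).
#' @examples
#' digest_sequence("TESYFVFSVGM", gi_enzymes())
#' @export
digest_sequence <- function(sequence, rules, parent_id = NA_character_) {
  sequence <- validate_sequence(sequence)
  if (!is.data.frame(rules) || nrow(rules) == 0) {
    rlang::abort("`rules` must contain at least one enzyme rule.")
  }
  cuts <- sort(unique(unlist(
    lapply(seq_len(nrow(rules)), function(i) find_cleavage_sites(sequence, rules[i, ]))
  )))
  n <- nchar(sequence)
  # 0-based half-open fragment intervals between consecutive cuts
  starts0 <- c(0L, cuts + 1L)
  ends0 <- c(cuts + 1L, n)
  out <- tibble::tibble(
    fragment = substring(sequence, starts0 + 1L, ends0),
    start = starts0 + 1L,
    end = as.integer(ends0)
  )
  structure(
    out,
    parent_id = parent_id, parent = sequence, cut_sites = as.integer(cuts),
    class = c("pep_digestion", class(out))
  )
}

#' @export
tidy.pep_digestion <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("fragment", "start", "end")])
}

#' @export
glance.pep_digestion <- function(x, ...) {
  tibble::tibble(
    parent_id = attr(x, "parent_id"),
    parent_length = nchar(attr(x, "parent")),
    n_cuts = length(attr(x, "cut_sites")),
    n_fragments = nrow(x),
    mean_fragment_length = mean(nchar(x$fragment))
  )
}

#' Digest every peptide of a dataset
#'
#' Data-frame-first wrapper around [digest_sequence()]: takes a tibble of
#' peptides, returns one row per released fragment with its parent id and
#' 1-based coordinates.
#'
#' @param x Data frame with columns `apd_id` and `sequence` (e.g.
#'   [reference_peptides()] or [random_peptides()]).
#' @param rules Tibble of enzyme rules (default: the gastrointestinal set).
#' @return Tibble with columns `apd_id`, `fragment`, `start`, `end`.
#' @export
digest <- function(x, rules = gi_enzymes()) {
  stopifnot(is.data.frame(x), all(c("apd_id", "sequence") %in% names(x)))
  purrr::map2(x$sequence, x$apd_id, function(s, id) {
    tibble::as_tibble(unclass(digest_sequence(s, rules, parent_id = id))[c("fragment", "start", "end")])
  }) |>
    rlang::set_names(x$apd_id) |>
    dplyr::bind_rows(.id = "apd_id")
}

#' Map unique short fragments to the parents that release them
#'
#' Digests the dataset and keeps fragments whose length is in `lengths`
#' (default di- and tripeptides), deduplicating repeated releases from the
#' same parent.
#'
#' @inheritParams digest
#' @param lengths Fragment lengths to keep (default `2:3`).
#' @return Tibble with columns `fragment`, `parents` (list-column of sorted
#'   parent ids) and `n_parents`, arranged by fragment.
#' @examples
#' unique_fragments(reference_peptides())
#' @export
unique_fragments <- function(x, rules = gi_enzymes(), lengths = 2:3) {
  digest(x, rules) |>
    dplyr::filter(nchar(.data$fragment) %in% lengths) |>
    dplyr::distinct(.data$fragment, .data$apd_id) |>
    dplyr::group_by(.data$fragment) |>
    dplyr::summarise(parents = list(sort(unique(.data$apd_id))), .groups = "drop") |>
    dplyr::mutate(n_parents = lengths(.data$parents)) |>
    dplyr::arrange(.data$fragment)
}
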