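#' The bioactivity annotation table for digestion fragments
#'
#' Static snapshot mapping each released di/tripeptide to its activity
#' classes (ACE inhibitor, dipeptidyl peptidase IV inhibitor, antioxidative,
#' and the rarer peptidase-inhibitor and neuropeptide classes) and to the
#' source oligopeptides reported to release it. A snapshot asset is used
#' instead of a live database query so results are reproducible.
#'
#' @param path Optional path to an alternative TSV asset with columns
#'   `activity`, `fragment`, `source_ids` (semicolon-separated).
#' @return Tibble with columns `activity`, `fragment`, `sources`
#'   (list-column of APD accessions), one row per (activity, fragment) pair.
#' @export
activity_table <- function(path = NULL) {
  load <- function(p) {
    out <- readr::read_tsv(p, comment = "#", col_types = "ccc")
    out$fragment <- validate_sequence(out$fragment)
    stopifnot(all(nchar(out$fragment) %in% 2:3))
    tibble::tibble(
      activity = out$activity,
      fragment = out$fragment,
      sources = strsplit(out$source_ids, ";", fixed = TRUE)
    )
  }
  if (is.null(path)) cached("activity_table", load(pep_asset("activity_table.tsv"))) else load(path)
}

#' Annotate a fragment map with bioactivities
#'
#' Inner-joins a fragment -> parents map (from [unique_fragments()]) with the
#' activity table. Fragments absent from the table are kept in the result
#' with `activity = NA` (the "unannotated" bucket), so the join is lossless:
#' annotated rows + distinct unannotated fragments account for every input
#' fragment.
#'
#' @param fragment_map Tibble with columns `fragment` and `parents`
#'   (list-column of parent ids), as returned by [unique_fragments()].
#' @param activities Activity table (default [activity_table()]).
#' @return Tibble with columns `activity`, `fragment`, `parents`, annotated
#'   rows first, ordered by activity (table order), then fragment.
#' @export
annotate_fragments <- function(fragment_map, activities = activity_table()) {
  stopifnot(is.data.frame(fragment_map))
  if (nrow(fragment_map) == 0) {
    return(tibble::tibble(
      activity = character(), fragment = character(), parents = list()
    ))
  }
  fragment_map <- dplyr::mutate(
    fragment_map,
    fragment = validate_sequence(.data$fragment),
    parents = purrr::map(.data$parents, sort)
  )
  lvl <- unique(activities$activity)
  annotated <- activities |>
    dplyr::select("activity", "fragment") |>
    dplyr::inner_join(fragment_map[c("fragment", "parents")], by = "fragment")
  unannotated <- fragment_map |>
    dplyr::filter(!(.data$fragment %in% activities$fragment)) |>
    dplyr::transmute(activity = NA_character_, .data$fragment, .data$parents)
  dplyr::bind_rows(annotated, unannotated) |>
    dplyr::arrange(is.na(.data$activity), match(.data$activity, lvl), .data$fragment)
}

#' Activity-major digestion report
#'
#' End-to-end convenience: digest a peptide dataset with the given rules,
#' keep the unique di/tripeptides, and report the annotated fragments
#' grouped by activity (unannotated fragments are dropped here; use
#' [annotate_fragments()] to see them).
#'
#' @inheritParams digest
#' @param activities Activity table (default [activity_table()]).
#' @return Tibble with columns `activity`, `fragment`, `parents`.
#' @examples
#' activity_profile(reference_peptides())
#' @export
activity_profile <- function(x, rules = gi_enzymes(), activities = activity_table()) {
  annotate_fragments(unique_fragments(x, rules), activities) |>
    dplyr::filter(!is.na(.data$activity))
}
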