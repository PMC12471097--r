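#' Classify a di/tripeptide's resistance to microbial proteases
#'
#' Applies the two small-intestine microbial proteases to a released
#' fragment: oligopeptidase F (inert on substrates shorter than its length
#' floor, so di/tripeptides pass through intact) and proteinase P1
#' (lactocepin), which cuts every internal bond whose (P1, P1') pair is in
#' its cleaved-pair table; pairs not in the table default to resistant.
#' A fragment is resistant overall iff both enzymes leave it intact.
#'
#' @param fragment A single di- or tripeptide sequence.
#' @param rules Microbial rule set (default [microbial_enzymes()]); must
#'   contain rules named `oligopeptidase_f` and `proteinase_p1`.
#' @return One-row tibble: `fragment`, `opf_products` and `p1_products`
#'   (list-columns of ordered products), `resistant_both`.
#' @examples
#' classify_fragment("AR")
#' classify_fragment("PGL")
#' @export
classify_fragment <- function(fragment, rules = microbial_enzymes()) {
  fragment <- validate_sequence(fragment)
  stopifnot(length(fragment) == 1)
  if (!nchar(fragment) %in% 2:3) {
    rlang::abort(sprintf(
      "Resistance classification is defined for di/tripeptides; got length %d ('%s'). Use digest_sequence() for longer substrates.",
      nchar(fragment), fragment
    ))
  }
  opf <- rules[rules$name == "oligopeptidase_f", ]
  p1 <- rules[rules$name == "proteinase_p1", ]
  if (nrow(opf) != 1 || nrow(p1) != 1) {
    rlang::abort("`rules` must contain one 'oligopeptidase_f' and one 'proteinase_p1' rule.")
  }
  opf_products <- digest_sequence(fragment, opf)$fragment
  p1_products <- digest_sequence(fragment, p1)$fragment
  intact <- identical(opf_products, fragment) && identical(p1_products, fragment)
  tibble::tibble(
    fragment = fragment,
    opf_products = list(opf_products),
    p1_products = list(p1_products),
    resistant_both = intact
  )
}

#' Resistance screen over a set of fragments
#'
#' @param fragments Character vector of di/tripeptides (input order is
#'   preserved in the output).
#' @inheritParams classify_fragment
#' @return Tibble with one [classify_fragment()] row per fragment.
#' @examples
#' resistance_table(c("AR", "PGL", "QL"))
#' @export
resistance_table <- function(fragments, rules = microbial_enzymes()) {
  if (length(fragments) == 0) {
    return(tibble::tibble(
      fragment = character(), opf_products = list(), p1_products = list(),
      resistant_both = logical()
    ))
  }
  purrr::map(fragments, classify_fragment, rules = rules) |> dplyr::bind_rows()
}
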