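#' Generate random peptides with controlled composition
#'
#' Lengths are drawn uniformly from `length_range` and residues i.i.d. from
#' `composition`. A single explicit integer seed drives a local RNG stream;
#' the global random state is left untouched, and a fixed seed gives
#' byte-identical output.
#'
#' @param n Number of peptides.
#' @param length_range Integer `c(min, max)`, `min >= 2` (the shortest
#'   peptide with a bond); default spans the di-peptide to small-protein
#'   range the digestion engine is used on.
#' @param composition Named non-negative sampling weights over the 20
#'   canonical residues (unnamed residues get weight 0); `NULL` for uniform.
#' @param motif Optional di/tripeptide embedded in every peptide via
#'   [embed_motif()] so that digestion with `rules` releases it.
#' @param rules Rule set used by `motif` embedding (default [gi_enzymes()]).
#' @param seed Integer seed (required, no silent global-state dependence).
#' @return Tibble with columns `apd_id` (`SYN00001`, ...), `name`, `source`,
#'   `sequence`.
#' @examples
#' random_peptides(3, seed = 42)
#' @export
random_peptides <- function(n, length_range = c(2, 60), composition = NULL,
                            motif = NULL, rules = gi_enzymes(), seed) {
  stopifnot(n >= 0, length(length_range) == 2, length_range[1] >= 2,
            length_range[1] <= length_range[2])
  if (missing(seed)) rlang::abort("`seed` is required for reproducible generation.")
  if (is.null(composition)) {
    composition <- stats::setNames(rep(1, 20), AA_CANONICAL)
  }
  if (is.null(names(composition)) || any(composition < 0) || sum(composition) == 0) {
    rlang::abort("`composition` must be named, non-negative, and not all zero.")
  }
  bad <- setdiff(names(composition), AA_CANONICAL)
  if (length(bad) > 0) {
    rlang::abort(sprintf("Unknown residue(s) in `composition`: %s", paste(bad, collapse = ", ")))
  }
  w <- stats::setNames(rep(0, 20), AA_CANONICAL)
  w[names(composition)] <- composition
  seqs <- with_local_seed(seed, {
    # sample.int avoids base sample()'s scalar expansion when min == max
    lens <- length_range[1] - 1L +
      sample.int(length_range[2] - length_range[1] + 1L, n, replace = TRUE)
    vapply(lens, function(L) {
      paste(sample(AA_CANONICAL, L, replace = TRUE, prob = w), collapse = "")
    }, character(1))
  })
  if (!is.null(motif)) {
    seqs <- vapply(seqs, embed_motif, character(1), motif = motif, rules = rules,
                   USE.NAMES = FALSE)
  }
  tibble::tibble(
    apd_id = sprintf("SYN%05d", seq_len(n)),
    name = sprintf("synthetic peptide %d", seq_len(n)),
    source = "synthetic",
    sequence = seqs
  )
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv()) else
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  expr
}

#' Embed a motif so digestion releases it intact
#'
#' Appends the motif at the C-terminus of the host, preceded by a flanking
#' P1 residue chosen from the rule set, so that the simultaneous digest cuts
#' immediately before the motif and nowhere inside it. Errors if the motif
#' cannot survive the rules (an internal bond of the motif is itself a
#' cleavage site) or no usable flank residue exists.
#'
#' @param sequence Host sequence (may be empty).
#' @param motif Di- or tripeptide to plant.
#' @param rules Enzyme rule set the release must hold under.
#' @return The constructed sequence; `digest_sequence()` on it releases
#'   `motif` as a standalone fragment.
#' @examples
#' embed_motif("", "GL", gi_enzymes())
#' @export
embed_motif <- function(sequence, motif, rules = gi_enzymes()) {
  motif <- validate_sequence(motif)
  if (!nchar(motif) %in% 2:3) rlang::abort("`motif` must be a di- or tripeptide.")
  if (nzchar(gsub("\\s", "", sequence))) sequence <- validate_sequence(sequence) else sequence <- ""
  internal <- unlist(lapply(seq_len(nrow(rules)), function(i) {
    find_cleavage_sites(motif, rules[i, ])
  }))
  internal <- setdiff(internal, nchar(motif) - 1L)
  if (length(internal) > 0) {
    rlang::abort(sprintf(
      "Motif '%s' is destroyed by the rule set: internal bond %s is a cleavage site.",
      motif, paste(sort(unique(internal)) + 1L, collapse = ", ")
    ))
  }
  # flank must cut C-terminally with the motif's first residue at P1'
  candidates <- unique(unlist(rules$p1))
  ok <- vapply(candidates, function(r) {
    any(vapply(seq_len(nrow(rules)), function(i) {
      length(find_cleavage_sites(paste0(r, motif), rules[i, ])) > 0 &&
        0L %in% find_cleavage_sites(paste0(r, motif), rules[i, ])
    }, logical(1)))
  }, logical(1))
  if (!any(ok)) {
    rlang::abort(sprintf("No flank residue in the rule set releases motif '%s'.", motif))
  }
  paste0(sequence, candidates[ok][1], motif)
}
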