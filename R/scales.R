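# Loaders for the shipped per-residue scales and pKa sets. All are parsed
# once and cached; each returns base R structures (named numeric vectors /
# matrices) because the descriptor code indexes them heavily.

read_residue_scale <- function(file) {
  tab <- readr::read_tsv(pep_asset(file), comment = "#", col_types = "cd")
  stopifnot(nrow(tab) == 20, setequal(tab$residue, AA_CANONICAL))
  stats::setNames(tab$value, tab$residue)[AA_CANONICAL]
}

#' Kyte-Doolittle hydropathy scale
#'
#' @return Named numeric vector over the 20 canonical residues.
#' @export
hydropathy_scale <- function() {
  cached("kd_scale", read_residue_scale("hydropathy_kyte_doolittle.tsv"))
}

#' Boman (protein-binding potential) residue scale
#'
#' Per-residue transfer free energies in kcal/mol, hydrophilic-positive
#' convention, so the Boman index is simply their mean over a sequence.
#'
#' @return Named numeric vector over the 20 canonical residues.
#' @export
boman_scale <- function() {
  cached("boman_scale", read_residue_scale("boman_scale.tsv"))
}

#' Guruprasad dipeptide instability weight matrix (DIWV)
#'
#' @return 20 x 20 numeric matrix, rows = first residue, columns = second;
#'   pairs not assigned a published weight carry the default 1.0.
#' @export
instability_matrix <- function() {
  cached("diwv", {
    tab <- readr::read_tsv(pep_asset("instability_matrix.tsv"),
      comment = "#", col_types = readr::cols("p1" = "c", .default = "d")
    )
    m <- as.matrix(tab[, AA_CANONICAL])
    rownames(m) <- tab$p1
    stopifnot(identical(dim(m), c(20L, 20L)))
    m[AA_CANONICAL, AA_CANONICAL]
  })
}

#' Ionizable-group pKa sets
#'
#' Two sets are shipped. `"pi"` is the EMBOSS-style set (N-terminus 8.6,
#' C-terminus 3.6, C 8.5, D 3.9, E 4.1, H 6.5, K 10.8, R 12.5, Y 10.1) used
#' for the theoretical isoelectric point; `"charge"` is identical except
#' His 6.0 and reproduces the published pH-7 net charges. The two columns of
#' the published characterization came from different calculators, hence the
#' two sets.
#'
#' @param set `"pi"` or `"charge"`.
#' @return Tibble with columns `group` (residue code, `nterm` or `cterm`),
#'   `pka`, `polarity` (`acid`/`base`).
#' @export
pka_set <- function(set = c("pi", "charge")) {
  set <- match.arg(set)
  all <- cached("pka_sets", {
    tab <- readr::read_tsv(pep_asset("pka_sets.tsv"), comment = "#", col_types = "ccdc")
    names(tab)[names(tab) == "set"] <- "pka_set"
    stopifnot(all(tab$pka > 0 & tab$pka < 14), all(tab$polarity %in% c("acid", "base")))
    tab
  })
  out <- all[all$pka_set == set, c("group", "pka", "polarity")]
  tibble::as_tibble(out)
}
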