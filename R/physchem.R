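#' Grand average of hydropathicity (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over the residues of each sequence.
#' Negative values indicate a hydrophilic peptide.
#'
#' @param sequence Character vector of peptide sequences.
#' @param scale Named per-residue hydropathy vector (default Kyte-Doolittle).
#' @return Numeric vector (unrounded; the reporting layer rounds to 2
#'   decimals).
#' @examples
#' gravy(c("AR", "IL"))
#' @export
gravy <- function(sequence, scale = hydropathy_scale()) {
  sequence <- validate_sequence(sequence)
  vapply(sequence, function(s) mean(scale[seq_chars(s)]), numeric(1), USE.NAMES = FALSE)
}

#' Ikai aliphatic index
#'
#' `100 * (fA + 2.9 * fV + 3.9 * (fI + fL))` over mole fractions; a proxy
#' for the relative volume of aliphatic side chains, read here as
#' thermostability when above 100.
#'
#' @inheritParams gravy
#' @return Numeric vector in `[0, 390]`.
#' @examples
#' aliphatic_index("IL") # 390, the maximum
#' @export
aliphatic_index <- function(sequence) {
  sequence <- validate_sequence(sequence)
  vapply(sequence, function(s) {
    ch <- seq_chars(s)
    f <- function(a) mean(ch == a)
    100 * (f("A") + 2.9 * f("V") + 3.9 * (f("I") + f("L")))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Boman index (protein-binding potential)
#'
#' Mean per-residue transfer free energy (kcal/mol) under the
#' hydrophilic-positive convention. Values above 2.48 kcal/mol indicate
#' high potential for binding membranes or protein receptors.
#'
#' @inheritParams gravy
#' @param scale Named per-residue free-energy vector (default [boman_scale()]).
#' @return Numeric vector, kcal/mol.
#' @examples
#' boman_index(c("AR", "IL"))
#' @export
boman_index <- function(sequence, scale = boman_scale()) {
  sequence <- validate_sequence(sequence)
  vapply(sequence, function(s) mean(scale[seq_chars(s)]), numeric(1), USE.NAMES = FALSE)
}

#' Henderson-Hasselbalch net charge at a given pH
#'
#' Sums the fractional charges of the N-terminus, C-terminus and every
#' ionizable side chain: each basic group contributes
#' `+1 / (1 + 10^(pH - pKa))`, each acidic group `-1 / (1 + 10^(pKa - pH))`.
#'
#' @inheritParams gravy
#' @param pH pH value(s) in `[0, 14]` (scalar, recycled over sequences).
#' @param pkas pKa set tibble (default the `"charge"` set, see [pka_set()]).
#' @return Numeric vector of net charges in elementary-charge units
#'   (unrounded; the published column rounds to 1 decimal).
#' @examples
#' net_charge("AR", 7)
#' @export
net_charge <- function(sequence, pH = 7, pkas = pka_set("charge")) {
  sequence <- validate_sequence(sequence)
  stopifnot(all(pH >= 0 & pH <= 14))
  side <- pkas[!pkas$group %in% c("nterm", "cterm"), ]
  nterm <- pkas[pkas$group == "nterm", ]
  cterm <- pkas[pkas$group == "cterm", ]
  frac <- function(pka, polarity, pH) {
    ifelse(polarity == "base", 1 / (1 + 10^(pH - pka)), -1 / (1 + 10^(pka - pH)))
  }
  mapply(function(s, ph) {
    ch <- seq_chars(s)
    q <- frac(nterm$pka, nterm$polarity, ph) + frac(cterm$pka, cterm$polarity, ph)
    for (i in seq_len(nrow(side))) {
      n_res <- sum(ch == side$group[i])
      if (n_res > 0) q <- q + n_res * frac(side$pka[i], side$polarity[i], ph)
    }
    q
  }, sequence, pH, USE.NAMES = FALSE)
}

#' Theoretical isoelectric point
#'
#' The pH at which the Henderson-Hasselbalch net charge vanishes. The charge
#' curve is strictly decreasing in pH, so the unique root on `[0, 14]` is
#' found by bisection (stops when `|charge| < 1e-6` or the bracketing
#' interval is narrower than `1e-6` pH units).
#'
#' @inheritParams gravy
#' @param pkas pKa set tibble (default the `"pi"` set, see [pka_set()]).
#' @return Numeric vector of pH values.
#' @examples
#' isoelectric_point("AR") # 10.55
#' @export
isoelectric_point <- function(sequence, pkas = pka_set("pi")) {
  sequence <- validate_sequence(sequence)
  vapply(sequence, function(s) {
    lo <- 0
    hi <- 14
    repeat {
      mid <- (lo + hi) / 2
      q <- net_charge(s, mid, pkas)
      if (abs(q) < 1e-6 || (hi - lo) < 1e-6) return(mid)
      if (q > 0) lo <- mid else hi <- mid
    }
  }, numeric(1), USE.NAMES = FALSE)
}

#' Guruprasad instability index
#'
#' `(10 / L) * sum(DIWV(x_i, x_{i+1}))` over the `L - 1` overlapping
#' dipeptides of the sequence. Values above 40 predict in vitro instability.
#' The terminal residue contributes no dipeptide term; single-residue input
#' is rejected rather than defined.
#'
#' @inheritParams gravy
#' @param matrix 20 x 20 dipeptide weight matrix (default
#'   [instability_matrix()]).
#' @return Numeric vector.
#' @examples
#' instability_index(c("TF", "PGL"))
#' @export
instability_index <- function(sequence, matrix = instability_matrix()) {
  sequence <- validate_sequence(sequence)
  if (any(nchar(sequence) < 2)) {
    rlang::abort("The instability index is undefined for single residues (length >= 2 required).")
  }
  vapply(sequence, function(s) {
    ch <- seq_chars(s)
    n <- length(ch)
    (10 / n) * sum(matrix[cbind(ch[-n], ch[-1])])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Water-solubility class
#'
#' `"good"` iff the sequence contains at least one charged-side-chain
#' residue (D, E, K, R, H), else `"poor"` — the rule that reproduces the
#' published good/poor column.
#'
#' @inheritParams gravy
#' @return Character vector of `"good"` / `"poor"`.
#' @export
solubility_class <- function(sequence) {
  sequence <- validate_sequence(sequence)
  ifelse(grepl("[DEKRH]", sequence), "good", "poor")
}

#' Derive interpretation flags from computed descriptors
#'
#' Thresholds follow the standard readings: Boman index > 2.48 kcal/mol for
#' high protein-binding potential, instability index > 40 for in vitro
#' instability, aliphatic index > 100 for thermostability, and length <= 3
#' as the PEPT1/PEPT2 transportability proxy. Flags are computed from the
#' unrounded descriptor values.
#'
#' @param profile Tibble from [physchem_profile()] (columns `sequence`,
#'   `boman`, `instability`, `aliphatic` required).
#' @param boman_threshold,instability_threshold,aliphatic_threshold,transport_max_length
#'   Classification thresholds.
#' @return `profile` with logical columns `high_binding`, `unstable`,
#'   `thermostable`, `pept_transportable` added (or replaced).
#' @export
classify_profile <- function(profile, boman_threshold = 2.48,
                             instability_threshold = 40,
                             aliphatic_threshold = 100,
                             transport_max_length = 3) {
  stopifnot(is.data.frame(profile), all(c("sequence", "boman", "instability", "aliphatic") %in% names(profile)))
  dplyr::mutate(
    profile,
    high_binding = .data$boman > boman_threshold,
    unstable = .data$instability > instability_threshold,
    thermostable = .data$aliphatic > aliphatic_threshold,
    pept_transportable = nchar(.data$sequence) <= transport_max_length
  )
}

#' Full physicochemical profile of peptides
#'
#' Computes the seven descriptors (Boman index, net charge at pH 7,
#' theoretical pI, instability index, aliphatic index, GRAVY, solubility
#' class) plus the interpretation flags for each sequence. Values are
#' unrounded; see [format_physchem()] for the published rounding convention.
#'
#' @param x Character vector of sequences, or a data frame with a `sequence`
#'   column.
#' @param charge_pkas,pi_pkas pKa sets for the charge and pI columns
#'   (defaults: the `"charge"` and `"pi"` sets, see [pka_set()]).
#' @param ... Threshold overrides passed to [classify_profile()].
#' @return A `pep_physchem` tibble, one row per sequence.
#' @examples
#' physchem_profile(c("AR", "IL", "PGL"))
#' @export
physchem_profile <- function(x, charge_pkas = pka_set("charge"),
                             pi_pkas = pka_set("pi"), ...) {
  sequence <- if (is.data.frame(x)) x$sequence else x
  sequence <- validate_sequence(sequence)
  out <- tibble::tibble(
    sequence = sequence,
    boman = boman_index(sequence),
    net_charge = net_charge(sequence, 7, charge_pkas),
    pi = isoelectric_point(sequence, pi_pkas),
    instability = instability_index(sequence),
    aliphatic = aliphatic_index(sequence),
    gravy = gravy(sequence),
    solubility = solubility_class(sequence)
  ) |>
    classify_profile(...)
  class(out) <- c("pep_physchem", class(out))
  out
}

#' Round a physicochemical profile to reporting precision
#'
#' Descriptors to 2 decimals, net charge to 1 decimal, matching the
#' published table convention. Classification flags are untouched (they are
#' always derived from unrounded values).
#'
#' @param profile Tibble from [physchem_profile()].
#' @return Tibble with rounded numeric columns.
#' @export
format_physchem <- function(profile) {
  dplyr::mutate(
    profile,
    dplyr::across(dplyr::any_of(c("boman", "pi", "instability", "aliphatic", "gravy")), ~ round(.x, 2)),
    dplyr::across(dplyr::any_of("net_charge"), ~ round(.x, 1))
  )
}
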