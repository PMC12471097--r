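#' Plot a physicochemical profile
#'
#' Scatter of Boman index against GRAVY, sized by aliphatic index and
#' colored by solubility class, with the high-binding threshold drawn. A
#' compact overview of which released peptides are hydrophilic, soluble and
#' likely to bind protein targets.
#'
#' @param object A `pep_physchem` tibble from [physchem_profile()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.pep_physchem <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$gravy, y = .data$boman,
    colour = .data$solubility, size = .data$aliphatic
  )) +
    ggplot2::geom_hline(yintercept = 2.48, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_text(ggplot2::aes(label = .data$sequence),
      vjust = -0.9, size = 3, show.legend = FALSE
    ) +
    ggplot2::annotate("text",
      x = Inf, y = 2.48, label = "high binding potential",
      hjust = 1.05, vjust = -0.5, size = 3, colour = "grey40"
    ) +
    ggplot2::labs(
      x = "GRAVY (Kyte-Doolittle)", y = "Boman index (kcal/mol)",
      colour = "water solubility", size = "aliphatic index"
    ) +
    ggplot2::theme_minimal()
}

#' Plot fragment coverage of a digestion
#'
#' Shows the released fragments as segments along the parent sequence, with
#' cut sites marked — a quick visual check of the simultaneous cleavage
#' model.
#'
#' @param object A `pep_digestion` from [digest_sequence()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.pep_digestion <- function(object, ...) {
  frag <- tidy(object)
  frag$short <- nchar(frag$fragment) <= 3
  ggplot2::ggplot(frag) +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$start - 0.5, xend = .data$end + 0.5,
        y = .data$fragment, yend = .data$fragment, colour = .data$short
      ),
      linewidth = 3, lineend = "butt"
    ) +
    ggplot2::geom_vline(
      xintercept = attr(object, "cut_sites") + 1.5,
      linetype = "dotted", colour = "grey50"
    ) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#D55E00", `FALSE` = "grey35"),
      labels = c(`TRUE` = "di/tripeptide", `FALSE` = "longer"), name = NULL
    ) +
    ggplot2::labs(
      x = "position on parent (residues)", y = NULL,
      title = attr(object, "parent_id")
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
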