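triage_palette <- c(red = "#d62728", blue = "#1f77b4", green = "#2ca02c")

#' Plot a clustering result
#'
#' For the five-score view this is the MDS plot (two abstract coordinates,
#' points coloured by pathogenicity cluster); for the scatter view it is the
#' REVEL-by-Condel scatter plot.
#'
#' @param object A [cluster_variants()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot triage_clusters
#' @export
autoplot.triage_clusters <- function(object, ...) {
  view <- attr(object, "view")
  axes <- if (identical(view, "scatter")) {
    c("REVEL", "Condel")
  } else {
    c("Coordinate 1", "Coordinate 2")
  }
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$coord1, .data$coord2,
                               colour = .data$color)) +
    ggplot2::geom_point(size = 2, alpha = 0.85) +
    ggplot2::scale_colour_manual(
      values = triage_palette,
      labels = c(red = "possibly pathogenic", blue = "uncertain",
                 green = "possibly benign"),
      name = NULL
    ) +
    ggplot2::labs(x = axes[1], y = axes[2]) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.triage_clusters
#' @param clusters A [cluster_variants()] result.
#' @export
plot_clusters <- function(clusters, ...) autoplot.triage_clusters(clusters, ...)

#' Plot per-cluster score distributions
#'
#' Dot plot of each predictor score stratified by cluster colour, with the
#' CADD score divided by 33 so all five scores share the unit scale;
#' horizontal bars mark cluster means.
#'
#' @param cohort A cohort tibble restricted to scored rows.
#' @param labels Cluster colours aligned with `cohort` rows (or a label
#'   column name).
#' @return A ggplot object.
#' @export
plot_score_panels <- function(cohort, labels) {
  if (is.character(labels) && length(labels) == 1) {
    labels <- cohort[[labels]]
  }
  long <- cohort |>
    dplyr::mutate(.label = labels, cadd_scaled = .data$cadd_phred / 33) |>
    dplyr::filter(!is.na(.data$.label)) |>
    tidyr::pivot_longer(
      cols = dplyr::all_of(c("metalr", "metasvm", "cadd_scaled", "revel",
                             "condel")),
      names_to = "score", values_to = "value"
    ) |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(.data$.label, .data$value,
                                     colour = .data$.label)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7, size = 1.4) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.5,
                          colour = "black", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = triage_palette, guide = "none") +
    ggplot2::facet_wrap(~score, nrow = 1) +
    ggplot2::labs(x = NULL, y = "score") +
    ggplot2::theme_minimal()
}

#' Plot a conservation profile
#'
#' Per-column conservation score along the alignment, with low-coverage
#' (gap-heavy) columns marked.
#'
#' @param profile A [conservation_profile()].
#' @param sites Optional residue numbers to highlight.
#' @return A ggplot object.
#' @export
plot_conservation <- function(profile, sites = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(.data$column, .data$jsd)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(data = profile[profile$low_coverage, ],
                        colour = "orange", size = 1) +
    ggplot2::labs(x = "alignment column", y = "JSD conservation") +
    ggplot2::theme_minimal()
  if (!is.null(sites)) {
    hit <- profile[!is.na(profile$human_residue) &
                     profile$human_residue %in% sites, ]
    p <- p + ggplot2::geom_point(data = hit, colour = "#d62728", size = 2)
  }
  p
}
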