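#' Length-width view of cavity profiles
#'
#' Radius against arc length from the active site, one line per cavity —
#' the view in which bottleneck positions and depths are compared across
#' similar cavities.
#'
#' @param profiles Long profile tibble from [length_width_profiles()].
#' @param clusters Optional assignment tibble; lines are coloured by
#'   cluster instead of drawn anonymously.
#'
#' @return A ggplot object.
#' @export
plot_length_width <- function(profiles, clusters = NULL) {
  if (!is.null(clusters)) {
    profiles <- dplyr::inner_join(profiles, clusters, by = "cavity_id") |>
      dplyr::mutate(cluster = factor(.data$cluster))
    p <- ggplot2::ggplot(profiles, ggplot2::aes(
      .data$arc_length, .data$radius,
      group = .data$cavity_id, colour = .data$cluster
    ))
  } else {
    p <- ggplot2::ggplot(profiles, ggplot2::aes(
      .data$arc_length, .data$radius, group = .data$cavity_id
    ))
  }
  p + ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "Length from active site (Å)",
                  y = "Cavity radius (Å)") +
    ggplot2::theme_minimal()
}

#' Scatter plot of a 2-D cavity projection
#'
#' @param coords Tibble from [project_tsne()].
#' @param groups Optional tibble (`cavity_id` plus a `cluster` or
#'   `template_id` column) used to colour points.
#'
#' @return A ggplot object.
#' @export
plot_projection <- function(coords, groups = NULL) {
  if (!is.null(groups)) {
    key <- intersect(c("cluster", "template_id"), names(groups))[1]
    coords <- dplyr::inner_join(coords, groups, by = "cavity_id") |>
      dplyr::mutate(group = factor(.data[[key]]))
    p <- ggplot2::ggplot(coords, ggplot2::aes(.data$x, .data$y,
                                              colour = .data$group))
  } else {
    p <- ggplot2::ggplot(coords, ggplot2::aes(.data$x, .data$y))
  }
  p + ggplot2::geom_point(size = 1.5, alpha = 0.8) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", colour = "group") +
    ggplot2::theme_minimal()
}

#' Bar view of amino-acid composition
#'
#' Per-cluster mean residue counts (or per-cavity counts) as bars, the
#' view in which composition differences between change patterns show up.
#'
#' @param profile Tibble from [amino_acid_profile()].
#'
#' @return A ggplot object.
#' @export
plot_residue_profile <- function(profile) {
  if ("cluster" %in% names(profile)) {
    ggplot2::ggplot(profile, ggplot2::aes(.data$res_name, .data$mean_n)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::facet_wrap(~cluster, ncol = 1) +
      ggplot2::labs(x = NULL, y = "Mean residues per cavity") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  } else {
    ggplot2::ggplot(profile, ggplot2::aes(.data$res_name, .data$n)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = NULL, y = "Residues lining cavity") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  }
}
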