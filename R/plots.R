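#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Stacked process-fraction bars
#'
#' @param object An `assembly_partition`.
#' @param ... Unused.
#' @return A ggplot: one stacked bar per group showing the five process
#'   fractions.
#' @export
autoplot.assembly_partition <- function(object, ...) {
  frac <- process_fractions(object)
  if (!"group" %in% names(frac)) frac$group <- "all"
  frac$process <- factor(frac$process, levels = rev(process_levels))
  ggplot2::ggplot(frac, ggplot2::aes(x = .data$group, y = .data$fraction,
                                     fill = .data$process)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "fraction of pairwise comparisons",
                  fill = "process") +
    ggplot2::theme_minimal()
}

#' Ordination scatter plot
#'
#' @param object An `eco_pcoa`.
#' @param metadata Optional metadata tibble; points are colored by
#'   `colour` when given.
#' @param colour Metadata column to color by.
#' @param ... Unused.
#' @return A ggplot of the first two axes with variance-explained labels.
#' @export
autoplot.eco_pcoa <- function(object, metadata = NULL, colour = "habitat",
                              ...) {
  df <- object$coords
  aes <- ggplot2::aes(x = .data$axis1, y = .data$axis2)
  if (!is.null(metadata) && colour %in% names(metadata)) {
    df <- dplyr::left_join(df, metadata, by = "sample_id")
    aes <- ggplot2::aes(x = .data$axis1, y = .data$axis2,
                        colour = .data[[colour]])
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PCo2 (%.1f%%)", 100 * object$var_explained[2]),
      title = paste("PCoA,", object$metric)
    ) +
    ggplot2::theme_minimal()
}

#' Observed vs random-network topology
#'
#' Dot-and-interval comparison of observed topology metrics against the
#' Erdos-Renyi ensemble mean +/- sd.
#'
#' @param report A `topology_report` for the observed network.
#' @param ensemble Output of [er_ensemble()] at the same (n, m).
#' @return A ggplot.
#' @export
plot_topology_vs_random <- function(report, ensemble) {
  obs <- glance(report)
  df <- ensemble |>
    dplyr::filter(.data$metric %in% names(obs)) |>
    dplyr::mutate(observed = purrr::map_dbl(.data$metric, ~ obs[[.x]]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric)) +
    ggplot2::geom_pointrange(ggplot2::aes(y = .data$mean,
                                          ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), colour = "red",
                        size = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "value",
                  subtitle = "red = observed, grey = Erdos-Renyi mean +/- sd") +
    ggplot2::theme_minimal()
}

#' Alpha-diversity habitat comparison
#'
#' @param alpha_tbl Output of [alpha_diversity()].
#' @param metadata Metadata tibble with the grouping column.
#' @param group Grouping column name.
#' @return A faceted boxplot ggplot.
#' @export
plot_alpha_diversity <- function(alpha_tbl, metadata, group = "habitat") {
  df <- dplyr::left_join(alpha_tbl, metadata, by = "sample_id") |>
    tidyr::pivot_longer(dplyr::all_of(c("observed_otus", "chao1", "shannon",
                                        "faith_pd")),
                        names_to = "index", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[group]], y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
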