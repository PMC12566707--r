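# ggplot2 figures for the main result types.

#' Heatmap of stage-mean importance values
#'
#' Species-by-stage heatmap of mean IV, optionally row-normalized to
#' `[0, 1]` so each species' trajectory is comparable regardless of its
#' absolute dominance.
#'
#' @param stage_iv A wide species x stage tibble from
#'   [stage_mean_iv()].
#' @param top_n Show the `top_n` species by overall mean IV (default
#'   20).
#' @param normalize Row-normalize each species to `[0, 1]` (default
#'   `TRUE`).
#' @return A ggplot object.
#' @export
plot_iv_heatmap <- function(stage_iv, top_n = 20, normalize = TRUE) {
  df <- stage_iv |>
    head(top_n) |>
    tidyr::pivot_longer(dplyr::all_of(.stages),
                        names_to = "stage", values_to = "iv") |>
    mutate(stage = factor(.data$stage, levels = .stages))
  if (normalize) {
    df <- df |>
      group_by(.data$species) |>
      mutate(iv = if (max(.data$iv) > min(.data$iv)) {
        (.data$iv - min(.data$iv)) / (max(.data$iv) - min(.data$iv))
      } else 0) |>
      ungroup()
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$stage,
                                   factor(.data$species, levels = rev(stage_iv$species[seq_len(min(top_n, nrow(stage_iv)))])),
                                   fill = .data$iv)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = if (normalize) "IV (row 0-1)" else "mean IV") +
    ggplot2::labs(x = "expansion stage", y = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of standardized Resistance Index by species
#'
#' @param resistance A tibble from [resistance_scores()].
#' @param layer Optional single layer to display.
#' @return A ggplot object; bars are colored by class (Resistant /
#'   Neutral / Susceptible).
#' @export
plot_resistance <- function(resistance, layer = NULL) {
  df <- resistance
  if (!is.null(layer)) df <- df |> filter(.data$layer == !!layer)
  df <- df |> filter(is.finite(.data$ri_z))
  ggplot2::ggplot(df, ggplot2::aes(.data$ri_z,
                                   stats::reorder(.data$species, .data$ri_z),
                                   fill = .data$klass)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = c(-1, 1), linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(Resistant = "#2e7d32",
                                          Neutral = "grey60",
                                          Susceptible = "#e65100"),
                               name = NULL) +
    ggplot2::facet_wrap(~layer, scales = "free_y") +
    ggplot2::labs(x = "standardized Resistance Index", y = NULL) +
    ggplot2::theme_minimal()
}

#' Diversity indices by expansion stage
#'
#' Boxplots of one or more diversity indices across the four stages,
#' faceted by layer and index.
#'
#' @param diversity A per-plot diversity tibble (e.g. from
#'   [alpha_diversity()], optionally joined with PD/NRI/NTI columns).
#' @param indices Index columns to plot.
#' @return A ggplot object.
#' @export
plot_diversity_stages <- function(diversity,
                                  indices = c("richness", "shannon", "simpson",
                                              "margalef", "pielou")) {
  df <- diversity |>
    tidyr::pivot_longer(dplyr::all_of(indices),
                        names_to = "index", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$stage, .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::facet_grid(index ~ layer, scales = "free_y") +
    ggplot2::labs(x = "expansion stage", y = NULL) +
    ggplot2::theme_minimal()
}

#' Triplot of a gradient RDA
#'
#' Sites as points, responses and predictors as arrows on the first two
#' constrained axes.
#'
#' @param object An `rda_gradient` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rda_gradient <- function(object, ...) {
  if (length(object$explained_fraction_per_axis) < 2) {
    stop_validation("triplot needs at least 2 constrained axes")
  }
  sites <- as.data.frame(object$site_scores[, 1:2])
  names(sites) <- c("a1", "a2")
  resp <- as.data.frame(object$response_scores[, 1:2])
  names(resp) <- c("a1", "a2"); resp$label <- rownames(object$response_scores)
  pred <- as.data.frame(object$predictor_scores[, 1:2])
  names(pred) <- c("a1", "a2"); pred$label <- rownames(object$predictor_scores)
  sc <- max(abs(sites)) / max(abs(pred))
  ggplot2::ggplot(sites, ggplot2::aes(.data$a1, .data$a2)) +
    ggplot2::geom_point(size = 2, colour = "grey30") +
    ggplot2::geom_segment(data = resp,
                          ggplot2::aes(x = 0, y = 0, xend = .data$a1, yend = .data$a2),
                          colour = "steelblue",
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_text(data = resp, ggplot2::aes(label = .data$label),
                       colour = "steelblue", vjust = -0.6, size = 3) +
    ggplot2::geom_segment(data = pred,
                          ggplot2::aes(x = 0, y = 0,
                                       xend = .data$a1 * sc, yend = .data$a2 * sc),
                          colour = "darkorange",
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_text(data = pred,
                       ggplot2::aes(x = .data$a1 * sc, y = .data$a2 * sc,
                                    label = .data$label),
                       colour = "darkorange", vjust = 1.4, size = 3) +
    ggplot2::labs(
      x = sprintf("RDA1 (%.1f%% of constrained)", object$explained_fraction_per_axis[1]),
      y = sprintf("RDA2 (%.1f%% of constrained)", object$explained_fraction_per_axis[2])
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of variance-partitioning fractions
#'
#' @param object A `vpa_fractions` tibble from [variance_partition()]
#'   (possibly several layers bound together with a `layer` column).
#' @param ... Unused.
#' @return A ggplot object showing the clamped display fractions.
#' @export
autoplot.vpa_fractions <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(component = factor(.data$component,
                              levels = c("unique_cover", "shared",
                                         "unique_soil", "unexplained")))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$component,
                                        .data$fraction_display,
                                        fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(unique_cover = "#2e7d32",
                                          shared = "grey55",
                                          unique_soil = "#795548",
                                          unexplained = "grey85"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = "fraction of total variance") +
    ggplot2::theme_minimal()
  if ("layer" %in% names(df)) p <- p + ggplot2::facet_wrap(~layer)
  p
}
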