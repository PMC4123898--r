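#' Map a raster with ggplot2
#'
#' @param r A [bd_raster()] (e.g. dNPV or mortality).
#' @param name Legend title.
#' @return A ggplot object.
#' @export
plot_raster <- function(r, name = "value") {
  df <- raster_to_tibble(r)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = name, na.value = "grey80") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)") +
    ggplot2::theme_minimal()
}

#' Map delineated gaps
#'
#' @param gapmap A `bd_gapmap` from [label_gaps()].
#' @return A ggplot object; background pixels are blank.
#' @export
plot_gapmap <- function(gapmap) {
  df <- raster_to_tibble(gapmap$labels)
  df$value[df$value == 0] <- NA
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = factor(.data$value))) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(
      x = "easting (m)", y = "northing (m)",
      title = sprintf("%d gaps at dNPV >= %g", nrow(gapmap$gaps),
                      gapmap$threshold)) +
    ggplot2::theme_minimal()
}

#' Ordination diagram of an NMDS fit
#'
#' @param object A `bd_nmds` from [nmds_ordination()].
#' @param colour Optional vector (e.g. sub-plot mortality) to colour
#'   points by.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bd_nmds <- function(object, colour = NULL, ...) {
  df <- object$scores
  p <- if (is.null(colour)) {
    ggplot2::ggplot(df, ggplot2::aes(.data$NMDS1, .data$NMDS2))
  } else {
    df$colour <- colour
    ggplot2::ggplot(df, ggplot2::aes(.data$NMDS1, .data$NMDS2,
                                     colour = .data$colour)) +
      ggplot2::scale_colour_viridis_c(name = "mortality (%)")
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(
      title = sprintf("NMDS (stress = %.3f)", object$stress)) +
    ggplot2::theme_minimal()
}

#' Diversity along the mortality gradient
#'
#' Richness, Shannon diversity and rarefied richness of the
#' mortality-ranked groups against group mean mortality.
#'
#' @param div Output of [diversity_by_group()].
#' @return A ggplot object (facetted by measure).
#' @export
plot_diversity_gradient <- function(div) {
  long <- tidyr::pivot_longer(
    div, c("richness", "shannon", "rarefied_richness"),
    names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$mean_mortality_pct,
                                     .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x + I(x^2),
                         se = FALSE, linewidth = 0.4) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "group mean sub-plot mortality (%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Genus response curves along the mortality gradient
#'
#' @param guilds Output of [genus_guilds()].
#' @return A ggplot object; one line per genus, coloured by guild.
#' @export
plot_guild_curves <- function(guilds) {
  df <- purrr::map_dfr(guilds$curves, tidy) |>
    dplyr::left_join(guilds$summary[, c("genus", "guild")], by = "genus")
  ggplot2::ggplot(df, ggplot2::aes(.data$mortality_pct, .data$fitted,
                                   group = .data$genus,
                                   colour = .data$guild)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "sub-plot mortality (%)",
                  y = "fitted abundance per group",
                  colour = "guild") +
    ggplot2::theme_minimal()
}
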