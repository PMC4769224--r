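#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_raster geom_col
#'   scale_fill_manual coord_equal labs theme_minimal position_fill
#' @export
ggplot2::autoplot

#' Plot a crypt lattice
#'
#' @param object A [generate_lattice()] result.
#' @param ... Unused.
#' @return A ggplot: crypt centres coloured by lineage.
#' @export
autoplot.crypt_lattice <- function(object, ...) {
  ggplot(object, aes(x = .data$x, y = .data$y, colour = .data$lineage)) +
    geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(RED = "#d73027", GREEN = "#1a9850")) +
    coord_equal() +
    labs(x = "x (µm)", y = "y (µm)", colour = "lineage") +
    theme_minimal()
}

#' Plot a label map
#'
#' @param object A [label_map()].
#' @param ... Unused.
#' @return A ggplot raster: red, green, and non-tissue pixels.
#' @export
autoplot.label_map <- function(object, ...) {
  lab <- object$labels
  df <- tibble(
    x = rep(seq_len(nrow(lab)), times = ncol(lab)) * object$pixel_size,
    y = rep(seq_len(ncol(lab)), each = nrow(lab)) * object$pixel_size,
    label = factor(c("NON_TISSUE", "RED", "GREEN")[as.vector(lab) + 1L],
                   levels = c("RED", "GREEN", "NON_TISSUE")))
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$label)) +
    geom_raster() +
    scale_fill_manual(values = c(RED = "#d73027", GREEN = "#1a9850",
                                 NON_TISSUE = "#ffffbf")) +
    coord_equal() +
    labs(x = "x (µm)", y = "y (µm)", fill = NULL) +
    theme_minimal()
}

#' Plot an architecture table
#'
#' @param object An [tabulate_architecture()] result.
#' @param ... Unused.
#' @return A ggplot: phenotype composition per pathological category.
#' @export
autoplot.architecture_table <- function(object, ...) {
  df <- tidy(object) |> dplyr::filter(.data$category != "Total")
  ggplot(df, aes(x = .data$category, y = .data$count,
                 fill = .data$phenotype)) +
    geom_col(position = position_fill()) +
    scale_fill_manual(values = c(heterotypic = "#fee08b",
                                 homotypic_red = "#d73027",
                                 homotypic_green = "#1a9850")) +
    labs(x = NULL, y = "fraction of tumors", fill = NULL) +
    theme_minimal()
}

#' Plot detection power against the number of scored tumors
#'
#' @param f True multi-ancestral fraction(s); one curve per value.
#' @param p Green lineage fraction.
#' @param N Founder count.
#' @param n_max Largest cohort size on the x axis.
#' @return A ggplot of [detection_power()] curves.
#' @export
plot_power_curve <- function(f = c(0.01, 0.05, 0.1), p = 0.376, N = 2,
                             n_max = 300) {
  grid <- tidyr::expand_grid(n = seq_len(n_max), f = f) |>
    dplyr::mutate(power = detection_power(.data$n, .data$f, p, N),
                  f = factor(.data$f))
  ggplot(grid, aes(x = .data$n, y = .data$power, colour = .data$f)) +
    ggplot2::geom_line() +
    labs(x = "tumors scored (n)", y = "power to detect ≥ 1 heterotypic",
         colour = "multi-ancestral\nfraction f") +
    theme_minimal()
}
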