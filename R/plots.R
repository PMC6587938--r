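#' Plot an empirical semivariogram (and optional fitted model)
#'
#' Points are the binned semivariances sized by pair count; the cloud is
#' shown faintly behind them; a fitted model curve can be overlaid.
#'
#' @param object An `empirical_variogram` or `variogram_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.empirical_variogram <- function(object, ...) {
  cloud <- variogram_cloud(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$h, y = .data$gamma)) +
    ggplot2::geom_point(data = cloud, alpha = 0.15, size = 0.7) +
    ggplot2::geom_point(ggplot2::aes(size = .data$np), colour = "steelblue") +
    ggplot2::scale_size_area(max_size = 4, name = "pairs") +
    ggplot2::labs(x = "lag h (m)", y = expression(hat(gamma)(h)),
                  title = attr(object, "attribute")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.empirical_variogram
#' @export
autoplot.variogram_fit <- function(object, ...) {
  emp <- object$empirical
  hh <- seq(0, max(emp$h), length.out = 200)
  curve <- tibble::tibble(h = hh, gamma = model_curve(object, hh))
  autoplot.empirical_variogram(emp) +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::labs(subtitle = sprintf("%s fit: nugget/sill = %.2f (%s dependence)",
                                     object$family, nugget_sill_ratio(object),
                                     spatial_dependence_class(object)))
}

#' Map a kriging result
#'
#' Filled-tile map of predictions (or kriging variance) over the grid.
#'
#' @param object A `kriging_result`.
#' @param what `"prediction"` or `"variance"`.
#' @param observed Optional data frame of observed points (`easting`,
#'   `northing`) overlaid as circles.
#' @param ... Unused.
#' @export
autoplot.kriging_result <- function(object, what = c("prediction", "variance"),
                                    observed = NULL, ...) {
  what <- match.arg(what)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$easting, y = .data$northing)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data[[what]])) +
    ggplot2::scale_fill_viridis_c(name = what) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Easting (m)", y = "Northing (m)",
                  title = attr(object, "attribute")) +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_point(data = observed, shape = 21, fill = "white")
  }
  p
}

#' Plot a Mantel correlogram
#'
#' Statistic per distance class; filled points are classes significant at the
#' given level.
#'
#' @param object A `mantel_correlogram`.
#' @param alpha Significance level for filling points (default 0.05).
#' @param ... Unused.
#' @export
autoplot.mantel_correlogram <- function(object, alpha = 0.05, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      significant = .data$p_value < alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$statistic)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(fill = .data$significant), shape = 21, size = 2.5) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "white", `TRUE` = "black"),
                               name = sprintf("p < %.2g", alpha)) +
    ggplot2::labs(x = "distance class centre (m)", y = "Mantel statistic") +
    ggplot2::theme_minimal()
}

#' Heatmap-style plot of a taxa-environment correlation table
#'
#' Tiles coloured by Spearman r; non-significant cells are blanked, echoing
#' the usual two-tier (p < 0.05 / p < 0.01) presentation.
#'
#' @param object A `correlation_table` from [spearman_matrix()].
#' @param ... Unused.
#' @export
autoplot.correlation_table <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      r_shown = ifelse(.data$tier == "ns", NA_real_, .data$r))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variable, y = .data$taxon)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$r_shown), colour = "grey80") +
    ggplot2::scale_fill_gradient2(low = "darkred", mid = "white", high = "darkblue",
                                  limits = c(-1, 1), na.value = "grey95",
                                  name = "Spearman r") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
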