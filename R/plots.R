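#' Plot a group-level PPMR table
#'
#' Group mean PPMR against weighted mean predator body mass on log10 axes,
#' coloured by the proportion of fish in the diet (by biomass for `R_bio`,
#' by numbers for `R_num`).
#'
#' @param object A [ppmr_groups()] table.
#' @param metric `"R_bio"` or `"R_num"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ppmr_groups <- function(object, metric = c("R_bio", "R_num"), ...) {
  metric <- match.arg(metric)
  mass <- if (metric == "R_bio") "mean_mass_biow_g" else "mean_mass_numw_g"
  fish <- if (metric == "R_bio") "fish_prop_mass" else "fish_prop_count"
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[mass]], y = .data[[metric]],
                                       colour = .data[[fish]])) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "Weighted mean predator body mass (g)",
                  y = metric, colour = "Fish in diet") +
    ggplot2::theme_minimal()
}

#' Plot the sequential Bayesian R-squared decomposition
#'
#' @param object A [bayesian_r2()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ppmr_r2 <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$level_set, y = .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$hpd_lo, ymax = .data$hpd_hi)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Coefficients included", y = "Bayesian R²") +
    ggplot2::theme_minimal()
}

#' Plot community-wide mean PPMR by region
#'
#' Median community PPMR against size class with the 5th-95th percentile
#' band, one panel per region.
#'
#' @param object A [community_ppmr()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ppmr_community <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_lo_log10g + 0.05)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q05, ymax = .data$q95),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$region)) +
    ggplot2::labs(x = "log10 predator body mass (g)",
                  y = paste("Community", object$metric[1])) +
    ggplot2::theme_minimal()
}

#' Plot the fitted fixed-effect mass relationship with the group data
#'
#' @param object A [fit_ppmr()] object.
#' @param n_grid Number of mass values for the fitted curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ppmr_fit <- function(object, n_grid = 100, ...) {
  lx <- seq(min(object$design$lx), max(object$design$lx), length.out = n_grid)
  eta <- object$draws[, sprintf("beta[%d]", 1:3)] %*% t(apply_scaler(object$design$scaler, lx))
  band <- apply(eta, 2, quantile, c(0.05, 0.5, 0.95))
  curve <- tibble::tibble(lx = lx, lo = 10^band[1, ], mid = 10^band[2, ],
                          hi = 10^band[3, ])
  pts <- tibble::tibble(lx = object$design$lx, R = 10^object$design$y)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$lx)) +
    ggplot2::geom_point(data = pts, ggplot2::aes(y = .data$R),
                        alpha = 0.3, colour = "grey40") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.3, fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mid), colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "log10 predator body mass (g)", y = object$response) +
    ggplot2::theme_minimal()
}
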