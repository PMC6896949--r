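#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a contribution likelihood surface
#'
#' Filled tiles of the log-likelihood over the `(a, b)` lattice, with the
#' maximiser marked.
#'
#' @param object A [estimate_contributions()] fit with a retained surface.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.contribution_fit <- function(object, ...) {
  surf <- likelihood_surface(object)
  surf <- surf[is.finite(surf$lnp), ]
  ggplot2::ggplot(surf, ggplot2::aes(x = .data$a, y = .data$b,
                                     fill = .data$lnp)) +
    ggplot2::geom_tile() +
    ggplot2::annotate("point", x = object$a, y = object$b,
                      colour = "white", shape = 4, size = 3) +
    ggplot2::scale_fill_viridis_c(name = "ln P") +
    ggplot2::labs(
      x = sprintf("a (%s)", object$sources[1]),
      y = sprintf("b (%s)", object$sources[2]),
      title = "Admixture contribution log-likelihood"
    )
}

#' Plot an ABC founder-size scan
#'
#' Matching frequency against candidate founder sample size, with the
#' optimum marked.
#'
#' @param object An [abc_scan()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.abc_scan <- function(object, ...) {
  g <- ggplot2::ggplot(object$grid,
                       ggplot2::aes(x = .data$n_founders,
                                    y = .data$matching_frequency)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "founder sample size N", y = "matching frequency",
                  title = "ABC founder-size scan")
  if (!object$no_signal) {
    g <- g + ggplot2::geom_vline(xintercept = object$optimal_n,
                                 linetype = "dashed")
  }
  g
}

#' Plot a rarefaction table with its fitted saturation curve
#'
#' @param object A [shannon_rarefaction()] table.
#' @param fit Optional [fit_saturation_curve()] result to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.saturation_tbl <- function(object, fit = NULL, ...) {
  g <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$sample_size,
                                    y = .data$proportion_i)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "sample size", y = "proportion of Shannon index",
                  title = "Shannon-index saturation")
  if (!is.null(fit)) {
    grid <- tibble(sample_size = seq(min(object$sample_size),
                                     max(object$sample_size), length.out = 200))
    grid$proportion_i <- predict(fit, grid)
    g <- g + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  g
}

#' Plot a skyline series with its fastest-growth interval
#'
#' @param object A [skyline_tbl()] series.
#' @param growth Optional [fastest_growth_interval()] estimate to shade.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.skyline_tbl <- function(object, growth = NULL, ...) {
  g <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$time, y = .data$ne)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "years before present", y = "effective size Ne",
                  title = "Bayesian skyline")
  if (!is.null(growth)) {
    g <- g + ggplot2::annotate("rect",
                               xmin = growth$start_time, xmax = growth$end_time,
                               ymin = -Inf, ymax = Inf, alpha = 0.15,
                               fill = "tomato")
  }
  g
}
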