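# ggplot2 views of the analysis results.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_step
#'   geom_abline scale_x_log10 scale_y_log10 labs theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot an MSD series
#'
#' Log-log MSD vs lag; the dashed line shows the free-diffusion slope 1
#' through the last point.
#'
#' @param object An [msd_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msd_series <- function(object, ...) {
  ggplot(object, aes(x = .data$lag_ps, y = .data$msd)) +
    geom_point() + geom_line(alpha = 0.4) +
    scale_x_log10() + scale_y_log10() +
    labs(x = "lag Δt (ps)", y = "MSD (nm²)") +
    theme_minimal()
}

#' Plot apparent diffusion coefficients vs observation interval
#'
#' `D_app(lag) = MSD / (6 lag)`: decreases from the single-bead value
#' towards the center-of-mass coefficient for connected beads, and drops
#' at short lags under inertial (Langevin) dynamics.
#'
#' @param series An [msd_curve()] result.
#' @return A ggplot.
#' @export
plot_apparent_D <- function(series) {
  ggplot(series, aes(x = .data$lag_ps, y = .data$D_app)) +
    geom_point() + geom_line(alpha = 0.4) +
    scale_x_log10() + scale_y_log10() +
    labs(x = "observation interval Δt (ps)",
         y = expression(D[app] ~ (nm^2 / ps))) +
    theme_minimal()
}

#' Plot an orientation autocorrelation and its fit
#' @param object A [rotational_relaxation()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bd_fit_tau <- function(object, ...) {
  p <- ggplot(object$acf, aes(x = .data$lag_ps, y = .data$C)) +
    geom_point() +
    labs(x = "lag (ps)", y = "<u(0) · u(t)>") +
    theme_minimal()
  if (is.finite(object$tau))
    p <- p + geom_line(data = tibble(
      lag_ps = object$acf$lag_ps,
      C = exp(-object$acf$lag_ps / object$tau)), colour = "red3")
  p
}

#' Plot a scaling fit
#' @param object A [scaling_exponent()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bd_fit_scaling <- function(object, ...) {
  df <- tibble(size = exp(object$fit$model[["log(size)"]]),
               value = exp(object$fit$model[["log(value)"]]))
  ggplot(df, aes(x = .data$size, y = .data$value)) +
    geom_point(size = 2) +
    geom_line(data = tibble(size = df$size,
                            value = exp(stats::fitted(object$fit))),
              colour = "red3") +
    scale_x_log10() + scale_y_log10() +
    labs(x = "N", y = "value",
         title = sprintf("scaling exponent %.3f ± %.3f",
                         object$exponent, object$se)) +
    theme_minimal()
}

#' Plot a cumulative transport curve and its straight-line fit
#' @param object A [transport_fit()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bd_fit_transport <- function(object, ...) {
  df <- tibble(time_ps = object$fit$model$time_ps,
               N_L = object$fit$model$N_L)
  ggplot(df, aes(x = .data$time_ps, y = .data$N_L)) +
    geom_step() +
    geom_abline(intercept = coef(object$fit)[1], slope = coef(object$fit)[2],
                colour = "red3") +
    labs(x = "time (ps)", y = expression(N[L]),
         title = sprintf("R_D = %.3g us^-1, T_D = %.3g us",
                         object$R_D * 1e6, object$T_D / 1e6)) +
    theme_minimal()
}

#' Plot network measures over time
#'
#' Three stacked views of a [network_timeseries()]: the cluster-size
#' band, mean/max degree, and the count and mean size of non-trivial
#' clusters.
#'
#' @param object A `network_series`.
#' @param ... Unused.
#' @return A ggplot (cluster sizes panel); the degree and cluster-count
#'   panels are available via `plot_network_degrees()` and
#'   `plot_network_clusters()`.
#' @export
autoplot.network_series <- function(object, ...) {
  sizes <- object |>
    dplyr::select("time_ps", "cluster_sizes") |>
    tidyr::unnest("cluster_sizes")
  ggplot(sizes, aes(x = .data$time_ps / 1e6, y = .data$cluster_sizes)) +
    geom_point(shape = 15, size = 0.8, alpha = 0.6) +
    labs(x = "time (µs)", y = "cluster sizes present") +
    theme_minimal()
}

#' @rdname autoplot.network_series
#' @param series A `network_series`.
#' @export
plot_network_degrees <- function(series) {
  df <- tidyr::pivot_longer(series[, c("time_ps", "mean_degree", "max_degree")],
                            -"time_ps")
  ggplot(df, aes(x = .data$time_ps / 1e6, y = .data$value,
                 colour = .data$name)) +
    geom_line() +
    labs(x = "time (µs)", y = "degree", colour = NULL) +
    theme_minimal()
}

#' @rdname autoplot.network_series
#' @export
plot_network_clusters <- function(series) {
  df <- tidyr::pivot_longer(series[, c("time_ps", "n_clusters_gt1",
                                       "mean_size_gt1")], -"time_ps")
  ggplot(df, aes(x = .data$time_ps / 1e6, y = .data$value,
                 colour = .data$name)) +
    geom_line() +
    labs(x = "time (µs)", y = NULL, colour = NULL) +
    theme_minimal()
}
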