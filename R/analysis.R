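# Trajectory post-processing: mean-squared displacements and diffusion
# coefficients, rotational relaxation, scaling exponents, transport fits.

frames_of <- function(x) {
  if (inherits(x, "bd_trajectory")) x$frames else as_tibble(x)
}

default_lags <- function(n_frames, n_out = 40) {
  mx <- n_frames - 1
  if (mx < 1) abort("need at least two frames")
  unique(round(exp(seq(0, log(mx), length.out = min(n_out, mx)))))
}

#' Time- and ensemble-averaged mean-squared displacement
#'
#' Overlapping-window time average over each trace plus an ensemble
#' average over equivalent traces (all beads, or all protein centers of
#' mass). Coordinates must be unwrapped (the engine records unwrapped
#' positions, with periodic crossings accumulated).
#'
#' @param x A `bd_trajectory` or a frames tibble.
#' @param target `"bead"` (per-gestalt displacements) or `"com"`
#'   (per-protein center of mass; used directly if the trajectory was
#'   recorded with the `"com_ee"` reducer).
#' @param lags Integer frame lags; default ~40 log-spaced lags. Lags
#'   beyond the trajectory length are dropped with a warning.
#' @return A tibble (class `msd_series`) with `lag_ps`, `msd` (nm^2) and
#'   `n` (sample count), plus `D_app = msd / (6 lag)`.
#' @export
msd_curve <- function(x, target = c("bead", "com"), lags = NULL) {
  target <- match.arg(target)
  fr <- frames_of(x)
  if (target == "com" && !"gestalt" %in% names(fr)) {
    traces <- fr |> dplyr::group_by(.data$protein)
  } else if (target == "com") {
    fr <- fr |>
      dplyr::group_by(.data$frame, .data$time_ps, .data$protein) |>
      dplyr::summarise(x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
                       .groups = "drop")
    traces <- fr |> dplyr::group_by(.data$protein)
  } else {
    if (!"gestalt" %in% names(fr))
      abort("per-bead MSD needs a full (non-reduced) trajectory")
    traces <- fr |> dplyr::group_by(.data$gestalt)
  }
  keys <- dplyr::group_keys(traces)
  parts <- dplyr::group_split(traces)
  n_frames <- min(vapply(parts, nrow, 1L))
  lags <- sort(unique(as.integer(lags %||% default_lags(n_frames))))
  if (any(lags >= n_frames)) {
    warn(sprintf("dropping %d lag(s) >= trajectory length", sum(lags >= n_frames)))
    lags <- lags[lags < n_frames]
  }
  if (!length(lags)) abort("no usable lags")
  dt_frame <- diff(sort(unique(parts[[1]]$time_ps))[1:2])
  acc <- numeric(length(lags)); cnt <- numeric(length(lags))
  for (tr in parts) {
    tr <- tr[order(tr$frame), ]
    m <- cbind(tr$x, tr$y, tr$z)
    nf <- nrow(m)
    for (j in seq_along(lags)) {
      l <- lags[j]
      d <- m[(l + 1):nf, , drop = FALSE] - m[1:(nf - l), , drop = FALSE]
      acc[j] <- acc[j] + sum(d * d)
      cnt[j] <- cnt[j] + (nf - l)
    }
  }
  out <- tibble(lag_ps = lags * dt_frame, msd = acc / cnt, n = cnt)
  out$D_app <- out$msd / (6 * out$lag_ps)
  class(out) <- c("msd_series", class(out))
  out
}

#' Long-time diffusion coefficient from an MSD series
#'
#' Least-squares slope of MSD vs lag over a fit window (default: the last
#' decade of lags, the long-time linear regime), divided by 6.
#'
#' @param series An [msd_curve()] result.
#' @param window Lag window `c(min, max)` in ps; default
#'   `c(max(lag)/10, max(lag))`.
#' @return A `bd_fit_D` object with elements `D`, `se`, `fit`; see
#'   [tidy()] / [glance()].
#' @export
fit_long_time_D <- function(series, window = NULL) {
  window <- window %||% c(max(series$lag_ps) / 10, max(series$lag_ps))
  use <- series[series$lag_ps >= window[1] & series$lag_ps <= window[2], ]
  if (nrow(use) < 3) abort("fewer than 3 MSD points in the fit window",
                           class = "brownsim_fit_error")
  fit <- lm(msd ~ lag_ps, data = use)
  sm <- summary(fit)$coefficients
  structure(list(D = unname(coef(fit)[2] / 6), se = sm[2, 2] / 6,
                 window = window, n = nrow(use), fit = fit),
            class = "bd_fit_D")
}

#' @export
print.bd_fit_D <- function(x, ...) {
  cat(sprintf("<long-time D = %.4g +/- %.2g nm^2/ps (%d lags in [%.3g, %.3g] ps)>\n",
              x$D, x$se, x$n, x$window[1], x$window[2]))
  invisible(x)
}

#' @export
tidy.bd_fit_D <- function(x, ...) {
  tibble(term = "D", estimate = x$D, std.error = x$se)
}

#' @export
glance.bd_fit_D <- function(x, ...) {
  tibble(D = x$D, se = x$se, n_lags = x$n,
         r.squared = summary(x$fit)$r.squared)
}

#' Orientation traces from a trajectory
#'
#' @param x A `bd_trajectory` or frames tibble.
#' @param vector `"end_to_end"` (first to last gestalt of each protein;
#'   taken directly from `"com_ee"`-reduced frames) or `"body_axis"`
#'   (gestalt z axis from the orientation quaternions).
#' @return Tibble with `protein` (or `gestalt`), `time_ps`, `ux`, `uy`,
#'   `uz` (unnormalised).
#' @export
orientation_series <- function(x, vector = c("end_to_end", "body_axis")) {
  vector <- match.arg(vector)
  fr <- frames_of(x)
  if (vector == "end_to_end") {
    if ("ex" %in% names(fr))
      return(tibble(protein = fr$protein, time_ps = fr$time_ps,
                    ux = fr$ex, uy = fr$ey, uz = fr$ez))
    fr |>
      dplyr::group_by(.data$frame, .data$time_ps, .data$protein) |>
      dplyr::summarise(ux = .data$x[dplyr::n()] - .data$x[1],
                       uy = .data$y[dplyr::n()] - .data$y[1],
                       uz = .data$z[dplyr::n()] - .data$z[1], .groups = "drop") |>
      dplyr::select("protein", "time_ps", "ux", "uy", "uz")
  } else {
    if (!"qw" %in% names(fr))
      abort("body_axis needs a full trajectory with orientations")
    # z axis of the body frame
    tibble(protein = fr$protein, gestalt = fr$gestalt, time_ps = fr$time_ps,
           ux = 2 * (fr$qx * fr$qz + fr$qw * fr$qy),
           uy = 2 * (fr$qy * fr$qz - fr$qw * fr$qx),
           uz = 1 - 2 * (fr$qx^2 + fr$qy^2))
  }
}

#' Rotational relaxation time of an orientation vector
#'
#' Normalised orientation autocorrelation `C(t) = <u(0) . u(t)>` (time-
#' and ensemble-averaged), fitted by a single exponential over lags up to
#' the first crossing of `exp(-2)`; `tau_rot` is the fitted decay time.
#' For a rigid sphere `tau_rot = 1 / (2 D_rot)`. If the correlation never
#' decays below `exp(-1)` within the trajectory the fit is flagged
#' unreliable (`tau = Inf` for a frozen orientation).
#'
#' @param x A `bd_trajectory`, frames tibble, or an [orientation_series()]
#'   tibble.
#' @param vector Passed to [orientation_series()] when `x` is a
#'   trajectory.
#' @param lags Integer frame lags (default: all up to half the length).
#' @return A `bd_fit_tau` with `tau` (ps), `se`, `reliable`, and the
#'   correlation curve in `$acf`.
#' @export
rotational_relaxation <- function(x, vector = "end_to_end", lags = NULL) {
  u <- if (is.data.frame(x) && "ux" %in% names(x)) as_tibble(x)
       else orientation_series(x, vector)
  key <- if ("gestalt" %in% names(u)) "gestalt" else "protein"
  parts <- dplyr::group_split(dplyr::group_by(u, .data[[key]]))
  n_frames <- min(vapply(parts, nrow, 1L))
  # default grid: at most ~400 lags up to half the trajectory (the
  # correlation sum is O(n_frames) per lag)
  lags <- lags %||% unique(round(seq(1, max(1, n_frames %/% 2),
                                     length.out = 400)))
  lags <- sort(unique(c(0L, as.integer(lags))))
  dt_frame <- diff(sort(unique(parts[[1]]$time_ps))[1:2])
  acc <- numeric(length(lags)); cnt <- numeric(length(lags))
  for (tr in parts) {
    tr <- tr[order(tr$time_ps), ]
    m <- cbind(tr$ux, tr$uy, tr$uz)
    nv <- sqrt(rowSums(m^2))
    if (any(nv < 1e-12)) abort("zero orientation vector in trajectory")
    m <- m / nv
    nf <- nrow(m)
    for (j in seq_along(lags)) {
      l <- lags[j]
      acc[j] <- acc[j] + sum(m[(l + 1):nf, , drop = FALSE] * m[1:(nf - l), , drop = FALSE])
      cnt[j] <- cnt[j] + (nf - l)
    }
  }
  acf <- tibble(lag_ps = lags * dt_frame, C = acc / cnt)
  # fit window: lag 0 to the first crossing of exp(-2)
  cross2 <- which(acf$C < exp(-2))[1]
  reliable <- TRUE
  if (all(acf$C > 0.999999)) {                       # frozen orientation
    return(structure(list(tau = Inf, se = NA_real_, reliable = FALSE,
                          acf = acf, fit = NULL), class = "bd_fit_tau"))
  }
  if (!any(acf$C < exp(-1), na.rm = TRUE)) {
    warn("orientation correlation never decays below exp(-1); tau_rot unreliable")
    reliable <- FALSE
  }
  if (is.na(cross2)) cross2 <- nrow(acf)
  use <- acf[seq_len(cross2), ]
  use <- use[use$C > 0, ]
  if (nrow(use) < 3) {
    use <- acf[acf$C > 0, ][seq_len(min(3, sum(acf$C > 0))), ]
    reliable <- FALSE
  }
  fit <- lm(log(C) ~ lag_ps, data = use)
  sl <- coef(fit)[2]
  se <- summary(fit)$coefficients[2, 2]
  structure(list(tau = unname(-1 / sl), se = unname(se / sl^2),
                 reliable = reliable, acf = acf, fit = fit),
            class = "bd_fit_tau")
}

#' @export
print.bd_fit_tau <- function(x, ...) {
  cat(sprintf("<tau_rot = %.4g ps +/- %.2g%s>\n", x$tau, x$se,
              if (x$reliable) "" else " (unreliable)"))
  invisible(x)
}

#' @export
tidy.bd_fit_tau <- function(x, ...) {
  tibble(term = "tau_rot", estimate = x$tau, std.error = x$se)
}

#' @export
glance.bd_fit_tau <- function(x, ...) {
  tibble(tau = x$tau, se = x$se, reliable = x$reliable)
}

#' Power-law scaling exponent
#'
#' Least-squares slope of `log(value)` vs `log(size)`; e.g. the
#' center-of-mass diffusion coefficient of bead-spring polymers scales as
#' N^-1 without hydrodynamic interactions.
#'
#' @param size Sizes (e.g. bead numbers), all > 0, length >= 3.
#' @param value Measured values, all > 0.
#' @return A `bd_fit_scaling` with `exponent`, `se`.
#' @examples
#' scaling_exponent(c(3, 5, 10, 15), c(3, 5, 10, 15)^-1)
#' @export
scaling_exponent <- function(size, value) {
  if (is.data.frame(size)) { value <- size[[2]]; size <- size[[1]] }
  if (length(size) < 3) abort("need at least 3 points",
                              class = "brownsim_fit_error")
  if (any(size <= 0) || any(value <= 0))
    abort("sizes and values must be positive", class = "brownsim_fit_error")
  fit <- lm(log(value) ~ log(size))
  sm <- summary(fit)$coefficients
  structure(list(exponent = unname(coef(fit)[2]), se = sm[2, 2], fit = fit),
            class = "bd_fit_scaling")
}

#' @export
print.bd_fit_scaling <- function(x, ...) {
  cat(sprintf("<scaling exponent = %.4g +/- %.2g>\n", x$exponent, x$se))
  invisible(x)
}

#' @export
tidy.bd_fit_scaling <- function(x, ...) {
  tibble(term = "exponent", estimate = x$exponent, std.error = x$se)
}

#' @export
glance.bd_fit_scaling <- function(x, ...) {
  tibble(exponent = x$exponent, se = x$se,
         r.squared = summary(x$fit)$r.squared)
}

#' Cumulative interface transport log
#'
#' @param x A `bd_trajectory` with interface events, or an events tibble.
#' @param type Event type to accumulate (default absorptions).
#' @param side Restrict to interfaces on this side (`"low"` / `"high"`),
#'   e.g. `"high"` for the exit count N_L at the rho = 0 boundary of the
#'   transport setup; `NULL` keeps all interfaces.
#' @param interface Alternatively, an interface index to keep.
#' @param times Optional time grid (ps) on which to evaluate the
#'   cumulative count (default: the trajectory's frame times).
#' @return Tibble with `time_ps`, `N_L` (cumulative count) and, when
#'   available, `n_p` (mobile particle number).
#' @export
transport_log <- function(x, type = "absorb", side = NULL, interface = NULL,
                          times = NULL) {
  ev <- if (inherits(x, "bd_trajectory")) x$events else as_tibble(x)
  ev <- ev[ev$type == type, ]
  if (!is.null(side) && nrow(ev)) ev <- ev[ev$side == side, ]
  if (!is.null(interface) && nrow(ev)) ev <- ev[ev$interface == interface, ]
  grid <- times %||% (if (inherits(x, "bd_trajectory")) x$series$time_ps else
    seq(0, max(ev$time_ps), length.out = 200))
  out <- tibble(time_ps = grid,
                N_L = vapply(grid, function(t) sum(ev$time_ps <= t), 1.0))
  if (inherits(x, "bd_trajectory") && identical(grid, x$series$time_ps))
    out$n_p <- x$series$n_p
  out
}

#' Straight-line fit of a cumulative transport curve
#'
#' Fits `N_L(t)` after a burn-in with a straight line: the slope is the
#' stationary transport rate `R_D` (ps^-1) and the x-axis intercept the
#' delay time `T_D` (ps) the particles need to cross the volume.
#'
#' @param log_df Tibble with `time_ps` and `N_L` (may be an average over
#'   runs).
#' @param burn_in Time (ps) to discard; default: everything before the
#'   first recorded absorption.
#' @return A `bd_fit_transport` with `R_D`, `R_D_se`, `T_D`.
#' @examples
#' transport_fit(tibble::tibble(time_ps = 0:100,
#'                              N_L = pmax(0, (0:100 - 5) * 2)))
#' @export
transport_fit <- function(log_df, burn_in = NULL) {
  log_df <- as_tibble(log_df)
  if (max(log_df$N_L) <= 0)
    abort("no absorbed particles; transport fit undefined",
          class = "brownsim_fit_error")
  burn_in <- burn_in %||% min(log_df$time_ps[log_df$N_L > 0])
  use <- log_df[log_df$time_ps >= burn_in, ]
  fit <- lm(N_L ~ time_ps, data = use)
  sm <- summary(fit)$coefficients
  a <- coef(fit)[1]; b <- coef(fit)[2]
  structure(list(R_D = unname(b), R_D_se = sm[2, 2], T_D = unname(-a / b),
                 burn_in = burn_in, fit = fit),
            class = "bd_fit_transport")
}

#' @export
print.bd_fit_transport <- function(x, ...) {
  cat(sprintf("<transport: R_D = %.4g ps^-1 (%.3g us^-1) +/- %.2g, T_D = %.4g ps>\n",
              x$R_D, x$R_D * 1e6, x$R_D_se, x$T_D))
  invisible(x)
}

#' @export
tidy.bd_fit_transport <- function(x, ...) {
  tibble(term = c("R_D", "T_D"), estimate = c(x$R_D, x$T_D),
         std.error = c(x$R_D_se, NA_real_))
}

#' @export
glance.bd_fit_transport <- function(x, ...) {
  tibble(R_D = x$R_D, R_D_se = x$R_D_se, T_D = x$T_D, burn_in = x$burn_in)
}
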