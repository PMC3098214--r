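# Boundary helpers mirrored at the R level: coordinate wrapping,
# minimum-image separations, specular reflection and the constant-density
# interface arithmetic. The engine applies the same rules in the hot loop.

#' Wrap coordinates into the primary periodic cell
#'
#' @param x An n x 3 matrix of positions (nm).
#' @param box A [simulation_box()]; only `"periodic"` axes are wrapped
#'   (into `[0, L)`).
#' @return Matrix of wrapped positions.
#' @export
wrap_coords <- function(x, box) {
  x <- rbind(x)[, 1:3, drop = FALSE]
  dimnames(x) <- NULL
  for (ax in 1:3) if (box$modes[ax] == "periodic") {
    L <- box$L[ax]
    x[, ax] <- x[, ax] - L * floor(x[, ax] / L)
  }
  x
}

#' Minimum-image separation vectors
#'
#' @param d An n x 3 matrix (or length-3 vector) of raw separation
#'   vectors.
#' @param box A [simulation_box()].
#' @return Separations folded into the nearest periodic image on periodic
#'   axes.
#' @export
minimum_image <- function(d, box) {
  d <- rbind(d)[, 1:3, drop = FALSE]
  dimnames(d) <- NULL
  for (ax in 1:3) if (box$modes[ax] == "periodic") {
    L <- box$L[ax]
    d[, ax] <- d[, ax] - L * round(d[, ax] / L)
  }
  d
}

#' Specular reflection at box walls
#'
#' Folds overshoots beyond reflecting walls back into the box: a particle
#' that ends up a distance delta beyond a wall is placed delta inside it.
#'
#' @param x An n x 3 matrix of positions.
#' @param box A [simulation_box()]; applies to `"reflecting"` axes.
#' @return Matrix of corrected positions.
#' @export
reflect_coords <- function(x, box) {
  x <- rbind(x)[, 1:3, drop = FALSE]
  dimnames(x) <- NULL
  for (ax in 1:3) if (box$modes[ax] == "reflecting") {
    L <- box$L[ax]
    p <- x[, ax] %% (2 * L)
    x[, ax] <- ifelse(p > L, 2 * L - p, p)
  }
  x
}

#' Mean insertions per step at a constant-density interface
#'
#' The one-sided thermal flux of an ideal reservoir at density `rho`
#' through a plane of area `A` over one Brownian step is
#' `nu = rho * A * sqrt(D dt / pi)`.
#'
#' @param rho Reservoir density, nm^-3.
#' @param A Interface area, nm^2.
#' @param D Species diffusion coefficient, nm^2/ps.
#' @param dt Timestep, ps.
#' @return Expected insertion count per step.
#' @examples
#' injection_rate(4e-4, 400, 1e-4, 10) # 2.854e-3
#' @export
injection_rate <- function(rho, A, D, dt) rho * A * sqrt(D * dt / pi)

#' Sample one-step crossing depths at an interface
#'
#' A particle starting at uniform depth x0 on the reservoir side and
#' making one Brownian step of standard deviation `sqrt(2 D dt)` that
#' crosses the plane ends up at depth `d = R - x0` with `R` drawn from the
#' length-biased (Rayleigh) step distribution and `x0` uniform on
#' `(0, R)`. This is the profile used by the engine when injecting.
#'
#' @param n Number of samples.
#' @param D Diffusion coefficient, nm^2/ps.
#' @param dt Timestep, ps.
#' @return Numeric vector of depths (nm).
#' @export
sample_crossing_depth <- function(n, D, dt) {
  s <- sqrt(2 * D * dt)
  r <- s * sqrt(-2 * log(runif(n)))
  r * runif(n)
}
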