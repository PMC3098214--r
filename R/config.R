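# Simulation box, boundary set and run configuration.

#' Simulation box
#'
#' @param L Edge lengths (nm), length 3 (recycled if scalar). Ignored on
#'   axes with mode `"none"`.
#' @param modes Per-axis boundary mode: `"none"` (infinite), `"periodic"`
#'   (minimum-image wrapping into `[0, L)`), `"reflecting"` (specular
#'   walls at 0 and L) or `"open"` (constant-density interfaces, see
#'   [density_interface()]).
#' @return A `simulation_box` object.
#' @examples
#' simulation_box(c(30, 20, 20), c("open", "periodic", "periodic"))
#' @export
simulation_box <- function(L = c(0, 0, 0), modes = "none") {
  L <- rep_len(as.numeric(L), 3)
  modes <- rep_len(modes, 3)
  ok <- c("none", "periodic", "reflecting", "open")
  if (!all(modes %in% ok))
    abort(sprintf("box modes must be one of %s", paste(ok, collapse = ", ")))
  if (any(modes != "none" & L <= 0))
    abort("box edge lengths must be > 0 on bounded axes")
  structure(list(L = L, modes = modes), class = "simulation_box")
}

#' Constant-density reservoir interface
#'
#' An open boundary plane: particles of the given species crossing it are
#' removed (and counted), while new ones are injected with the one-sided
#' thermal flux of an infinite reservoir at density `rho`, i.e. on average
#' `rho * A * sqrt(D dt / pi)` insertions per step with the one-step
#' crossing-depth profile. Species without an interface on a crossed plane
#' are reflected there.
#'
#' @param axis `"x"`, `"y"` or `"z"` (the axis must have box mode
#'   `"open"`).
#' @param side `"low"` (plane at 0, inflow towards +) or `"high"` (plane
#'   at L).
#' @param species Template name of the exchanged species (single-gestalt
#'   templates only).
#' @param rho Reservoir number density, nm^-3 (>= 0; 0 makes a purely
#'   absorbing interface).
#' @return A `density_interface` object.
#' @export
density_interface <- function(axis, side, species, rho) {
  axis <- match.arg(axis, c("x", "y", "z"))
  side <- match.arg(side, c("low", "high"))
  if (rho < 0) abort("interface density must be >= 0")
  structure(list(axis = axis, side = side, species = species, rho = rho),
            class = "density_interface")
}

#' Run configuration
#'
#' @param dt Timestep, ps (> 0).
#' @param steps Number of steps.
#' @param stride Output cadence: a frame is recorded every `stride` steps
#'   (plus the initial state).
#' @param kT Thermal energy, kDa nm^2 ps^-2.
#' @param hi Enable hydrodynamic interactions (TEA-approximated
#'   Rotne-Prager tensor over all gestalten carrying a hydro sphere)?
#' @param kappa Inverse Debye length, nm^-1 (0 = unscreened).
#' @param eps_r Relative solvent permittivity.
#' @param seed Integer RNG seed; the same seed and configuration give a
#'   bit-identical trajectory.
#' @param record `"full"` (per-gestalt positions and orientations),
#'   `"com_ee"` (per-protein center of mass and first-to-last-gestalt
#'   end-to-end vector; keeps output small) or `"none"`.
#' @param tensor_stride Recompute the TEA coefficients every this many
#'   steps (1 = every step; larger values are a documented approximation).
#' @param propagation `"auto"` selects Langevin stepping for gestalten
#'   with a defined mass and Brownian stepping otherwise; `"bd"` forces
#'   overdamped stepping for everything (a warning reminds of the
#'   dt >= 10 tau_rel validity bound where masses are known).
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(dt, steps, stride = 1L, kT = bd_units()$kT,
                              hi = FALSE, kappa = 0, eps_r = 80, seed = 1L,
                              record = c("full", "com_ee", "none"),
                              tensor_stride = 1L,
                              propagation = c("auto", "bd")) {
  record <- match.arg(record)
  propagation <- match.arg(propagation)
  if (dt <= 0) abort("dt must be > 0")
  if (steps < 0) abort("steps must be >= 0")
  if (stride < 1) abort("stride must be >= 1")
  if (kT <= 0) abort("kT must be > 0")
  structure(list(dt = dt, steps = as.numeric(steps), stride = as.integer(stride),
                 kT = kT, hi = isTRUE(hi), kappa = kappa, eps_r = eps_r,
                 seed = as.integer(seed), record = record,
                 tensor_stride = as.integer(tensor_stride),
                 propagation = propagation),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("<simulation_config: dt=%g ps, %g steps, stride %d, HI %s, seed %d>\n",
              x$dt, x$steps, x$stride, if (x$hi) "on" else "off", x$seed))
  invisible(x)
}
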