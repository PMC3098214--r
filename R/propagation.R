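# Time stepping: the simulate() front end over the engine, plus the
# elementary per-step operations exposed for direct use.

#' Raw Gaussian random displacement
#'
#' Zero-mean displacements with per-component variance `2 D dt` — the
#' statistical moments of free Brownian motion over one step (before any
#' hydrodynamic correlation).
#'
#' @param D Self-diffusion coefficient, nm^2/ps.
#' @param dt Timestep, ps.
#' @param n Number of draws.
#' @return n x 3 matrix, nm.
#' @export
random_displacement <- function(D, dt, n = 1) {
  if (D < 0) abort("D must be >= 0")
  matrix(rnorm(3 * n, sd = sqrt(2 * D * dt)), n, 3)
}

#' Friction coefficient from the Einstein relation
#' @param D Self-diffusion coefficient, nm^2/ps.
#' @param kT Thermal energy, kDa nm^2 ps^-2.
#' @return gamma = kT / D in kDa/ps.
#' @examples
#' friction_coefficient(1.2e-4) # ~20.3 kDa/ps
#' @export
friction_coefficient <- function(D, kT = bd_units()$kT) kT / D

#' Convert a random displacement into an equivalent force
#'
#' The effective force `f = gamma R / dt` whose BD propagation over one
#' step reproduces the displacement `R` exactly. Returned in the
#' package's kT-based force unit, `f_kT = R / (D dt)` (kT/nm).
#'
#' @param R Displacement(s), nm (vector or n x 3 matrix).
#' @param D Self-diffusion coefficient, nm^2/ps.
#' @param dt Timestep, ps.
#' @return Effective force(s), kT/nm, same shape as `R`.
#' @export
displacement_to_force <- function(R, D, dt) R / (D * dt)

#' One overdamped Brownian step
#'
#' `x' = x + D F dt + R`: the displacement from the deterministic force
#' grows linearly with the timestep; `R` is the (possibly
#' hydrodynamically correlated) random displacement.
#'
#' @param x Position, nm.
#' @param F Total deterministic force, kT/nm.
#' @param D Self-diffusion coefficient, nm^2/ps.
#' @param dt Timestep, ps.
#' @param R Random displacement, nm.
#' @return New position.
#' @export
bd_step <- function(x, F, D, dt, R = 0) x + D * F * dt + R

#' One finitely damped Langevin step
#'
#' Integrates the Langevin equation analytically under a force held
#' constant over the step:
#' `v(dt) = v0 e^(-dt/tau) + (F/gamma)(1 - e^(-dt/tau))` and
#' `dx = (F/gamma) dt + tau (v0 - F/gamma)(1 - e^(-dt/tau))` with
#' `tau = m D / kT`. The random displacement `R` enters as its effective
#' force `gamma R / dt`. For `dt >> tau` the exponentials vanish and the
#' update reduces to the Brownian step.
#'
#' @param x Position, nm.
#' @param v Velocity carried from the previous step, nm/ps.
#' @param F Deterministic force, kT/nm.
#' @param D Self-diffusion coefficient, nm^2/ps.
#' @param mass Mass, kDa.
#' @param dt Timestep, ps.
#' @param R Random displacement, nm.
#' @param kT Thermal energy.
#' @return List with `x` and `v`.
#' @export
ld_step <- function(x, v, F, D, mass, dt, R = 0, kT = bd_units()$kT) {
  tau <- mass * D / kT
  e <- exp(-dt / tau)
  fg <- D * F + R / dt            # F_total / gamma, nm/ps
  list(x = x + fg * dt + tau * (v - fg) * (1 - e),
       v = v * e + fg * (1 - e))
}

#' One rotational diffusion step
#'
#' Applies the world-frame rotation vector
#' `w = D_rot T dt + N(0, 2 D_rot dt)` (per axis) as a quaternion
#' composition and renormalises. Valid for `D_rot dt << 1` (small-angle
#' update, asserted at configuration time).
#'
#' @param q Orientation quaternion `c(w, x, y, z)`.
#' @param torque World-frame torque, kT.
#' @param D_rot Rotational diffusion coefficient, ps^-1.
#' @param dt Timestep, ps.
#' @return New unit quaternion.
#' @export
rotation_step <- function(q, torque = c(0, 0, 0), D_rot = 0, dt = 1) {
  if (D_rot == 0 && all(torque == 0)) return(q)
  w <- D_rot * vec3(torque, "torque") * dt +
    rnorm(3, sd = sqrt(2 * D_rot * dt))
  th <- sqrt(sum(w^2))
  dq <- if (th < 1e-14) c(1, w / 2) else c(cos(th / 2), sin(th / 2) * w / th)
  out <- quat_multiply(dq, q)
  out / sqrt(sum(out^2))
}

#' Run a simulation
#'
#' Propagates the system for `config$steps` steps. Each step: zero the
#' accumulators; evaluate all pair, bond and external forces; if
#' hydrodynamics is on, apply the TEA coupling to the deterministic
#' forces and correlate the raw random displacements; advance every
#' gestalt with its scheme (Langevin when a mass is defined, Brownian
#' otherwise — both may coexist) plus rotational diffusion; apply
#' boundaries and constant-density interfaces; record frames at the
#' output stride.
#'
#' @param system A `bd_system`.
#' @param config A [simulation_config()].
#' @return A `bd_trajectory`: list with tibbles `frames` (unwrapped
#'   coordinates and orientations, or per-protein center-of-mass +
#'   end-to-end reduction), `series` (time, particle count, potential
#'   energy), `events` (interface absorb/inject log) and bookkeeping
#'   (`counters`, `config`, `final_state`).
#' @examples
#' sys <- new_system(simulation_box(), colour_pair(1, 1, 1, 0.4)) |>
#'   instantiate(build_polymer(3), c(0, 0, 0))
#' trj <- simulate(sys, simulation_config(dt = 5e-4, steps = 100, stride = 10,
#'                                        seed = 7))
#' trj$frames
#' @export
simulate <- function(system, config) {
  stopifnot(inherits(system, "bd_system"), inherits(config, "simulation_config"))
  validate_system(system, config)
  set.seed(config$seed)
  out <- cpp_run(compile_system(system, config), engine_config(config))
  frames <- as_tibble(out$frames)
  if (config$record == "com_ee")
    names(frames) <- c("frame", "time_ps", "protein", "species", "n_gestalts",
                       "x", "y", "z", "ex", "ey", "ez")
  if (nrow(frames) && "species" %in% names(frames))
    frames$species <- names(system$templates)[frames$species + 1]
  if ("gestalt" %in% names(frames)) frames$gestalt <- frames$gestalt + 1
  events <- as_tibble(out$events)
  if (nrow(events)) {
    meta <- purrr::map_dfr(system$interfaces, function(f)
      tibble(axis = f$axis, side = f$side, species = f$species))
    events <- dplyr::mutate(events,
                            type = ifelse(.data$type == 0, "absorb", "inject"),
                            axis = meta$axis[.data$interface],
                            side = meta$side[.data$interface])
  }
  structure(list(
    frames = frames,
    series = as_tibble(out$series),
    events = events,
    counters = out$counters,
    tea = out$tea,
    config = config,
    box = system$box,
    final_state = out$state
  ), class = "bd_trajectory")
}

#' @export
print.bd_trajectory <- function(x, ...) {
  cat(sprintf("<bd_trajectory: %d frames (%s), %g ps simulated, %d interface events>\n",
              length(unique(x$frames$frame)), x$config$record,
              max(x$series$time_ps), nrow(x$events)))
  invisible(x)
}

#' @export
as_tibble.bd_trajectory <- function(x, ...) x$frames
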