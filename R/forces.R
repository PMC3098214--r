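# Single-pair force/energy evaluations (R-facing wrappers over the engine
# kernels) and the full accumulator.

#' Screened Coulomb interaction of two buried point charges
#'
#' U = C_e q_i q_k exp(-kappa (r - B)) / (eps_r r) with B = b_i + b_k the
#' summed burial depths (the interaction is unscreened over the stretch
#' buried inside the particles, where no counter ions screen) and C_e the
#' Coulomb constant at the configured thermal energy.
#'
#' @param r_i,r_k World positions of the two charges (nm).
#' @param q_i,q_k Charges, e.
#' @param b_i,b_k Burial depths, nm.
#' @param kappa Inverse Debye length, nm^-1.
#' @param eps_r Relative permittivity.
#' @param kT Thermal energy (sets the Coulomb constant).
#' @return List with `energy` (kT) and `force` (kT/nm, acting on charge
#'   i; the force on k is its negative).
#' @examples
#' lB <- coulomb_constant() / 80
#' electrostatic_pair(c(0, 0, 0), c(lB, 0, 0), 1, 1)$energy # 1 kT
#' @export
electrostatic_pair <- function(r_i, r_k, q_i, q_k, b_i = 0, b_k = 0,
                               kappa = 0, eps_r = 80, kT = bd_units()$kT) {
  d <- vec3(r_i, "r_i") - vec3(r_k, "r_k")
  if (sqrt(sum(d^2)) < 1e-12)
    abort("singular configuration: charges coincide",
          class = "brownsim_singular")
  res <- cpp_pair_es(d, q_i, q_k, b_i, b_k, kappa, eps_r, coulomb_constant(kT))
  list(energy = res$energy, force = as.numeric(res$force))
}

#' Short-range van-der-Waals interaction of two coloured spheres
#'
#' Lennard-Jones 12-6 in the surface-surface distance
#' `s = |r| - a_i - a_k`, minimum `-epsilon` at `s = sigma`;
#' repulsive-only parameter sets keep the s^-12 branch. Below the
#' linearisation threshold the force is constant and the energy continues
#' linearly; beyond the cutoff both are zero.
#'
#' @param r_i,r_k World sphere centers (nm).
#' @param a_i,a_k Sphere radii (nm).
#' @param params A one-row [colour_pair()] tibble (or list with fields
#'   `epsilon`, `sigma`, `attractive`, `cutoff`, `r_lin`).
#' @return List with `energy` (kT) and `force` on sphere i (kT/nm).
#' @export
vdw_pair <- function(r_i, r_k, a_i, a_k, params) {
  d <- vec3(r_i, "r_i") - vec3(r_k, "r_k")
  res <- cpp_pair_vdw(d, a_i, a_k, params$epsilon, params$sigma, params$cutoff,
                      isTRUE(params$attractive) || isTRUE(params$attractive == 1),
                      params$r_lin)
  list(energy = res$energy, force = as.numeric(res$force))
}

#' Bond forces and torques between two gestalten
#'
#' U = k2/2 (d - L0)^2 + k4/4 (d - L0)^4 in the hook-hook distance d; the
#' force acts at the hook points, so eccentric hooks generate torques
#' `offset x F` about the gestalt origins. At d = 0 with L0 > 0 the force
#' direction is undefined and resolved along +x (documented tie-break).
#'
#' @param bd A [bond()] (hook offsets in the gestalt frames).
#' @param pos_a,pos_b Gestalt origins (nm).
#' @param quat_a,quat_b Gestalt orientations (unit quaternions).
#' @return List with `energy`, `force_a`, `torque_a`, `force_b`,
#'   `torque_b` (kT units).
#' @examples
#' b <- bond(1, 2, k2 = 1000, L0 = 2.5)
#' bond_forces(b, c(0, 0, 0), c(2.6, 0, 0))$force_a # 100 kT/nm along +x
#' @export
bond_forces <- function(bd, pos_a, pos_b, quat_a = c(1, 0, 0, 0),
                        quat_b = c(1, 0, 0, 0)) {
  pa <- vec3(pos_a, "pos_a") + quat_rotate(quat_a, bd$hook_a)
  pb <- vec3(pos_b, "pos_b") + quat_rotate(quat_b, bd$hook_b)
  d <- pa - pb
  r <- sqrt(sum(d^2))
  u <- if (r < 1e-12) c(1, 0, 0) else d / r
  dl <- r - bd$L0
  fmag <- bd$k2 * dl + bd$k4 * dl^3
  fa <- -fmag * u
  list(energy = 0.5 * bd$k2 * dl^2 + 0.25 * bd$k4 * dl^4,
       force_a = fa,
       torque_a = cross3(pa - vec3(pos_a, "pos_a"), fa),
       force_b = -fa,
       torque_b = cross3(pb - vec3(pos_b, "pos_b"), -fa))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' External restraint force on a gestalt
#'
#' @param restraint A [restraint_harmonic()] or [restraint_constant()].
#' @param pos Gestalt origin, nm.
#' @return Force vector, kT/nm.
#' @export
external_force <- function(restraint, pos) {
  if (restraint$type == "harmonic") -restraint$k * (vec3(pos, "pos") - restraint$x0)
  else restraint$F
}

#' Evaluate all forces of a system once
#'
#' Loops every mobile-mobile gestalt pair once and every mobile-fixed
#' pair (fixed-fixed pairs are never evaluated), so the pair count is
#' `N_p (N_p - 1) / 2 + N_p N_o`. Newton's third law holds pairwise for
#' the mobile-mobile interactions; periodic axes use minimum-image
#' separations.
#'
#' @param system A `bd_system`.
#' @param config A [simulation_config()] (provides kappa, eps_r, kT).
#' @return List with `forces` (tibble: gestalt, Fx..Fz, Tx..Tz, all kT
#'   units), `energy` (kT) and `n_int` (pair-interaction count).
#' @export
accumulate_forces <- function(system, config) {
  validate_system(system, config)
  res <- cpp_forces(compile_system(system, config), engine_config(config))
  list(forces = tibble(gestalt = seq_len(nrow(system$state)),
                       Fx = res$force[, 1], Fy = res$force[, 2], Fz = res$force[, 3],
                       Tx = res$torque[, 1], Ty = res$torque[, 2], Tz = res$torque[, 3]),
       energy = res$energy, n_int = res$n_int)
}

engine_config <- function(config, record_code = NULL) {
  rc <- record_code %||% match(config$record, c("none", "full", "com_ee")) - 1L
  list(dt = config$dt, kT = config$kT, kappa = config$kappa,
       eps_r = config$eps_r, coulomb = coulomb_constant(config$kT),
       steps = config$steps, stride = config$stride, record = rc,
       tensor_stride = config$tensor_stride, hi = config$hi)
}
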