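# Unit system: length nm, time ps, mass kDa, charge e.
# 1 kDa nm^2 ps^-2 = 1.66053906660e-18 J.

#' Physical constants of the simulation unit system
#'
#' The package works in nm / ps / kDa / e units. Thermal energy is an
#' explicit scalar of every [simulation_config()]; its default corresponds
#' to k_B * 293 K expressed in kDa nm^2 ps^-2, which reproduces the
#' velocity relaxation times tau_rel = m D / kT of typical coarse-grained
#' protein models (e.g. 0.99 ps for a 20 kDa bead with
#' D = 1.2e-4 nm^2/ps).
#'
#' @return A named list with elements `kT` (default thermal energy,
#'   kDa nm^2 ps^-2), `joule_per_unit` (J per kDa nm^2 ps^-2) and
#'   `temperature_K` (the temperature the default corresponds to).
#' @examples
#' bd_units()$kT
#' @export
bd_units <- function() {
  list(kT = 2.4361e-3, joule_per_unit = 1.66053906660e-18, temperature_K = 293)
}

#' Coulomb constant in kT-based units
#'
#' Returns e^2 / (4 pi eps_0 kT) in units of kT * nm, i.e. the vacuum
#' Bjerrum length at the given thermal energy. Dividing by a relative
#' permittivity gives the solvent Bjerrum length; two unit charges in
#' water (eps_r = 80) then have interaction energy 1 kT at ~0.71 nm.
#'
#' @param kT Thermal energy in kDa nm^2 ps^-2.
#' @return Scalar, kT * nm.
#' @examples
#' coulomb_constant() / 80 # Bjerrum length of water, nm
#' @export
coulomb_constant <- function(kT = bd_units()$kT) {
  e <- 1.602176634e-19          # C
  eps0 <- 8.8541878128e-12      # F/m
  kT_J <- kT * bd_units()$joule_per_unit
  # e^2/(4 pi eps0) in J*m -> J*nm -> kT*nm
  e^2 / (4 * pi * eps0) * 1e9 / kT_J
}

#' Rotational diffusion coefficient of a sphere from its translational one
#'
#' For a sphere of radius `a`, Stokes friction gives
#' D_rot = 3 D_tr / (4 a^2); a 2 nm sphere with D_tr = 1.2e-4 nm^2/ps has
#' D_rot = 2.25e-5 ps^-1.
#'
#' @param D_tr Translational diffusion coefficient, nm^2/ps.
#' @param a Sphere radius, nm.
#' @return D_rot in ps^-1.
#' @export
sphere_D_rot <- function(D_tr, a) 3 * D_tr / (4 * a^2)

#' Velocity relaxation time of a Langevin particle
#'
#' tau_rel = m / gamma = m D / kT is the time over which the velocity of a
#' finitely damped particle decorrelates; Brownian (overdamped) propagation
#' is conceptually valid only for timesteps well above it (roughly
#' dt >= 10 tau_rel).
#'
#' @param mass Particle mass, kDa.
#' @param D_tr Translational self-diffusion coefficient, nm^2/ps.
#' @param kT Thermal energy, kDa nm^2 ps^-2.
#' @return tau_rel in ps.
#' @examples
#' velocity_relaxation_time(20, 1.2e-4) # ~0.99 ps
#' @export
velocity_relaxation_time <- function(mass, D_tr, kT = bd_units()$kT) {
  mass * D_tr / kT
}
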