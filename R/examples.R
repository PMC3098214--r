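# Ready-made setups of the four reference studies: polymer diffusion
# scaling, HCP multi-bead elastic proteins, obstacle-array transport, and
# patchy-particle agglomeration.

#' Bead-spring polymer study system
#'
#' An unbounded system holding one constrained polymer: beads of radius
#' and diffusion coefficient 1 (reduced units), nearest-neighbour springs
#' k_N = 1000 of length 2.5 (so neighbouring beads do not overlap),
#' angle-confining next-neighbour springs of length 5 with stiffness
#' `k_2N`, and a short-range repulsion between all bead pairs as
#' exclusion volume. The reference timestep is 5e-4.
#'
#' @param N Bead count.
#' @param k_2N Next-neighbour spring constant (0.1 = soft ... 1000 =
#'   stiff).
#' @param with_HI Attach hydrodynamic spheres?
#' @return A `bd_system` with the polymer instantiated at the origin.
#' @examples
#' sys <- example_polymer_system(5, k_2N = 0.1)
#' @export
example_polymer_system <- function(N, k_2N = 0.1, with_HI = FALSE) {
  tpl <- build_polymer(N, k_N = 1000, k_2N = k_2N, L_N = 2.5, L_2N = 5,
                       bead_radius = 1, D_bead = 1, with_HI = with_HI)
  new_system(simulation_box(),
             colour_pair(1, 1, epsilon = 1, sigma = 0.4, cutoff = 1.2,
                         r_lin = 0.3)) |>
    instantiate(tpl)
}

#' Stable Brownian timestep for a spring network
#'
#' The BD update of a harmonic network mode with Laplacian eigenvalue
#' lambda multiplies it by `1 - D k lambda dt` per step; stability needs
#' `D k lambda dt < 2` with `lambda <= 4` for a chain (and up to twice
#' the coordination number in general). This helper returns a timestep
#' with a 5x safety margin on the chain bound,
#' `dt = 0.2 / (D (k_N + k_2N))`.
#'
#' @param k_N,k_2N Spring constants, kT/nm^2.
#' @param D Bead diffusion coefficient, nm^2/ps.
#' @return Timestep, ps.
#' @export
polymer_timestep <- function(k_N = 1000, k_2N = 0.1, D = 1) {
  0.2 / (D * (k_N + k_2N))
}


#' HCP multi-bead elastic protein study system
#'
#' One quasi-spherical particle of `N` beads (radius 2 nm, single-bead
#' D_bead = 1.2e-4 nm^2/ps) on a hexagonal close packing grid with 5 nm
#' springs to the up to twelve direct neighbours, plus a short-range bead
#' repulsion.
#'
#' @param N Bead count (4, 13, 39 or 57 are complete shells).
#' @param with_HI Attach hydrodynamic spheres?
#' @param D_bead Single-bead diffusion coefficient (rescaled in the
#'   matched no-HI runs).
#' @param k Spring constant, kT/nm^2.
#' @return A `bd_system`.
#' @export
example_hcp_system <- function(N, with_HI = TRUE, D_bead = 1.2e-4, k = 50) {
  tpl <- build_hcp_particle(N, bead_radius = 2, spacing = 5, k = k,
                            D_bead = D_bead, with_HI = with_HI)
  new_system(simulation_box(),
             colour_pair(1, 1, epsilon = 1, sigma = 0.8, cutoff = 2.4,
                         r_lin = 0.6)) |>
    instantiate(tpl)
}

#' Obstacle-array transport study system
#'
#' The open-box non-equilibrium setup: a box of length `L_x` = 30 nm and
#' 2D-periodic cross-section bounded by two constant-density interfaces —
#' inflow reservoir at `rho_0` on the low-x side, absorbing (rho = 0) on
#' the high-x side — with 2 nm mobile spheres (D = 1e-4 nm^2/ps) and
#' optionally one or two 3 x 3 layers of fixed spherical obstacles.
#' Obstacle-particle contacts are purely repulsive or carry a short-range
#' attraction.
#'
#' @param layers Obstacle layer positions along x (nm), or `NULL` for the
#'   control geometry without obstacles.
#' @param A_o Obstacle radius, nm.
#' @param attractive Attractive obstacle-particle interaction?
#' @param rho_0 Reservoir density, nm^-3.
#' @param L_x,L_yz Box length and cross-section edge, nm.
#' @param epsilon_attr Attraction well depth, kT.
#' @return A `bd_system` (initially empty of mobile particles; the
#'   interfaces fill it).
#' @examples
#' sys <- example_transport_system() # control, no obstacles
#' @export
example_transport_system <- function(layers = NULL, A_o = 5, attractive = FALSE,
                                     rho_0 = 4e-4, L_x = 30, L_yz = 20,
                                     epsilon_attr = 1) {
  bead <- build_simple_bead(radius = 2, D = 1e-4, colour = 1L)
  cp <- dplyr::bind_rows(
    colour_pair(1, 1, epsilon = 1, sigma = 0.8, cutoff = 2.4, r_lin = 0.6),
    if (attractive)
      colour_pair(1, 3, epsilon = epsilon_attr, sigma = 1, attractive = TRUE,
                  cutoff = 3, r_lin = 0.8)
    else
      colour_pair(1, 3, epsilon = 1, sigma = 0.8, cutoff = 2.4, r_lin = 0.6))
  sys <- new_system(simulation_box(c(L_x, L_yz, L_yz),
                                   c("open", "periodic", "periodic")), cp)
  if (!is.null(layers))
    sys <- add_wall(sys, build_obstacle_wall(3, 3, L_yz, L_yz, A_o = A_o,
                                             layer_x = L_x / 2 + layers))
  sys |>
    add_interface(density_interface("x", "low", "bead", rho_0), bead) |>
    add_interface(density_interface("x", "high", "bead", 0), bead)
}

#' Patchy-particle agglomeration study system
#'
#' 27 two-sphere patchy particles (1.7 nm spheres displaced +/- 0.5 nm,
#' patch-patch attraction slightly below kT, all other contacts
#' repulsive) in a 30 nm cubic 3D-periodic box, with the diffusion
#' coefficients of an equivalent 2 nm sphere and a mass of 18 kDa
#' (Langevin propagation).
#'
#' @param n_particles Number of particles.
#' @param L Box edge, nm.
#' @param epsilon_patch Patch-patch well depth, kT.
#' @param seed Seed for the random initial placement.
#' @return A `bd_system`.
#' @export
example_agglomeration_system <- function(n_particles = 27, L = 30,
                                         epsilon_patch = 0.9, seed = 1) {
  tpl <- build_patchy_particle(sphere_radius = 1.7, displacement = 0.5,
                               D_tr = 1.2e-4, D_rot = 2.26e-5, mass = 18)
  cp <- dplyr::bind_rows(
    colour_pair(1, 1, epsilon = 1, sigma = 0.68, cutoff = 2.04, r_lin = 0.6),
    colour_pair(1, 2, epsilon = 1, sigma = 0.68, cutoff = 2.04, r_lin = 0.6),
    colour_pair(2, 2, epsilon = epsilon_patch, sigma = 0.4, attractive = TRUE,
                cutoff = 1.2, r_lin = 0.35))
  set.seed(seed)
  new_system(simulation_box(L, "periodic"), cp) |>
    instantiate_random(tpl, n_particles, min_dist = 4.5)
}

#' Measure the diffusion scaling of a polymer or HCP series
#'
#' Runs the given systems over several seeds, extracts the long-time
#' center-of-mass diffusion coefficient of each, and fits the scaling
#' exponent of D vs N.
#'
#' @param sizes Bead numbers.
#' @param system_fn Function `(N) -> bd_system`.
#' @param config A [simulation_config()] (its `record` is forced to
#'   `"com_ee"`).
#' @param seeds Seeds to average over.
#' @param lags Integer frame lags for the CoM MSD fit. The center of mass
#'   of an isolated particle is diffusive at every lag (its internal
#'   modes cancel there), so short lags give the best-conditioned
#'   estimate; default 1:5.
#' @param burn_in_frames Frames dropped before the MSD (conformational
#'   equilibration, e.g. for soft polymers started from a straight
#'   line).
#' @return List with `measurements` (tibble: N, seed, D, se), `by_size`
#'   (mean D per N) and `scaling` (a `bd_fit_scaling`).
#' @export
diffusion_scaling_study <- function(sizes, system_fn, config, seeds = 1:3,
                                    lags = 1:5, burn_in_frames = 0) {
  meas <- purrr::map_dfr(sizes, function(N) {
    sys <- system_fn(N)
    purrr::map_dfr(seeds, function(s) {
      cfg <- config
      cfg$seed <- as.integer(s)
      cfg$record <- "com_ee"
      trj <- simulate(sys, cfg)
      fr <- trj$frames[trj$frames$frame >= burn_in_frames, ]
      m <- msd_curve(fr, "com", lags = lags)
      fit <- fit_long_time_D(m, window = range(m$lag_ps))
      tibble(N = N, seed = s, D = fit$D, se = fit$se)
    })
  })
  by_size <- meas |>
    dplyr::group_by(.data$N) |>
    dplyr::summarise(se = sd(.data$D) / sqrt(dplyr::n()),
                     D = mean(.data$D), .groups = "drop") |>
    dplyr::select("N", "D", "se")
  list(measurements = meas, by_size = by_size,
       scaling = if (nrow(by_size) >= 3) scaling_exponent(by_size$N, by_size$D))
}
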