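# Deterministic builders for the four reference systems: constrained
# bead-spring polymers, HCP multi-bead elastic particles, fixed obstacle
# arrays, and two-sphere patchy particles.

#' Constrained bead-spring polymer
#'
#' `N` spherical beads on a line, connected by nearest-neighbour springs
#' (`k_N`, rest length `L_N`) and by angle-confining next-neighbour springs
#' (`k_2N`, rest length `L_2N`). All springs hook at the bead centers; the
#' beads carry a repulsive van-der-Waals sphere as exclusion volume, do not
#' rotate (D_rot = 0), and optionally carry a hydrodynamic sphere.
#'
#' For N >= 3 the bond count is 2N - 3 (N - 1 nearest plus N - 2 next
#' neighbours).
#'
#' @param N Bead count (>= 2).
#' @param k_N Nearest-neighbour spring constant, kT/nm^2.
#' @param k_2N Next-neighbour (stiffness) spring constant, kT/nm^2.
#' @param L_N Nearest-neighbour rest length, nm.
#' @param L_2N Next-neighbour rest length, nm.
#' @param bead_radius Bead radius, nm.
#' @param D_bead Bead self-diffusion coefficient, nm^2/ps.
#' @param with_HI Add a hydrodynamic sphere (radius `bead_radius`,
#'   D_self `D_bead`) to every bead?
#' @param colour Colour index of the repulsive bead spheres.
#' @param name Template name.
#' @return A [protein_template()].
#' @examples
#' build_polymer(5, with_HI = TRUE)
#' @export
build_polymer <- function(N, k_N = 1000, k_2N = 0.1, L_N = 2.5, L_2N = 5,
                          bead_radius = 1, D_bead = 1, with_HI = FALSE,
                          colour = 1L, name = sprintf("polymer%d", N)) {
  if (N < 2) abort("invalid template: a polymer needs N >= 2 beads",
                   class = "brownsim_invalid_template")
  stopifnot(k_N > 0, L_N > 0, L_2N > 0, bead_radius > 0, D_bead > 0)
  gl <- lapply(seq_len(N), function(i) {
    gestalt_template(
      geom = geom_spec(D_tr = D_bead, D_rot = 0),
      vdw = list(vdw_sphere(radius = bead_radius, colour = colour)),
      hydro = if (with_HI) hydro_sphere(a = bead_radius, D_self = D_bead),
      origin = c((i - 1) * L_N, 0, 0))
  })
  bonds <- c(
    lapply(seq_len(N - 1), function(i) bond(i, i + 1, k2 = k_N, L0 = L_N)),
    if (N >= 3 && k_2N > 0)
      lapply(seq_len(N - 2), function(i) bond(i, i + 2, k2 = k_2N, L0 = L_2N))
  )
  protein_template(name, gl, bonds)
}

#' Sites of an ideal hexagonal close packing lattice
#'
#' @param spacing Nearest-neighbour distance, nm.
#' @param extent Integer half-width of the generated index range.
#' @return Tibble with columns `i`, `j`, `k` (lattice indices) and
#'   `x`, `y`, `z` (nm).
#' @export
hcp_sites <- function(spacing = 5, extent = 4) {
  idx <- expand.grid(i = -extent:extent, j = -extent:extent, k = -extent:extent)
  tibble(
    i = idx$i, j = idx$j, k = idx$k,
    x = spacing * (2 * idx$i + (idx$j + idx$k) %% 2) / 2,
    y = spacing * sqrt(3) / 2 * (idx$j + (idx$k %% 2) / 3),
    z = spacing * sqrt(6) / 3 * idx$k)
}

#' Elastic multi-bead particle on a hexagonal close packing grid
#'
#' `N` beads are placed on HCP sites and connected to their (up to twelve)
#' direct lattice neighbours by harmonic springs with rest length equal to
#' the lattice spacing. The canonical sizes 13, 39 and 57 are complete
#' neighbour shells around a central site; `N = 4` is the tetrahedral cell.
#' Other `N` keep the sites closest to the cluster center (ties broken by
#' lexicographic site index).
#'
#' @param N Bead count.
#' @param bead_radius Bead radius, nm.
#' @param spacing Lattice spacing = spring rest length, nm (> 0).
#' @param k Spring constant, kT/nm^2.
#' @param D_bead Bead self-diffusion coefficient, nm^2/ps.
#' @param with_HI Attach hydrodynamic spheres to the beads?
#' @param colour Colour of the repulsive bead spheres.
#' @param name Template name.
#' @return A [protein_template()].
#' @examples
#' build_hcp_particle(13)
#' @export
build_hcp_particle <- function(N, bead_radius = 2, spacing = 5, k = 50,
                               D_bead = 1.2e-4, with_HI = FALSE, colour = 1L,
                               name = sprintf("hcp%d", N)) {
  if (spacing <= 0) abort("invalid template: lattice spacing must be > 0",
                          class = "brownsim_invalid_template")
  if (N < 1) abort("invalid template: N must be >= 1",
                   class = "brownsim_invalid_template")
  sites <- hcp_sites(spacing, extent = max(4, ceiling(N^(1 / 3)) + 2))
  center <- if (N == 4) {
    # centroid of a tetrahedral cell: a site, two in-plane neighbours and
    # the nestled site of the next layer
    tet <- sites[(sites$i == 0 & sites$j == 0 & sites$k %in% c(0, 1)) |
                   (sites$i == 1 & sites$j == 0 & sites$k == 0) |
                   (sites$i == 0 & sites$j == 1 & sites$k == 0), ]
    c(mean(tet$x), mean(tet$y), mean(tet$z))
  } else c(0, 0, 0)
  d2 <- (sites$x - center[1])^2 + (sites$y - center[2])^2 + (sites$z - center[3])^2
  ord <- order(round(d2, 9), sites$i, sites$j, sites$k)
  keep <- sites[ord[seq_len(N)], ]
  pos <- cbind(keep$x - mean(keep$x), keep$y - mean(keep$y), keep$z - mean(keep$z))

  gl <- lapply(seq_len(N), function(i) {
    gestalt_template(
      geom = geom_spec(D_tr = D_bead, D_rot = 0),
      vdw = list(vdw_sphere(radius = bead_radius, colour = colour)),
      hydro = if (with_HI) hydro_sphere(a = bead_radius, D_self = D_bead),
      origin = pos[i, ])
  })
  bonds <- list()
  if (N >= 2) {
    for (a in seq_len(N - 1)) for (b in (a + 1):N) {
      d <- sqrt(sum((pos[a, ] - pos[b, ])^2))
      if (abs(d - spacing) < 1e-6 * spacing)
        bonds[[length(bonds) + 1]] <- bond(a, b, k2 = k, L0 = spacing)
    }
  }
  protein_template(name, gl, bonds)
}

#' Patchy particle: two displaced van-der-Waals spheres
#'
#' One rigid gestalt carrying two spheres displaced by `displacement`
#' along the gestalt z axis: a "patch" sphere (at +z) and a "body" sphere
#' (at -z) with distinct colours, so that patch-patch contacts can be made
#' attractive while all other combinations stay repulsive.
#'
#' @param sphere_radius Radius of both spheres, nm.
#' @param displacement Center offset along z, nm (< `sphere_radius`).
#' @param D_tr,D_rot Translational/rotational diffusion coefficients.
#' @param mass Mass in kDa (enables Langevin propagation); `NULL` for BD.
#' @param patch_colour,body_colour Colour indices of the two spheres.
#' @param name Template name.
#' @return A [protein_template()].
#' @examples
#' build_patchy_particle()
#' @export
build_patchy_particle <- function(sphere_radius = 1.7, displacement = 0.5,
                                  D_tr = 1.2e-4, D_rot = 2.26e-5, mass = 18,
                                  patch_colour = 2L, body_colour = 1L,
                                  name = "patchy") {
  if (displacement >= sphere_radius)
    abort("displacement must be smaller than the sphere radius",
          class = "brownsim_invalid_template")
  g <- gestalt_template(
    geom = geom_spec(D_tr = D_tr, D_rot = D_rot, mass = mass),
    vdw = list(
      vdw_sphere(offset = c(0, 0, +displacement), radius = sphere_radius,
                 colour = patch_colour),
      vdw_sphere(offset = c(0, 0, -displacement), radius = sphere_radius,
                 colour = body_colour)))
  protein_template(name, list(g))
}

#' Fixed obstacle array wall
#'
#' A rectangular `rows` x `cols` grid of fixed spheres in the (periodic)
#' y-z cross-section, repeated at each x in `layer_x`. Grid points sit at
#' cell centers so the array tiles periodically.
#'
#' @param rows,cols Grid dimensions.
#' @param L_y,L_z Box cross-section, nm.
#' @param A_o Obstacle radius, nm (> 0).
#' @param layer_x Non-empty vector of layer x positions, nm.
#' @param colour Obstacle colour index.
#' @return A [wall_gestalt()].
#' @examples
#' build_obstacle_wall(A_o = 5, layer_x = c(-10, 10), L_y = 20, L_z = 20)
#' @export
build_obstacle_wall <- function(rows = 3, cols = 3, L_y = 20, L_z = 20, A_o = 5,
                                layer_x = 0, colour = 3L) {
  if (!length(layer_x)) abort("layer_x must be non-empty")
  if (A_o <= 0) abort("obstacle radius must be > 0")
  grid <- expand.grid(x = layer_x,
                      y = (seq_len(rows) - 0.5) * L_y / rows,
                      z = (seq_len(cols) - 0.5) * L_z / cols)
  wall_gestalt(data.frame(x = grid$x, y = grid$y, z = grid$z,
                          radius = A_o, colour = as.integer(colour)),
               name = sprintf("obstacles_%dx%dx%d", rows, cols, length(layer_x)))
}

#' Minimal spherical transport particle
#'
#' A single uncharged van-der-Waals sphere, the mobile species of the
#' obstacle-transport setup.
#'
#' @param radius Sphere radius, nm.
#' @param D Diffusion coefficient, nm^2/ps.
#' @param colour Colour index.
#' @param name Template name.
#' @return A [protein_template()].
#' @export
build_simple_bead <- function(radius = 2, D = 1e-4, colour = 1L,
                              name = "bead") {
  g <- gestalt_template(
    geom = geom_spec(D_tr = D, D_rot = 0),
    vdw = list(vdw_sphere(radius = radius, colour = colour)))
  protein_template(name, list(g))
}
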