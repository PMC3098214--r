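# Hierarchical particle model: a protein template owns independently moving
# gestalt units; each gestalt carries interaction shapes (van-der-Waals
# spheres, point charges, at most one hydrodynamic sphere) plus the always
# present geometry spec that converts forces into displacements.

vec3 <- function(x, what = "vector") {
  x <- as.numeric(x)
  if (length(x) != 3 || any(!is.finite(x)))
    abort(sprintf("%s must be 3 finite numbers", what))
  x
}

#' Van-der-Waals interaction sphere
#'
#' A sphere with a `colour` index; the colour pair of two spheres selects
#' the short-range interaction parameter set (see [colour_pair()]).
#'
#' @param offset Position in the gestalt frame (nm, length 3).
#' @param radius Sphere radius in nm, > 0.
#' @param colour Integer colour index (>= 1).
#' @return A `vdw_sphere` object.
#' @export
vdw_sphere <- function(offset = c(0, 0, 0), radius, colour = 1L) {
  if (!is.numeric(radius) || radius <= 0) abort("vdW sphere radius must be > 0")
  structure(list(offset = vec3(offset, "vdW offset"), radius = radius,
                 colour = as.integer(colour)), class = "vdw_sphere")
}

#' Buried point charge
#'
#' @param offset Position in the gestalt frame (nm).
#' @param q Charge in units of e.
#' @param b Burial depth in nm (>= 0): the stretch of the interaction
#'   distance exempt from Debye screening because it runs through the
#'   (counter-ion free) particle interior.
#' @return A `point_charge` object.
#' @export
point_charge <- function(offset = c(0, 0, 0), q, b = 0) {
  if (b < 0) abort("burial depth must be >= 0")
  structure(list(offset = vec3(offset, "charge offset"), q = as.numeric(q),
                 b = as.numeric(b)), class = "point_charge")
}

#' Hydrodynamic sphere
#'
#' At most one per gestalt, fixed at the gestalt origin; enters the
#' Rotne-Prager-Yamakawa diffusion tensor.
#'
#' @param a Hydrodynamic radius, nm (> 0).
#' @param D_self Self-diffusion coefficient, nm^2/ps (> 0).
#' @return A `hydro_sphere` object.
#' @export
hydro_sphere <- function(a, D_self) {
  if (a <= 0 || D_self <= 0) abort("hydro sphere needs a > 0 and D_self > 0")
  structure(list(a = a, D_self = D_self), class = "hydro_sphere")
}

#' Geometry spec of a gestalt
#'
#' Always present; holds the transport coefficients that convert forces
#' into displacements. A defined `mass` selects the finitely damped
#' Langevin propagation for the gestalt, otherwise overdamped Brownian
#' stepping is used.
#'
#' @param D_tr Translational diffusion coefficient, nm^2/ps (> 0).
#' @param D_rot Rotational diffusion coefficient, ps^-1 (>= 0; 0 freezes
#'   orientation).
#' @param mass Optional mass in kDa; `NULL` means massless (BD).
#' @return A `geom_spec` object.
#' @export
geom_spec <- function(D_tr, D_rot = 0, mass = NULL) {
  if (D_tr <= 0) abort("D_tr must be > 0")
  if (D_rot < 0) abort("D_rot must be >= 0")
  if (!is.null(mass) && (!is.numeric(mass) || mass <= 0))
    abort("mass must be NULL or > 0")
  structure(list(D_tr = D_tr, D_rot = D_rot, mass = mass), class = "geom_spec")
}

#' Harmonic position restraint
#' @param k Spring constant, kT/nm^2.
#' @param x0 Anchor point (world frame), nm.
#' @return A `restraint` object.
#' @export
restraint_harmonic <- function(k, x0 = c(0, 0, 0)) {
  structure(list(type = "harmonic", k = k, x0 = vec3(x0, "restraint anchor")),
            class = "restraint")
}

#' Constant external force
#' @param F Force vector, kT/nm.
#' @return A `restraint` object.
#' @export
restraint_constant <- function(F) {
  structure(list(type = "constant", F = vec3(F, "constant force")),
            class = "restraint")
}

#' Gestalt template
#'
#' @param geom A [geom_spec()].
#' @param vdw List of [vdw_sphere()]s.
#' @param charges List of [point_charge()]s.
#' @param hydro Optional [hydro_sphere()].
#' @param restraints List of restraints ([restraint_harmonic()],
#'   [restraint_constant()]).
#' @param origin Position of the gestalt in the protein (template) frame,
#'   nm; used when the template is instantiated.
#' @return A `gestalt_template` object.
#' @export
gestalt_template <- function(geom, vdw = list(), charges = list(),
                             hydro = NULL, restraints = list(),
                             origin = c(0, 0, 0)) {
  stopifnot(inherits(geom, "geom_spec"))
  if (length(vdw) && !all(vapply(vdw, inherits, TRUE, "vdw_sphere")))
    abort("vdw must be a list of vdw_sphere objects")
  if (length(charges) && !all(vapply(charges, inherits, TRUE, "point_charge")))
    abort("charges must be a list of point_charge objects")
  if (!is.null(hydro) && !inherits(hydro, "hydro_sphere"))
    abort("hydro must be NULL or a hydro_sphere")
  structure(list(geom = geom, vdw = vdw, charges = charges, hydro = hydro,
                 restraints = restraints, origin = vec3(origin, "gestalt origin")),
            class = "gestalt_template")
}

#' Bond between two gestalten of the same protein
#'
#' The potential is U = k2/2 (d - L0)^2 + k4/4 (d - L0)^4 in the
#' hook-to-hook distance d. Hooks may be attached eccentrically: a force on
#' an off-center hook exerts a torque about the gestalt origin.
#'
#' @param a,b 1-based gestalt indices within the protein; must differ.
#' @param k2 Harmonic constant, kT/nm^2 (>= 0).
#' @param k4 Quartic constant, kT/nm^4 (>= 0); `k2` and `k4` must not both
#'   be zero.
#' @param L0 Rest length, nm.
#' @param hook_a,hook_b Attachment offsets in the two gestalt frames, nm.
#' @return A `bond` object.
#' @export
bond <- function(a, b, k2, L0, k4 = 0, hook_a = c(0, 0, 0), hook_b = c(0, 0, 0)) {
  if (a == b) abort("a bond must connect two distinct gestalten")
  if (k2 < 0 || k4 < 0 || (k2 == 0 && k4 == 0))
    abort("bond constants must be >= 0 and not both zero")
  structure(list(a = as.integer(a), b = as.integer(b), k2 = k2, k4 = k4,
                 L0 = L0, hook_a = vec3(hook_a, "hook_a"),
                 hook_b = vec3(hook_b, "hook_b")), class = "bond")
}

#' Protein template
#'
#' The insertable/removable unit of a simulation: one or more gestalten
#' plus the bonds between them. Instantiating a template copies it; the
#' instances never alias template storage.
#'
#' @param name Template (species) name.
#' @param gestalts List of [gestalt_template()]s.
#' @param bonds List of [bond()]s with indices into `gestalts`.
#' @return A `protein_template` object.
#' @export
protein_template <- function(name, gestalts, bonds = list()) {
  if (!length(gestalts) || !all(vapply(gestalts, inherits, TRUE, "gestalt_template")))
    abort("invalid template: need at least one gestalt_template", class = "brownsim_invalid_template")
  ng <- length(gestalts)
  for (bd in bonds) {
    if (!inherits(bd, "bond")) abort("bonds must be bond objects")
    if (bd$a < 1 || bd$a > ng || bd$b < 1 || bd$b > ng)
      abort("invalid template: bond index out of range", class = "brownsim_invalid_template")
  }
  structure(list(name = name, gestalts = gestalts, bonds = bonds),
            class = "protein_template")
}

#' @export
print.protein_template <- function(x, ...) {
  nv <- sum(vapply(x$gestalts, function(g) length(g$vdw), 1L))
  nc <- sum(vapply(x$gestalts, function(g) length(g$charges), 1L))
  nh <- sum(vapply(x$gestalts, function(g) !is.null(g$hydro), TRUE))
  cat(sprintf("<protein_template '%s': %d gestalten, %d bonds, %d vdW spheres, %d charges, %d hydro spheres>\n",
              x$name, length(x$gestalts), length(x$bonds), nv, nc, nh))
  invisible(x)
}

#' Fixed wall built from a rigid gestalt
#'
#' Fixed structures (obstacle arrays, membrane patches) interact with the
#' mobile particles but never move; pair interactions among fixed objects
#' are never evaluated, so the per-step pair count is
#' N_p (N_p - 1) / 2 + N_p N_o.
#'
#' @param spheres A data frame with columns `x`, `y`, `z`, `radius`,
#'   `colour` (absolute coordinates, nm).
#' @param charges Optional data frame with columns `x`, `y`, `z`, `q`, `b`.
#' @param name Wall name.
#' @return A `wall_template` object.
#' @export
wall_gestalt <- function(spheres, charges = NULL, name = "wall") {
  spheres <- as.data.frame(spheres)
  need <- c("x", "y", "z", "radius", "colour")
  if (!all(need %in% names(spheres)))
    abort("wall spheres need columns x, y, z, radius, colour")
  if (is.null(charges)) charges <- data.frame(x = numeric(0), y = numeric(0),
                                              z = numeric(0), q = numeric(0),
                                              b = numeric(0))
  structure(list(name = name, spheres = spheres, charges = as.data.frame(charges)),
            class = "wall_template")
}

#' @export
print.wall_template <- function(x, ...) {
  cat(sprintf("<wall_template '%s': %d fixed vdW spheres, %d fixed charges>\n",
              x$name, nrow(x$spheres), nrow(x$charges)))
  invisible(x)
}

#' Short-range interaction parameters for one colour pair
#'
#' Van-der-Waals spheres interact through a Lennard-Jones 12-6 potential in
#' their surface-surface distance s, reparameterised so the minimum of
#' depth `-epsilon` sits at s = `sigma`. Repulsive pairs keep only the
#' s^-12 branch. Below the linearisation threshold `r_lin` the force is
#' held constant (energy continued linearly) for numerical stability.
#'
#' @param a,b Colour indices (order irrelevant).
#' @param epsilon Well depth / strength, kT (>= 0).
#' @param sigma Range, nm.
#' @param attractive Logical; `FALSE` keeps only the repulsive branch.
#' @param cutoff Interaction cutoff in surface distance, nm; default
#'   `3 * sigma`.
#' @param r_lin Linearisation threshold in surface distance, nm; default
#'   `sigma / 2`.
#' @return A one-row tibble describing the pair.
#' @export
colour_pair <- function(a, b, epsilon, sigma, attractive = FALSE,
                        cutoff = 3 * sigma, r_lin = sigma / 2) {
  if (epsilon < 0) abort("epsilon must be >= 0")
  tibble(colour_a = as.integer(min(a, b)), colour_b = as.integer(max(a, b)),
         epsilon = epsilon, sigma = sigma, attractive = attractive,
         cutoff = cutoff, r_lin = r_lin)
}

# Internal: colour table tibble -> symmetric matrices for the engine.
compile_colours <- function(pairs, n_colours) {
  mk <- function(fill) matrix(fill, n_colours, n_colours)
  out <- list(eps = mk(0), sigma = mk(1), cutoff = mk(0), rlin = mk(0),
              attractive = mk(0L), defined = mk(0L))
  if (!is.null(pairs) && nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      p <- pairs[i, ]
      for (idx in list(c(p$colour_a, p$colour_b), c(p$colour_b, p$colour_a))) {
        out$eps[idx[1], idx[2]] <- p$epsilon
        out$sigma[idx[1], idx[2]] <- p$sigma
        out$cutoff[idx[1], idx[2]] <- p$cutoff
        out$rlin[idx[1], idx[2]] <- p$r_lin
        out$attractive[idx[1], idx[2]] <- as.integer(p$attractive)
        out$defined[idx[1], idx[2]] <- 1L
      }
    }
  }
  out
}
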