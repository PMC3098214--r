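# System state assembly: templates are instantiated into flat shape tables
# which the engine consumes directly.

quat_identity <- function() c(1, 0, 0, 0)

#' Quaternion from axis and angle
#' @param axis Rotation axis (length 3, need not be normalised).
#' @param angle Rotation angle, rad.
#' @return Unit quaternion `c(w, x, y, z)`.
#' @export
quat_axis_angle <- function(axis, angle) {
  axis <- vec3(axis, "axis")
  n <- sqrt(sum(axis^2))
  if (n < 1e-14) return(quat_identity())
  c(cos(angle / 2), sin(angle / 2) * axis / n)
}

#' Rotate vectors by a quaternion
#' @param q Unit quaternion `c(w, x, y, z)`.
#' @param v A length-3 vector or an n x 3 matrix.
#' @return Rotated vector(s), same shape as `v`.
#' @export
quat_rotate <- function(q, v) {
  R <- quat_to_matrix(q)
  if (is.matrix(v)) t(R %*% t(v)) else as.numeric(R %*% v)
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Create an empty simulation system
#'
#' @param box A [simulation_box()].
#' @param colour_pairs Tibble of [colour_pair()] rows (bind with
#'   `dplyr::bind_rows()`).
#' @return A `bd_system` object to which templates are added with
#'   [instantiate()], walls with [add_wall()] and open boundaries with
#'   [add_interface()].
#' @examples
#' new_system(simulation_box(), colour_pair(1, 1, epsilon = 1, sigma = 0.4))
#' @export
new_system <- function(box = simulation_box(), colour_pairs = NULL) {
  structure(list(
    box = box,
    colour_pairs = colour_pairs,
    templates = list(),
    state = tibble(protein = integer(), species = character(),
                   x = numeric(), y = numeric(), z = numeric(),
                   qw = numeric(), qx = numeric(), qy = numeric(), qz = numeric(),
                   vx = numeric(), vy = numeric(), vz = numeric(),
                   D_tr = numeric(), D_rot = numeric(), mass = numeric()),
    vdw = tibble(gestalt = integer(), ox = numeric(), oy = numeric(),
                 oz = numeric(), radius = numeric(), colour = integer()),
    charges = tibble(gestalt = integer(), ox = numeric(), oy = numeric(),
                     oz = numeric(), q = numeric(), b = numeric()),
    hydro = tibble(gestalt = integer(), a = numeric(), D = numeric()),
    restraints = tibble(gestalt = integer(), type = integer(), k = numeric(),
                        x0x = numeric(), x0y = numeric(), x0z = numeric(),
                        Fx = numeric(), Fy = numeric(), Fz = numeric()),
    bonds = tibble(a = integer(), b = integer(),
                   oax = numeric(), oay = numeric(), oaz = numeric(),
                   obx = numeric(), oby = numeric(), obz = numeric(),
                   k2 = numeric(), k4 = numeric(), L0 = numeric()),
    wall_spheres = tibble(x = numeric(), y = numeric(), z = numeric(),
                          radius = numeric(), colour = integer()),
    wall_charges = tibble(x = numeric(), y = numeric(), z = numeric(),
                          q = numeric(), b = numeric()),
    interfaces = list(),
    next_protein = 1L
  ), class = "bd_system")
}

#' @export
print.bd_system <- function(x, ...) {
  cat(sprintf("<bd_system: %d gestalten in %d proteins, %d bonds, %d wall spheres, %d interfaces>\n",
              nrow(x$state), length(unique(x$state$protein)), nrow(x$bonds),
              nrow(x$wall_spheres), length(x$interfaces)))
  invisible(x)
}

#' Number of mobile gestalten
#' @param system A `bd_system`.
#' @return Integer count.
#' @export
n_gestalts <- function(system) nrow(system$state)

#' Insert a protein template into the system
#'
#' Appends an independent copy of the template (instances never alias
#' template storage) at the given position and orientation and returns the
#' grown system. Insertions whose van-der-Waals spheres overlap a fixed
#' obstacle beyond the colour pair's linearisation threshold are rejected
#' with a condition of class `brownsim_rejected_insertion` so the caller
#' can retry elsewhere.
#'
#' @param system A `bd_system`.
#' @param template A [protein_template()].
#' @param position World position of the template origin, nm.
#' @param orientation Unit quaternion `c(w, x, y, z)`.
#' @return The updated `bd_system`.
#' @export
instantiate <- function(system, template, position = c(0, 0, 0),
                        orientation = c(1, 0, 0, 0)) {
  stopifnot(inherits(system, "bd_system"), inherits(template, "protein_template"))
  position <- vec3(position, "position")
  qn <- sqrt(sum(orientation^2))
  if (abs(qn - 1) > 1e-9) abort("orientation must be a unit quaternion")
  if (is.null(system$templates[[template$name]]))
    system$templates[[template$name]] <- template

  ng0 <- nrow(system$state)
  pid <- system$next_protein
  ng <- length(template$gestalts)

  # world placement + wall-overlap check before mutating anything
  new_vdw <- list(); new_state <- list()
  for (gi in seq_len(ng)) {
    g <- template$gestalts[[gi]]
    gpos <- position + quat_rotate(orientation, g$origin)
    new_state[[gi]] <- list(pos = gpos, g = g)
    for (s in g$vdw) {
      sp <- gpos + quat_rotate(orientation, s$offset)
      new_vdw[[length(new_vdw) + 1]] <- list(pos = sp, radius = s$radius,
                                             colour = s$colour)
    }
  }
  if (nrow(system$wall_spheres)) {
    ct <- system$colour_pairs
    for (s in new_vdw) {
      dx <- minimum_image(cbind(s$pos[1] - system$wall_spheres$x,
                                s$pos[2] - system$wall_spheres$y,
                                s$pos[3] - system$wall_spheres$z), system$box)
      d <- sqrt(rowSums(dx^2)) - s$radius - system$wall_spheres$radius
      rlin <- vapply(system$wall_spheres$colour, function(cw) {
        row <- ct[(ct$colour_a == min(s$colour, cw) & ct$colour_b == max(s$colour, cw)), ]
        if (nrow(row)) row$r_lin[1] else 0
      }, 1.0)
      if (any(d < rlin))
        abort("insertion overlaps a fixed obstacle",
              class = "brownsim_rejected_insertion")
    }
  }

  for (gi in seq_len(ng)) {
    g <- new_state[[gi]]$g
    gpos <- new_state[[gi]]$pos
    gid <- ng0 + gi
    system$state <- dplyr::bind_rows(system$state, tibble(
      protein = pid, species = template$name,
      x = gpos[1], y = gpos[2], z = gpos[3],
      qw = orientation[1], qx = orientation[2], qy = orientation[3],
      qz = orientation[4],
      vx = 0, vy = 0, vz = 0,
      D_tr = g$geom$D_tr, D_rot = g$geom$D_rot,
      mass = g$geom$mass %||% NA_real_))
    for (s in g$vdw)
      system$vdw <- dplyr::bind_rows(system$vdw, tibble(
        gestalt = gid, ox = s$offset[1], oy = s$offset[2], oz = s$offset[3],
        radius = s$radius, colour = s$colour))
    for (ch in g$charges)
      system$charges <- dplyr::bind_rows(system$charges, tibble(
        gestalt = gid, ox = ch$offset[1], oy = ch$offset[2], oz = ch$offset[3],
        q = ch$q, b = ch$b))
    if (!is.null(g$hydro))
      system$hydro <- dplyr::bind_rows(system$hydro, tibble(
        gestalt = gid, a = g$hydro$a, D = g$hydro$D_self))
    for (r in g$restraints)
      system$restraints <- dplyr::bind_rows(system$restraints, tibble(
        gestalt = gid, type = if (r$type == "harmonic") 0L else 1L,
        k = r$k %||% 0,
        x0x = (r$x0 %||% c(0, 0, 0))[1], x0y = (r$x0 %||% c(0, 0, 0))[2],
        x0z = (r$x0 %||% c(0, 0, 0))[3],
        Fx = (r$F %||% c(0, 0, 0))[1], Fy = (r$F %||% c(0, 0, 0))[2],
        Fz = (r$F %||% c(0, 0, 0))[3]))
  }
  for (bd in template$bonds)
    system$bonds <- dplyr::bind_rows(system$bonds, tibble(
      a = ng0 + bd$a, b = ng0 + bd$b,
      oax = bd$hook_a[1], oay = bd$hook_a[2], oaz = bd$hook_a[3],
      obx = bd$hook_b[1], oby = bd$hook_b[2], obz = bd$hook_b[3],
      k2 = bd$k2, k4 = bd$k4, L0 = bd$L0))
  system$next_protein <- pid + 1L
  system
}

#' Insert multiple copies at random non-overlapping positions
#'
#' Draws uniform positions (and, for templates with rotational freedom,
#' uniform random orientations) inside the box, retrying rejected
#' insertions. Uses the current RNG state.
#'
#' @param system A `bd_system` with a bounded box.
#' @param template A [protein_template()].
#' @param n Number of copies.
#' @param min_dist Minimal center-center distance to already placed
#'   proteins, nm.
#' @param max_tries Retry budget per copy.
#' @return The updated system.
#' @export
instantiate_random <- function(system, template, n, min_dist = 0,
                               max_tries = 1000) {
  L <- system$box$L
  if (any(L <= 0)) abort("instantiate_random needs a bounded box")
  rot <- any(vapply(template$gestalts, function(g) g$geom$D_rot > 0, TRUE))
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      pos <- runif(3) * L
      if (min_dist > 0 && nrow(system$state)) {
        d <- minimum_image(cbind(pos[1] - system$state$x, pos[2] - system$state$y,
                                 pos[3] - system$state$z), system$box)
        if (min(sqrt(rowSums(d^2))) < min_dist) next
      }
      q <- if (rot) random_quaternion() else quat_identity()
      ok <- tryCatch({
        system <- instantiate(system, template, pos, q); TRUE
      }, brownsim_rejected_insertion = function(e) FALSE)
      if (ok) { placed <- TRUE; break }
    }
    if (!placed) abort(sprintf("could not place copy %d of '%s' in %d tries",
                               i, template$name, max_tries))
  }
  system
}

random_quaternion <- function() {
  # uniform over SO(3) (Shoemake)
  u <- runif(3)
  c(sqrt(u[1]) * cos(2 * pi * u[3]),
    sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]))
}

#' Add a fixed wall to the system
#' @param system A `bd_system`.
#' @param wall A [wall_gestalt()] / [build_obstacle_wall()].
#' @return The updated system.
#' @export
add_wall <- function(system, wall) {
  stopifnot(inherits(system, "bd_system"), inherits(wall, "wall_template"))
  system$wall_spheres <- dplyr::bind_rows(system$wall_spheres,
                                          as_tibble(wall$spheres))
  if (nrow(wall$charges))
    system$wall_charges <- dplyr::bind_rows(system$wall_charges,
                                            as_tibble(wall$charges))
  system
}

#' Attach a constant-density interface
#'
#' @param system A `bd_system` whose box is `"open"` on the interface
#'   axis.
#' @param interface A [density_interface()].
#' @param template The [protein_template()] of the exchanged species
#'   (single gestalt), registered if new.
#' @return The updated system.
#' @export
add_interface <- function(system, interface, template) {
  stopifnot(inherits(interface, "density_interface"),
            inherits(template, "protein_template"))
  ax <- match(interface$axis, c("x", "y", "z"))
  if (system$box$modes[ax] != "open")
    abort(sprintf("axis %s must have box mode 'open' for an interface",
                  interface$axis))
  if (length(template$gestalts) != 1)
    abort("only single-gestalt species can be exchanged at an interface")
  if (template$name != interface$species)
    abort("interface species does not match the template name")
  if (is.null(system$templates[[template$name]]))
    system$templates[[template$name]] <- template
  system$interfaces[[length(system$interfaces) + 1]] <- interface
  system
}

# ---- engine compilation -----------------------------------------------------

compile_template_single <- function(template) {
  g <- template$gestalts[[1]]
  nv <- length(g$vdw)
  voff <- matrix(0, nv, 3); vr <- numeric(nv); vc <- integer(nv)
  for (i in seq_len(nv)) {
    voff[i, ] <- g$vdw[[i]]$offset
    vr[i] <- g$vdw[[i]]$radius
    vc[i] <- g$vdw[[i]]$colour - 1L
  }
  list(Dtr = g$geom$D_tr, Drot = g$geom$D_rot, mass = g$geom$mass %||% NA_real_,
       vdw_off = voff, vdw_r = vr, vdw_col = vc,
       has_hydro = !is.null(g$hydro),
       hy_a = if (!is.null(g$hydro)) g$hydro$a else 0,
       hy_D = if (!is.null(g$hydro)) g$hydro$D_self else 0)
}

compile_system <- function(system, config) {
  st <- system$state
  n <- nrow(st)
  species_names <- names(system$templates)
  mode_code <- c(none = 0L, periodic = 1L, reflecting = 2L, open = 3L)
  n_colours <- max(c(system$vdw$colour, system$wall_spheres$colour,
                     system$colour_pairs$colour_b, 1L))
  mass <- st$mass
  if (!is.null(config) && config$propagation == "bd") {
    tau <- mass * st$D_tr / config$kT
    if (any(!is.na(tau) & config$dt < 10 * tau))
      warn("forcing BD for gestalten with dt < 10 * tau_rel; the overdamped approximation is not valid at this timestep")
    mass <- rep(NA_real_, n)
  }
  list(
    pos = cbind(st$x, st$y, st$z),
    quat = cbind(st$qw, st$qx, st$qy, st$qz),
    vel = cbind(st$vx, st$vy, st$vz),
    Dtr = st$D_tr, Drot = st$D_rot, mass = mass,
    species = match(st$species, species_names) - 1L,
    protein = st$protein,
    vdw_g = system$vdw$gestalt - 1L,
    vdw_off = cbind(system$vdw$ox, system$vdw$oy, system$vdw$oz),
    vdw_r = system$vdw$radius, vdw_col = system$vdw$colour - 1L,
    ch_g = system$charges$gestalt - 1L,
    ch_off = cbind(system$charges$ox, system$charges$oy, system$charges$oz),
    ch_q = system$charges$q, ch_b = system$charges$b,
    hy_g = system$hydro$gestalt - 1L,
    hy_a = system$hydro$a, hy_D = system$hydro$D,
    re_g = system$restraints$gestalt - 1L, re_type = system$restraints$type,
    re_k = system$restraints$k,
    re_x0 = cbind(system$restraints$x0x, system$restraints$x0y, system$restraints$x0z),
    re_F = cbind(system$restraints$Fx, system$restraints$Fy, system$restraints$Fz),
    bond_a = system$bonds$a - 1L, bond_b = system$bonds$b - 1L,
    bond_oa = cbind(system$bonds$oax, system$bonds$oay, system$bonds$oaz),
    bond_ob = cbind(system$bonds$obx, system$bonds$oby, system$bonds$obz),
    bond_k2 = system$bonds$k2, bond_k4 = system$bonds$k4, bond_L0 = system$bonds$L0,
    w_pos = cbind(system$wall_spheres$x, system$wall_spheres$y, system$wall_spheres$z),
    w_r = system$wall_spheres$radius, w_col = system$wall_spheres$colour - 1L,
    wc_pos = cbind(system$wall_charges$x, system$wall_charges$y, system$wall_charges$z),
    wc_q = system$wall_charges$q, wc_b = system$wall_charges$b,
    box_L = system$box$L,
    box_mode = unname(mode_code[system$box$modes]),
    colours = compile_colours(system$colour_pairs, n_colours),
    interfaces = lapply(system$interfaces, function(f) {
      list(axis = match(f$axis, c("x", "y", "z")) - 1L,
           side = if (f$side == "low") 0L else 1L,
           rho = f$rho,
           species = match(f$species, species_names) - 1L,
           template = compile_template_single(system$templates[[f$species]]))
    })
  )
}

# All colour pairs occurring in the system must have parameters.
validate_system <- function(system, config) {
  cols <- sort(unique(c(system$vdw$colour, system$wall_spheres$colour)))
  cp <- system$colour_pairs
  mob <- sort(unique(system$vdw$colour))
  for (a in mob) for (b in cols[cols >= a]) {
    hit <- !is.null(cp) && any(cp$colour_a == min(a, b) & cp$colour_b == max(a, b))
    if (!hit)
      abort(sprintf("no colour_pair parameters for colour pair (%d, %d)", a, b),
            class = "brownsim_config_error")
  }
  if (any(system$state$D_rot * config$dt > 0.1))
    abort("D_rot * dt > 0.1: the small-angle random-rotation update is not valid; reduce dt",
          class = "brownsim_config_error")
  # periodic minimum image needs cutoffs below half the smallest periodic edge
  per <- which(system$box$modes == "periodic")
  if (length(per) && !is.null(cp) && nrow(cp)) {
    rmax <- if (nrow(system$vdw)) max(system$vdw$radius) else 0
    wmax <- if (nrow(system$wall_spheres)) max(system$wall_spheres$radius) else 0
    reach <- max(cp$cutoff) + rmax + max(rmax, wmax)
    if (reach > min(system$box$L[per]) / 2)
      abort("interaction cutoff exceeds half the smallest periodic edge",
            class = "brownsim_config_error")
  }
  invisible(TRUE)
}
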