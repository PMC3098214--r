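# Configuration documents (YAML, unit-suffixed keys), trajectory writers
# and the run manifest.

SCHEMA_VERSION <- "brownsim/1"

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    abort(sprintf("unknown key%s %s in %s", if (length(bad) > 1) "s" else "",
                  paste0("'", bad, "'", collapse = ", "), where),
          class = "brownsim_config_error")
}

template_to_doc <- function(tpl) {
  list(name = tpl$name,
       gestalts = lapply(tpl$gestalts, function(g) list(
         geom = list(D_tr_nm2_ps = g$geom$D_tr, D_rot_per_ps = g$geom$D_rot,
                     mass_kDa = g$geom$mass),
         origin_nm = as.list(g$origin),
         vdw = lapply(g$vdw, function(s) list(
           offset_nm = as.list(s$offset), radius_nm = s$radius,
           colour = s$colour)),
         charges = lapply(g$charges, function(ch) list(
           offset_nm = as.list(ch$offset), q_e = ch$q, burial_nm = ch$b)),
         hydro = if (!is.null(g$hydro)) list(a_nm = g$hydro$a,
                                             D_self_nm2_ps = g$hydro$D_self))),
       bonds = lapply(tpl$bonds, function(b) list(
         a = b$a, b = b$b, k2_kT_nm2 = b$k2, k4_kT_nm4 = b$k4, L0_nm = b$L0,
         hook_a_nm = as.list(b$hook_a), hook_b_nm = as.list(b$hook_b))))
}

template_from_doc <- function(doc, where) {
  check_keys(doc, c("name", "gestalts", "bonds"), where)
  gl <- lapply(seq_along(doc$gestalts), function(i) {
    g <- doc$gestalts[[i]]
    here <- sprintf("%s.gestalts[%d]", where, i)
    check_keys(g, c("geom", "origin_nm", "vdw", "charges", "hydro"), here)
    check_keys(g$geom, c("D_tr_nm2_ps", "D_rot_per_ps", "mass_kDa"),
               paste0(here, ".geom"))
    gestalt_template(
      geom = geom_spec(g$geom$D_tr_nm2_ps, g$geom$D_rot_per_ps %||% 0,
                       g$geom$mass_kDa),
      vdw = lapply(g$vdw, function(s)
        vdw_sphere(unlist(s$offset_nm), s$radius_nm, s$colour)),
      charges = lapply(g$charges, function(ch)
        point_charge(unlist(ch$offset_nm), ch$q_e, ch$burial_nm %||% 0)),
      hydro = if (!is.null(g$hydro))
        hydro_sphere(g$hydro$a_nm, g$hydro$D_self_nm2_ps),
      origin = unlist(g$origin_nm %||% list(0, 0, 0)))
  })
  bonds <- lapply(doc$bonds, function(b)
    bond(b$a, b$b, k2 = b$k2_kT_nm2, L0 = b$L0_nm, k4 = b$k4_kT_nm4 %||% 0,
         hook_a = unlist(b$hook_a_nm %||% list(0, 0, 0)),
         hook_b = unlist(b$hook_b_nm %||% list(0, 0, 0))))
  protein_template(doc$name, gl, bonds)
}

#' Write a simulation setup document
#'
#' Serialises a system + configuration into the package's YAML schema
#' (`brownsim/1`), with explicit units in the key names. The document
#' round-trips: loading and re-dumping reproduces it.
#'
#' @param system A `bd_system`.
#' @param config A [simulation_config()].
#' @param path Output file.
#' @param species Optional named integer vector: initial random copy
#'   counts per template recorded in the document.
#' @return `path`, invisibly.
#' @export
write_config <- function(system, config, path, species = NULL) {
  doc <- list(
    schema = SCHEMA_VERSION,
    box = list(L_nm = as.list(system$box$L), modes = as.list(system$box$modes)),
    config = list(timestep_ps = config$dt, steps = config$steps,
                  stride = config$stride, kT = config$kT, hi = config$hi,
                  kappa_per_nm = config$kappa, eps_r = config$eps_r,
                  seed = config$seed, record = config$record,
                  tensor_stride = config$tensor_stride,
                  propagation = config$propagation),
    colour_pairs = if (!is.null(system$colour_pairs))
      lapply(seq_len(nrow(system$colour_pairs)), function(i) {
        p <- system$colour_pairs[i, ]
        list(colour_a = p$colour_a, colour_b = p$colour_b,
             epsilon_kT = p$epsilon, sigma_nm = p$sigma,
             attractive = p$attractive, cutoff_nm = p$cutoff,
             r_lin_nm = p$r_lin)
      }) else list(),
    templates = lapply(unname(system$templates), template_to_doc),
    species = if (!is.null(species))
      lapply(names(species), function(nm) list(template = nm,
                                               count = unname(species[[nm]])))
      else list(),
    walls = if (nrow(system$wall_spheres))
      list(list(spheres = lapply(seq_len(nrow(system$wall_spheres)), function(i) {
        s <- system$wall_spheres[i, ]
        list(x_nm = s$x, y_nm = s$y, z_nm = s$z, radius_nm = s$radius,
             colour = s$colour)
      }))) else list(),
    interfaces = lapply(system$interfaces, function(f)
      list(axis = f$axis, side = f$side, species = f$species,
           rho_per_nm3 = f$rho))
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Load a simulation setup document
#'
#' Parses and fully validates a `brownsim/1` YAML document: unknown keys
#' are rejected with the offending location, cross references (template
#' names, colour pairs) are resolved, and cutoff-vs-box constraints are
#' checked at run time.
#'
#' @param path Document path.
#' @return List with `system` (a `bd_system`; recorded species counts not
#'   yet placed), `config` (a [simulation_config()]), `templates` (named
#'   list) and `species` (named counts to place, see
#'   [instantiate_random()]).
#' @export
load_config <- function(path) {
  doc <- yaml::read_yaml(path)
  check_keys(doc, c("schema", "box", "config", "colour_pairs", "templates",
                    "species", "walls", "interfaces"), "document root")
  if (!identical(doc$schema, SCHEMA_VERSION))
    abort(sprintf("unsupported schema '%s' (this build reads %s)",
                  doc$schema %||% "<missing>", SCHEMA_VERSION),
          class = "brownsim_config_error")
  cfgd <- doc$config
  check_keys(cfgd, c("timestep_ps", "steps", "stride", "kT", "hi",
                     "kappa_per_nm", "eps_r", "seed", "record",
                     "tensor_stride", "propagation"), "config")
  config <- simulation_config(
    dt = cfgd$timestep_ps, steps = cfgd$steps, stride = cfgd$stride %||% 1L,
    kT = cfgd$kT %||% bd_units()$kT, hi = isTRUE(cfgd$hi),
    kappa = cfgd$kappa_per_nm %||% 0, eps_r = cfgd$eps_r %||% 80,
    seed = cfgd$seed %||% 1L, record = cfgd$record %||% "full",
    tensor_stride = cfgd$tensor_stride %||% 1L,
    propagation = cfgd$propagation %||% "auto")
  cp <- NULL
  for (i in seq_along(doc$colour_pairs)) {
    p <- doc$colour_pairs[[i]]
    check_keys(p, c("colour_a", "colour_b", "epsilon_kT", "sigma_nm",
                    "attractive", "cutoff_nm", "r_lin_nm"),
               sprintf("colour_pairs[%d]", i))
    cp <- dplyr::bind_rows(cp, colour_pair(
      p$colour_a, p$colour_b, p$epsilon_kT, p$sigma_nm,
      attractive = isTRUE(p$attractive),
      cutoff = p$cutoff_nm %||% (3 * p$sigma_nm),
      r_lin = p$r_lin_nm %||% (p$sigma_nm / 2)))
  }
  box <- simulation_box(unlist(doc$box$L_nm), unlist(doc$box$modes))
  sys <- new_system(box, cp)
  templates <- list()
  for (i in seq_along(doc$templates)) {
    tpl <- template_from_doc(doc$templates[[i]], sprintf("templates[%d]", i))
    templates[[tpl$name]] <- tpl
    sys$templates[[tpl$name]] <- tpl
  }
  for (i in seq_along(doc$walls)) {
    w <- doc$walls[[i]]
    check_keys(w, "spheres", sprintf("walls[%d]", i))
    sph <- purrr::map_dfr(w$spheres, function(s)
      tibble(x = s$x_nm, y = s$y_nm, z = s$z_nm, radius = s$radius_nm,
             colour = as.integer(s$colour)))
    sys <- add_wall(sys, wall_gestalt(sph))
  }
  for (i in seq_along(doc$interfaces)) {
    f <- doc$interfaces[[i]]
    check_keys(f, c("axis", "side", "species", "rho_per_nm3"),
               sprintf("interfaces[%d]", i))
    if (is.null(templates[[f$species]]))
      abort(sprintf("interfaces[%d] references undefined template '%s'",
                    i, f$species), class = "brownsim_config_error")
    sys <- add_interface(sys, density_interface(f$axis, f$side, f$species,
                                                f$rho_per_nm3),
                         templates[[f$species]])
  }
  species <- integer(0)
  for (i in seq_along(doc$species)) {
    s <- doc$species[[i]]
    check_keys(s, c("template", "count"), sprintf("species[%d]", i))
    if (is.null(templates[[s$template]]))
      abort(sprintf("species[%d] references undefined template '%s'",
                    i, s$template), class = "brownsim_config_error")
    species[s$template] <- s$count
  }
  list(system = sys, config = config, templates = templates, species = species)
}

#' Run a setup document and write its artifacts
#'
#' Loads a configuration, places the recorded species counts at random
#' non-overlapping positions, runs the simulation, and writes the
#' trajectory (plain text), the transport log (CSV, when interfaces are
#' present) and a run manifest (JSON with schema version, seed and config
#' hash); reruns with an identical manifest reproduce the outputs
#' bitwise.
#'
#' @param config_path Path to a `brownsim/1` YAML document.
#' @param out_dir Output directory (created if needed).
#' @param seed,steps,stride,hi Optional overrides of the document values.
#' @return The `bd_trajectory`, invisibly.
#' @export
run_command <- function(config_path, out_dir = ".", seed = NULL, steps = NULL,
                        stride = NULL, hi = NULL) {
  bundle <- load_config(config_path)
  config <- bundle$config
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(steps)) config$steps <- as.numeric(steps)
  if (!is.null(stride)) config$stride <- as.integer(stride)
  if (!is.null(hi)) config$hi <- isTRUE(hi)
  sys <- bundle$system
  if (length(bundle$species)) {
    set.seed(config$seed + 499979L)     # placement stream, separate from the run
    for (nm in names(bundle$species))
      if (bundle$species[[nm]] > 0)
        sys <- instantiate_random(sys, bundle$templates[[nm]],
                                  bundle$species[[nm]])
  }
  trj <- simulate(sys, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_trajectory(trj, file.path(out_dir, "trajectory.txt"))
  if (nrow(trj$events))
    write.csv(transport_log(trj), file.path(out_dir, "transport.csv"),
              row.names = FALSE)
  manifest <- list(schema = SCHEMA_VERSION, seed = config$seed,
                   steps = config$steps, stride = config$stride,
                   hi = config$hi, config_hash = rlang::hash(bundle),
                   n_gestalts = nrow(sys$state))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(trj)
}

#' Write trajectory frames as plain text
#'
#' Whitespace-separated table with a `#`-prefixed header; columns are the
#' frame columns (full record: frame, time, protein, species, gestalt,
#' position, quaternion; reduced record: center of mass + end-to-end).
#'
#' @param trajectory A `bd_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  fr <- trajectory$frames
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s trajectory", SCHEMA_VERSION), con)
  writeLines(paste0("# ", paste(names(fr), collapse = " ")), con)
  utils::write.table(fr, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a plain-text trajectory
#' @param path File written by [write_trajectory()].
#' @return A frames tibble.
#' @export
read_trajectory <- function(path) {
  hdr <- readLines(path, n = 2)
  cols <- strsplit(sub("^# ", "", hdr[2]), " ")[[1]]
  out <- utils::read.table(path, col.names = cols, comment.char = "#")
  as_tibble(out)
}

#' Write positions in XYZ format for molecular viewers
#'
#' @param trajectory A full-record `bd_trajectory`.
#' @param path Output file.
#' @param element Dummy element symbol.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(trajectory, path, element = "C") {
  fr <- trajectory$frames
  con <- file(path, "w")
  on.exit(close(con))
  for (f in unique(fr$frame)) {
    sub <- fr[fr$frame == f, ]
    writeLines(as.character(nrow(sub)), con)
    writeLines(sprintf("t = %g ps", sub$time_ps[1]), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", element, sub$x, sub$y, sub$z), con)
  }
  invisible(path)
}

#' Reduce full frames to center-of-mass + end-to-end records
#'
#' The post-hoc equivalent of the engine's `"com_ee"` on-the-fly reducer:
#' per protein and frame, the mean gestalt position and the vector from
#' the first to the last gestalt.
#'
#' @param frames A full-record frames tibble.
#' @return Reduced tibble with `x`, `y`, `z` (center of mass) and `ex`,
#'   `ey`, `ez`.
#' @export
reduce_com_ee <- function(frames) {
  frames |>
    dplyr::group_by(.data$frame, .data$time_ps, .data$protein, .data$species) |>
    dplyr::summarise(n_gestalts = dplyr::n(),
                     ex = .data$x[dplyr::n()] - .data$x[1],
                     ey = .data$y[dplyr::n()] - .data$y[1],
                     ez = .data$z[dplyr::n()] - .data$z[1],
                     x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
                     .groups = "drop") |>
    dplyr::select("frame", "time_ps", "protein", "species", "n_gestalts",
                  "x", "y", "z", "ex", "ey", "ez")
}
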