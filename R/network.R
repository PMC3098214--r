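# Dynamic interaction networks: map particle configurations onto graphs
# via a distance criterion and track cluster measures over time.

#' World positions of the coloured van-der-Waals spheres
#'
#' Extracts, for every frame, the world positions of all vdW spheres of a
#' given colour (e.g. the attractive patches), applying the gestalt
#' orientations and wrapping into the periodic cell.
#'
#' @param trajectory A full-record `bd_trajectory`.
#' @param system The `bd_system` the trajectory was generated from
#'   (provides the sphere offsets).
#' @param colour Colour index to extract.
#' @return Tibble with `frame`, `time_ps`, `node` (sphere id), `protein`,
#'   `x`, `y`, `z`.
#' @export
patch_positions <- function(trajectory, system, colour = 2L) {
  fr <- trajectory$frames
  if (!"qw" %in% names(fr)) abort("patch_positions needs a full trajectory")
  sp <- system$vdw[system$vdw$colour == colour, ]
  if (!nrow(sp)) abort(sprintf("no vdW spheres of colour %d", colour))
  sp$node <- seq_len(nrow(sp))
  out <- dplyr::inner_join(fr, sp, by = "gestalt", relationship = "many-to-many")
  # rotate offsets by the gestalt quaternions
  t2 <- function(a, b) 2 * (a * b)
  rx <- out$ox * (1 - t2(out$qy, out$qy) - t2(out$qz, out$qz)) +
    out$oy * (t2(out$qx, out$qy) - t2(out$qw, out$qz)) +
    out$oz * (t2(out$qx, out$qz) + t2(out$qw, out$qy))
  ry <- out$ox * (t2(out$qx, out$qy) + t2(out$qw, out$qz)) +
    out$oy * (1 - t2(out$qx, out$qx) - t2(out$qz, out$qz)) +
    out$oz * (t2(out$qy, out$qz) - t2(out$qw, out$qx))
  rz <- out$ox * (t2(out$qx, out$qz) - t2(out$qw, out$qy)) +
    out$oy * (t2(out$qy, out$qz) + t2(out$qw, out$qx)) +
    out$oz * (1 - t2(out$qx, out$qx) - t2(out$qy, out$qy))
  pos <- wrap_coords(cbind(out$x + rx, out$y + ry, out$z + rz), trajectory$box)
  tibble(frame = out$frame, time_ps = out$time_ps, node = out$node,
         protein = out$protein, x = pos[, 1], y = pos[, 2], z = pos[, 3])
}

#' Interaction network of one configuration
#'
#' Nodes are the supplied points; an undirected link connects every pair
#' with (minimum-image) center-center distance strictly less than
#' `cutoff`. The graph is simple: no self links, no duplicates.
#'
#' @param points Tibble/data frame with columns `x`, `y`, `z` and
#'   optionally `node` ids.
#' @param cutoff Distance criterion, nm (strict `<`).
#' @param box Optional [simulation_box()] for periodic minimum-image
#'   distances.
#' @return An `igraph` graph with vertex attribute `name`.
#' @export
build_network <- function(points, cutoff = 4, box = NULL) {
  points <- as_tibble(points)
  n <- nrow(points)
  ids <- as.character(points$node %||% seq_len(n))
  edges <- integer(0)
  if (n >= 2) {
    pr <- utils::combn(n, 2)
    d <- cbind(points$x[pr[1, ]] - points$x[pr[2, ]],
               points$y[pr[1, ]] - points$y[pr[2, ]],
               points$z[pr[1, ]] - points$z[pr[2, ]])
    if (!is.null(box)) d <- minimum_image(d, box)
    hit <- sqrt(rowSums(d^2)) < cutoff
    edges <- as.vector(pr[, hit, drop = FALSE])
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::simplify(g)
}

#' Cluster and degree measures of an interaction network
#'
#' @param network An `igraph` graph (from [build_network()]).
#' @return One-row tibble: `n_nodes`, `n_links`, `mean_degree`,
#'   `max_degree`, `n_clusters_gt1` (#CC(N>1)), `mean_size_gt1`
#'   (<N>(N>1)), `max_cluster`, plus the full `cluster_sizes` multiset as
#'   a list column.
#' @export
network_measures <- function(network) {
  deg <- igraph::degree(network)
  comp <- igraph::components(network)
  cs <- as.integer(comp$csize)
  big <- cs[cs > 1]
  tibble(n_nodes = igraph::vcount(network),
         n_links = igraph::ecount(network),
         mean_degree = if (length(deg)) mean(deg) else 0,
         max_degree = if (length(deg)) max(deg) else 0,
         n_clusters_gt1 = length(big),
         mean_size_gt1 = if (length(big)) mean(big) else 0,
         max_cluster = if (length(cs)) max(cs) else 0,
         cluster_sizes = list(sort(cs, decreasing = TRUE)))
}

#' Network measures over a whole trajectory
#'
#' Builds the distance-criterion network for every recorded frame and
#' returns the per-frame measures — the quantitative view of an
#' agglomeration simulation (cluster-size band, degree trace, cluster
#' counts).
#'
#' @param trajectory A full-record `bd_trajectory`.
#' @param system The originating `bd_system`.
#' @param colour Colour of the patch spheres that define the nodes.
#' @param cutoff Link criterion, nm (strict `<`).
#' @return Tibble: one row per frame with the [network_measures()]
#'   columns (class `network_series`).
#' @export
network_timeseries <- function(trajectory, system, colour = 2L, cutoff = 4) {
  pts <- patch_positions(trajectory, system, colour)
  out <- pts |>
    dplyr::group_by(.data$frame, .data$time_ps) |>
    dplyr::group_modify(function(df, key)
      network_measures(build_network(df, cutoff, trajectory$box))) |>
    dplyr::ungroup()
  class(out) <- c("network_series", class(out))
  out
}
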