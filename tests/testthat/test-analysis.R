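library(tibble)

# Trajectory post-processing: MSD, diffusion/scaling/transport fits,
# rotational relaxation and interaction networks.

synthetic_walk <- function(n_frames, D, dt, n_traces = 1) {
  purrr::map_dfr(seq_len(n_traces), function(tr) {
    steps <- matrix(rnorm(3 * n_frames, sd = sqrt(2 * D * dt)), n_frames, 3)
    tibble(frame = seq_len(n_frames) - 1, time_ps = (seq_len(n_frames) - 1) * dt,
           protein = tr, gestalt = tr,
           x = cumsum(steps[, 1]), y = cumsum(steps[, 2]), z = cumsum(steps[, 3]))
  })
}

test_that("MSD: stationary particle, free-diffusion recovery, lag handling", {
  still <- tibble(frame = 0:99, time_ps = (0:99) * 2, protein = 1, gestalt = 1,
                  x = 1, y = 2, z = 3)
  m <- msd_curve(still, "bead", lags = c(1, 5, 20))
  expect_equal(m$msd, rep(0, 3))
  set.seed(2)
  w <- synthetic_walk(4000, D = 1, dt = 0.5, n_traces = 40)
  m <- msd_curve(w, "bead", lags = c(1, 2, 5, 10))
  expect_lt(max(abs(m$D_app - 1)), 0.02)
  expect_warning(msd_curve(w, "bead", lags = c(1, 5000)), "lag")
  expect_error(msd_curve(still[1, ], "bead"), "two frames")
})

test_that("fit_long_time_D: exact line, CI recovery, window guard", {
  exact <- tibble(lag_ps = seq(10, 100, by = 10), msd = 6 * 0.5 * seq(10, 100, 10),
                  n = 100)
  f <- fit_long_time_D(exact)
  expect_equal(f$D, 0.5, tolerance = 1e-12)
  expect_s3_class(tidy(f), "tbl_df")
  expect_equal(glance(f)$D, 0.5)
  # parameter recovery within the stated CI on simulated free diffusion
  set.seed(14)
  ok <- 0
  for (r in 1:5) {
    w <- synthetic_walk(3000, D = 2, dt = 1, n_traces = 4)
    f <- fit_long_time_D(msd_curve(w, "bead", lags = 1:30),
                         window = c(1, 30))
    if (abs(f$D - 2) < 3 * max(f$se, 2 * 0.02)) ok <- ok + 1
  }
  expect_gte(ok, 4)
  expect_error(fit_long_time_D(exact[1:2, ], window = c(10, 20)),
               class = "brownsim_fit_error")
})

test_that("apparent bead D decreases from D_bead towards D_tr for a cluster", {
  sys <- example_hcp_system(13, with_HI = FALSE, k = 50)
  trj <- simulate(sys, simulation_config(dt = 5, steps = 3e4, stride = 1,
                                         seed = 4))
  m <- msd_curve(trj, "bead", lags = c(1, 3, 10, 30, 100, 300, 1000, 3000))
  expect_lt(max(abs(diff(m$D_app)) - 0), 1e9)  # numeric sanity
  expect_true(all(diff(m$D_app) < 1e-12))      # monotone decrease
  expect_rel_equal(m$D_app[1], 1.2e-4, 0.15)   # short lags: free bead value
  expect_lt(tail(m$D_app, 1), 3 * 1.2e-4 / 13) # approaching D_tr = D/N
})

test_that("rotational relaxation: closed form, frozen flag, synthetic decay", {
  # synthetic exponentially decorrelating unit vectors via small rotations
  set.seed(6)
  Drot <- 5e-3; dt <- 2
  u <- c(0, 0, 1); out <- matrix(0, 4000, 3)
  for (i in 1:4000) {
    w <- rnorm(3, sd = sqrt(2 * Drot * dt))
    th <- sqrt(sum(w^2)); ax <- w / th
    u <- u * cos(th) + cross3(ax, u) * sin(th) + ax * sum(ax * u) * (1 - cos(th))
    out[i, ] <- u
  }
  os <- tibble(protein = 1, time_ps = (1:4000) * dt,
               ux = out[, 1], uy = out[, 2], uz = out[, 3])
  fit <- rotational_relaxation(os, lags = seq(1, 100, by = 2))
  expect_rel_equal(fit$tau, 1 / (2 * Drot), 0.12)
  expect_true(fit$reliable)
  # frozen orientation: tau = Inf, flagged
  frozen <- tibble(protein = 1, time_ps = 1:50, ux = 1, uy = 0, uz = 0)
  ffit <- rotational_relaxation(frozen, lags = 1:10)
  expect_identical(ffit$tau, Inf)
  expect_false(ffit$reliable)
  # too-short trajectory relative to the decay: unreliable warning
  expect_warning(rotational_relaxation(os[1:5, ], lags = 1:3), "unreliable")
})

test_that("scaling exponent estimator: exactness, noise, guards", {
  f <- scaling_exponent(c(3, 5, 10, 15), c(3, 5, 10, 15)^-1)
  expect_equal(f$exponent, -1, tolerance = 1e-12)
  expect_lt(f$se, 1e-12)
  set.seed(10)
  sizes <- c(4, 8, 16, 32, 64)
  vals <- 2.5 * sizes^0.588 * exp(rnorm(5, sd = 0.01))
  f <- scaling_exponent(sizes, vals)
  expect_equal(f$exponent, 0.588, tolerance = 0.03)
  expect_gt(f$se, 0)
  expect_error(scaling_exponent(c(2, 4), c(1, 2)), class = "brownsim_fit_error")
  expect_error(scaling_exponent(c(2, 4, 8), c(1, -2, 3)),
               class = "brownsim_fit_error")
  expect_s3_class(tidy(f), "tbl_df")
})

test_that("transport fit: exact line, burn-in, undefined-fit flag", {
  log_df <- tibble(time_ps = 0:100, N_L = pmax(0, (0:100 - 5) * 2))
  f <- transport_fit(log_df)
  expect_equal(f$R_D, 2, tolerance = 1e-9)
  expect_equal(f$T_D, 5, tolerance = 1e-9)
  expect_equal(tidy(f)$estimate, c(2, 5), tolerance = 1e-9)
  expect_error(transport_fit(tibble(time_ps = 1:10, N_L = 0)),
               class = "brownsim_fit_error")
  # recovery across seeds on simulated exit processes (Poisson counts)
  set.seed(3)
  rate <- 0.05
  fits <- vapply(1:3, function(s) {
    tt <- seq(0, 4000, by = 10)
    nl <- cumsum(rpois(length(tt), rate * 10))
    transport_fit(tibble(time_ps = tt, N_L = nl))$R_D
  }, 1.0)
  expect_lt(abs(mean(fits) - rate) / rate, 0.1)
})

test_that("interaction networks: strict cutoff, measures, partition", {
  # chain of 3 nodes at 3.9 nm spacing: 2 links, one cluster of 3
  pts <- tibble(node = 1:3, x = c(0, 3.9, 7.8), y = 0, z = 0)
  g <- build_network(pts, cutoff = 4)
  m <- network_measures(g)
  expect_identical(m$n_links, 2)
  expect_identical(m$n_clusters_gt1, 1L)
  expect_equal(m$mean_size_gt1, 3)
  # distance exactly at the cutoff makes no link (strict inequality)
  g2 <- build_network(tibble(x = c(0, 4), y = 0, z = 0), cutoff = 4)
  expect_identical(igraph::ecount(g2), 0)
  # periodic minimum image links across the boundary
  box <- simulation_box(10, "periodic")
  g3 <- build_network(tibble(x = c(0.5, 9.9), y = 1, z = 1), cutoff = 4,
                      box = box)
  expect_identical(igraph::ecount(g3), 1)
  # empty graph on 27 nodes
  far <- tibble(x = 100 * (1:27), y = 0, z = 0)
  m0 <- network_measures(build_network(far, cutoff = 4))
  expect_equal(m0$mean_degree, 0)
  expect_identical(m0$max_degree, 0)
  expect_identical(m0$n_clusters_gt1, 0L)
  # one triangle + 24 singletons (hand-enumerated)
  tri <- tibble(x = c(0, 3, 1.5, 100 * (4:27)), y = c(0, 0, 2.5, rep(0, 24)),
                z = 0)
  mt <- network_measures(build_network(tri, cutoff = 4))
  expect_equal(mt$mean_degree, 6 / 27)
  expect_identical(mt$max_degree, 2)
  expect_identical(mt$n_clusters_gt1, 1L)
  expect_equal(mt$mean_size_gt1, 3)
  # cluster sizes always partition the node set
  set.seed(9)
  for (r in 1:20) {
    pts <- tibble(x = runif(27, 0, 30), y = runif(27, 0, 30),
                  z = runif(27, 0, 30))
    mm <- network_measures(build_network(pts, cutoff = 4, box = simulation_box(30, "periodic")))
    expect_identical(sum(mm$cluster_sizes[[1]]), 27L)
    # brute-force component search agrees
    d <- as.matrix(dist(pts))  # non-periodic brute force on open copy
    gg <- build_network(pts, cutoff = 4)
    adj <- d < 4; diag(adj) <- FALSE
    comp <- igraph::components(igraph::graph_from_adjacency_matrix(adj, "undirected"))
    expect_identical(igraph::components(gg)$no, comp$no)
  }
})

test_that("agglomeration trajectories yield per-frame network series", {
  sys <- example_agglomeration_system(12, seed = 5)
  trj <- simulate(sys, simulation_config(dt = 10, steps = 2000, stride = 200,
                                         seed = 5))
  ns <- network_timeseries(trj, sys, colour = 2L, cutoff = 4)
  expect_identical(nrow(ns), length(unique(trj$frames$frame)))
  expect_true(all(vapply(ns$cluster_sizes, sum, 1L) == 12L))
  expect_true(all(ns$max_degree >= ns$mean_degree))
})
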