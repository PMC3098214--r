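# Periodic wrapping and images, reflection, and the constant-density
# interface bookkeeping.

test_that("wrapping and minimum-image separations", {
  box <- simulation_box(c(10, 10, 10), "periodic")
  expect_equal(wrap_coords(c(10.1, -0.2, 3), box)[1, ], c(0.1, 9.8, 3))
  # pair at x = 0.1 and x = L - 0.1: separation 0.2, not L - 0.2
  d <- minimum_image(c(0.1 - 9.9, 0, 0), box)
  expect_equal(unname(d[1, 1]), 0.2)
  # pair energy invariant under shifting one particle by a full box length
  cfg <- simulation_config(dt = 1, steps = 1, seed = 1)
  mk <- function(shift) {
    g <- gestalt_template(geom_spec(1), vdw = list(vdw_sphere(radius = 1,
                                                              colour = 1L)))
    tpl <- protein_template("b", list(g))
    s <- new_system(box, colour_pair(1, 1, epsilon = 1, sigma = 0.5,
                                     attractive = TRUE, cutoff = 1.5))
    s <- instantiate(s, tpl, c(1, 5, 5))
    instantiate(s, tpl, c(3.7 + shift, 5, 5))
  }
  e0 <- accumulate_forces(mk(0), cfg)$energy
  expect_false(e0 == 0)
  expect_equal(accumulate_forces(mk(10), cfg)$energy, e0, tolerance = 1e-12)
  expect_equal(accumulate_forces(mk(-10), cfg)$energy, e0, tolerance = 1e-12)
  # cutoff must fit the periodic cell
  small <- simulation_box(c(4, 4, 4), "periodic")
  s <- instantiate(new_system(small, colour_pair(1, 1, 1, sigma = 2, cutoff = 6)),
                   protein_template("b", list(gestalt_template(geom_spec(1),
                     vdw = list(vdw_sphere(radius = 1, colour = 1L))))), c(1, 1, 1))
  expect_error(simulate(s, cfg), class = "brownsim_config_error")
})

test_that("reflection folds overshoots and preserves uniform density", {
  box <- simulation_box(c(5, 5, 5), "reflecting")
  expect_equal(reflect_coords(c(-0.3, 5.4, 2), box)[1, ], c(0.3, 4.6, 2))
  expect_equal(reflect_coords(c(1, 2, 3), box)[1, ], c(1, 2, 3))
  # long-run histogram in a closed reflecting box is uniform
  sys <- single_bead_system(D = 1, box = box)
  trj <- simulate(sys, simulation_config(dt = 0.05, steps = 4e4, stride = 4,
                                         seed = 3))
  xw <- trj$frames$x                  # on reflecting axes positions stay inside
  expect_true(all(xw >= 0 & xw <= 5))
  h <- hist(xw, breaks = seq(0, 5, by = 1), plot = FALSE)$counts
  expect_lt(max(abs(h / sum(h) - 0.2)), 0.05)
})

test_that("interface absorb/inject arithmetic and audit bookkeeping", {
  # nu = rho A sqrt(D dt / pi): reference value 2.854e-3 per step
  expect_equal(injection_rate(4e-4, 400, 1e-4, 10), 2.854e-3, tolerance = 1e-3)
  # crossing-depth sampler matches the analytic tail-profile oracle:
  # p(d) proportional to P(step > d), via a brute-force half-space hop
  set.seed(4)
  D <- 1e-4; dt <- 10; s <- sqrt(2 * D * dt)
  got <- sample_crossing_depth(4e4, D, dt)
  x0 <- runif(4e5) * 6 * s
  step <- abs(rnorm(4e5, sd = s))              # one-step move towards the plane
  brute <- (step - x0)[step > x0]
  expect_lt(suppressWarnings(ks.test(got, brute))$statistic, 0.02)
  # absorb: one particle stepped past the plane is removed and counted
  sys <- example_transport_system(rho_0 = 0)   # no injection, pure absorber
  bead <- build_simple_bead()
  sys <- instantiate(sys, bead, c(29.9, 10, 10))
  trj <- simulate(sys, simulation_config(dt = 10, steps = 3000, stride = 10,
                                         seed = 8, record = "none"))
  expect_identical(trj$counters$removed, 1)
  expect_identical(nrow(trj$events), 1L)
  expect_identical(trj$events$type, "absorb")
  # particle-number audit: N_p(t) - N_p(0) = injections - absorptions
  sys2 <- example_transport_system()
  trj2 <- simulate(sys2, simulation_config(dt = 10, steps = 3e4, stride = 100,
                                           seed = 9, record = "none"))
  ev <- trj2$events
  expect_equal(tail(trj2$series$n_p, 1),
                   sum(ev$type == "inject") - sum(ev$type == "absorb"))
  expect_equal(trj2$counters$inserted, sum(ev$type == "inject"))
})

test_that("opposed equal-density interfaces: detailed balance and equilibration", {
  # small fast-diffusing system so many fill times are simulated
  # ideal (non-interacting) particles: the reservoir bookkeeping is the
  # object under test, and at this step length a sub-step-sized repulsive
  # core could not be integrated meaningfully anyway
  bead <- build_simple_bead(radius = 0.2, D = 1e-3)
  rho <- 0.05; L <- 10; dt <- 10
  sys <- new_system(simulation_box(L, c("open", "periodic", "periodic")),
                    colour_pair(1, 1, epsilon = 0, sigma = 0.1,
                                cutoff = 0.3, r_lin = 0.05)) |>
    add_interface(density_interface("x", "low", "bead", rho), bead) |>
    add_interface(density_interface("x", "high", "bead", rho), bead)
  steps <- 3e4
  trj <- simulate(sys, simulation_config(dt = dt, steps = steps, stride = 100,
                                         seed = 21, record = "none"))
  ev <- trj$events
  # injection rate per interface = rho A sqrt(D dt / pi) (thermal one-sided
  # flux of the reservoir), within 5%
  nu <- injection_rate(rho, L^2, 1e-3, dt)
  expect_rel_equal(sum(ev$type == "inject") / steps, 2 * nu, 0.05)
  # at equilibrium the absorbed flux balances it
  expect_rel_equal(sum(ev$type == "absorb") / steps, 2 * nu, 0.05)
  # zero net mean current between the two sides
  ab_low <- sum(ev$type == "absorb" & ev$side == "low")
  ab_high <- sum(ev$type == "absorb" & ev$side == "high")
  expect_gt(ab_low, 1000)
  expect_lt(abs(ab_low - ab_high), 4 * sqrt(ab_low + ab_high))
  # time-averaged interior particle number reaches rho * V within 5%
  n_obs <- mean(tail(trj$series$n_p, 150))
  expect_rel_equal(n_obs, rho * L^3, 0.05)
})

test_that("unwrapped periodic trajectories equal the unbounded ones", {
  g <- gestalt_template(geom_spec(1), vdw = list(vdw_sphere(radius = 0.2,
                                                            colour = 1L)))
  tpl <- protein_template("b", list(g))
  cp <- colour_pair(1, 1, epsilon = 0, sigma = 0.05, cutoff = 0.15)
  cfg <- simulation_config(dt = 0.1, steps = 2000, stride = 1, seed = 33)
  open_sys <- instantiate(new_system(simulation_box(), cp), tpl, c(1, 1, 1))
  per_sys <- instantiate(new_system(simulation_box(2, "periodic"), cp),
                         tpl, c(1, 1, 1))
  t_open <- simulate(open_sys, cfg)
  t_per <- simulate(per_sys, cfg)
  expect_equal(t_per$frames$x, t_open$frames$x, tolerance = 1e-12)
  expect_equal(t_per$frames$z, t_open$frames$z, tolerance = 1e-12)
  # hence identical MSD after unwrapping
  expect_equal(msd_curve(t_per, "bead", lags = c(1, 10, 100))$msd,
               msd_curve(t_open, "bead", lags = c(1, 10, 100))$msd,
               tolerance = 1e-12)
})
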