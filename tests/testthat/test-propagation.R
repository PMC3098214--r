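# BD / LD stepping, rotational diffusion, determinism and divergence
# handling.

test_that("raw random displacements have the free-diffusion moments", {
  expect_equal(random_displacement(0, 1, 5), matrix(0, 5, 3))
  set.seed(1)
  D <- 0.7; dt <- 0.3
  R <- random_displacement(D, dt, 3e5)
  v <- 2 * D * dt
  # per-component variance 2 D dt within 0.5%
  expect_lt(max(abs(apply(R, 2, var) - v)) / v, 0.005 + 4 * sqrt(2 / 3e5))
  # zero mean within 4 standard errors
  expect_lt(max(abs(colMeans(R))), 4 * sqrt(v / 3e5))
})

test_that("displacement <-> force conversion round-trips through bd_step", {
  expect_equal(displacement_to_force(0, 1, 1), 0)
  # gamma = kT / D at the default thermal energy
  expect_equal(friction_coefficient(1.2e-4), bd_units()$kT / 1.2e-4)
  expect_rel_equal(friction_coefficient(1.2e-4), 20.3, 0.01)
  # f -> BD displacement reproduces R exactly
  R <- c(0.3, -0.1, 0.05)
  f <- displacement_to_force(R, D = 0.4, dt = 2)
  expect_equal(bd_step(c(0, 0, 0), f, D = 0.4, dt = 2), R)
})

test_that("bd_step: zero input, linearity in dt, ensemble MSD", {
  expect_equal(bd_step(c(1, 2, 3), c(0, 0, 0), 1, 0.1), c(1, 2, 3))
  d1 <- bd_step(0, 5, 0.3, 0.1) ; d2 <- bd_step(0, 5, 0.3, 0.2)
  expect_equal(d2, 2 * d1)
  # engine ensemble: free BD particles, per-step MSD = 6 D dt within 1%
  sys <- free_bead_ensemble(100, D = 1)
  trj <- simulate(sys, simulation_config(dt = 0.05, steps = 1000, stride = 1,
                                         seed = 5))
  fr <- trj$frames
  msd <- fr |>
    dplyr::group_by(.data$gestalt) |>
    dplyr::summarise(m = mean(diff(x)^2 + diff(y)^2 + diff(z)^2))
  expect_rel_equal(mean(msd$m), 6 * 1 * 0.05, 0.01)
})

test_that("ld_step closed form and the overdamped limit", {
  # F = 0, v0 = 0: nothing moves
  r <- ld_step(0, 0, 0, D = 1, mass = 1 / 1 * bd_units()$kT, dt = 1)
  expect_equal(r$x, 0); expect_equal(r$v, 0)
  # tau = 1, dt = 1, F/gamma = 1 nm/ps, v0 = 0:
  # dx = 1 - (1 - e^-1) = 0.367879
  kT <- bd_units()$kT
  D <- 1; mass <- kT          # tau = mass * D / kT = 1
  r <- ld_step(0, 0, F = 1 / D, D = D, mass = mass, dt = 1, kT = kT)
  expect_equal(r$x, 1 - (1 - exp(-1)), tolerance = 1e-9)
  expect_equal(r$v, 1 - exp(-1), tolerance = 1e-9)
  # dt >> tau: LD reduces to the BD displacement within 1%
  # the residual is exactly tau/dt = 1% at dt = 100 tau
  dt <- 100 * 1
  rb <- bd_step(0, F = 1, D = D, dt = dt)
  rl <- ld_step(0, 0, F = 1, D = D, mass = mass, dt = dt, kT = kT)
  expect_rel_equal(rl$x, rb, 0.0105)
})

test_that("free LD ensemble matches the inertial MSD closed form", {
  kT <- bd_units()$kT
  D <- 1.2e-4; m <- 20                  # tau_rel ~ 0.985 ps
  tau <- m * D / kT
  dt <- 0.2                             # dt/tau ~ 0.2
  sys <- free_bead_ensemble(150, D = D, mass = m)
  trj <- simulate(sys, simulation_config(dt = dt, steps = 1500, stride = 1,
                                         seed = 6))
  fr <- trj$frames[trj$frames$frame > 100, ]   # velocity thermalisation
  msd <- msd_curve(fr, "bead", lags = c(1, 2, 5, 10, 25, 50, 100))
  theory <- 6 * D * (msd$lag_ps - tau * (1 - exp(-msd$lag_ps / tau)))
  expect_lt(max(abs(msd$msd - theory) / theory), 0.10)
  # short-interval apparent D is suppressed well below the BD value
  expect_lt(msd$D_app[1], 0.35 * D)
})

test_that("apparent LD bead diffusion at dt ~ tau_rel is below the BD value", {
  # same multi-bead particle propagated with and without bead mass
  mk <- function(mass) {
    tpl <- build_hcp_particle(4, k = 50, with_HI = FALSE)
    if (!is.null(mass))
      for (i in seq_along(tpl$gestalts)) tpl$gestalts[[i]]$geom$mass <- mass
    new_system(simulation_box(),
               colour_pair(1, 1, epsilon = 1, sigma = 0.8, cutoff = 2.4,
                           r_lin = 0.4)) |> instantiate(tpl)
  }
  cfg <- simulation_config(dt = 1, steps = 4000, stride = 1, seed = 9)
  m_bd <- msd_curve(simulate(mk(NULL), cfg), "bead", lags = 1)
  m_ld <- msd_curve(simulate(mk(20), cfg), "bead", lags = 1)
  expect_lt(m_ld$D_app, m_bd$D_app)
  # mixed scheme in one run: massless protein diffuses per-step like BD,
  # massive one is inertially suppressed
  sys <- instantiate(mk(NULL), build_hcp_particle(4, k = 50,
                                                  name = "heavy4"),
                     position = c(100, 0, 0))
  sys$state$mass[5:8] <- 20
  trj <- simulate(sys, cfg)
  m <- msd_curve(trj$frames[trj$frames$protein == 1, ], "bead", lags = 1)
  m2 <- msd_curve(trj$frames[trj$frames$protein == 2, ], "bead", lags = 1)
  expect_lt(m2$D_app, 0.6 * m$D_app)
})

test_that("rotation step: frozen, free-rotor decay, Stokes-Einstein ratio", {
  q0 <- c(1, 0, 0, 0)
  expect_equal(rotation_step(q0, c(0, 0, 0), D_rot = 0, dt = 1), q0)
  # D_rot of a 2 nm sphere with D_tr = 1.2e-4: 3 D_tr / (4 a^2) = 2.25e-5,
  # matching the reported 2.26e-5 within rounding
  expect_equal(sphere_D_rot(1.2e-4, 2), 2.25e-5, tolerance = 1e-12)
  expect_rel_equal(sphere_D_rot(1.2e-4, 2), 2.26e-5, 0.005)
  # free rotor: <u(0).u(t)> = exp(-2 D_rot t)
  Drot <- 0.02; dt <- 0.5
  g <- gestalt_template(geom_spec(D_tr = 1, D_rot = Drot),
                        vdw = list(vdw_sphere(radius = 0.1, colour = 1L)))
  sys <- new_system(simulation_box(),
                    colour_pair(1, 1, epsilon = 0, sigma = 0.01, cutoff = 0.02))
  for (i in 1:60) sys <- instantiate(sys, protein_template("rotor", list(g)),
                                     c(10 * i, 0, 0))
  trj <- simulate(sys, simulation_config(dt = dt, steps = 2500, stride = 1,
                                         seed = 12))
  fit <- rotational_relaxation(trj, vector = "body_axis",
                               lags = seq(1, 150, by = 3))
  expect_rel_equal(fit$tau, 1 / (2 * Drot), 0.06)
  # orientation quaternions stay normalised through many updates
  qn <- with(trj$frames[trj$frames$frame == max(trj$frames$frame), ],
             qw^2 + qx^2 + qy^2 + qz^2)
  expect_lt(max(abs(qn - 1)), 1e-9)
})

test_that("trajectories are bitwise reproducible and zero-step runs are no-ops", {
  sys <- example_agglomeration_system(8, seed = 3)
  cfg <- simulation_config(dt = 10, steps = 300, stride = 10, seed = 42)
  t1 <- simulate(sys, cfg)
  t2 <- simulate(sys, cfg)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$series, t2$series)
  t3 <- simulate(sys, simulation_config(dt = 10, steps = 0, seed = 1))
  expect_identical(unique(t3$frames$frame), 0)
  expect_equal(t3$frames$x, sys$state$x)
})

test_that("diverging propagation names the step and gestalt", {
  g <- gestalt_template(geom_spec(D_tr = 1e4),
                        vdw = list(vdw_sphere(radius = 1, colour = 1L)),
                        restraints = list(restraint_constant(c(1e308, 0, 0))))
  sys <- instantiate(new_system(simulation_box(), colour_pair(1, 1, 1, 0.4)),
                     protein_template("runaway", list(g)))
  expect_error(simulate(sys, simulation_config(dt = 1e4, steps = 5, seed = 1)),
               "step.*gestalt")
})

test_that("a restrained particle reaches the Boltzmann positional variance", {
  k <- 10                                 # kT/nm^2 -> var = 1/k nm^2
  sys <- single_bead_system(D = 1, restraints = list(restraint_harmonic(k)))
  dt <- 0.002                             # D k dt = 0.02: discretisation ~1%
  trj <- simulate(sys, simulation_config(dt = dt, steps = 2e5, stride = 10,
                                         seed = 17))
  fr <- trj$frames[trj$frames$frame > 100, ]
  v <- mean(c(var(fr$x), var(fr$y), var(fr$z)))
  expect_rel_equal(v, 1 / k, 0.08)
})

test_that("forcing BD below ten velocity relaxation times warns", {
  g <- gestalt_template(geom_spec(D_tr = 1.2e-4, mass = 20),
                        vdw = list(vdw_sphere(radius = 1, colour = 1L)))
  sys <- instantiate(new_system(simulation_box(), colour_pair(1, 1, 1, 0.4)),
                     protein_template("heavy", list(g)))
  cfg <- simulation_config(dt = 1, steps = 2, seed = 1, propagation = "bd")
  expect_warning(simulate(sys, cfg), "tau_rel")
  # at dt >= 10 tau_rel the override is silent
  cfg2 <- simulation_config(dt = 20, steps = 2, seed = 1, propagation = "bd")
  expect_silent(suppressMessages(simulate(sys, cfg2)))
})
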