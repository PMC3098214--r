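# Pair interactions: screened electrostatics, colour-indexed vdW,
# bonds, external restraints and the accumulator's pair economics.

test_that("screened Coulomb energy: zero charge, Bjerrum length, burial", {
  r <- electrostatic_pair(c(0, 0, 0), c(1, 0, 0), q_i = 1, q_k = 0)
  expect_identical(r$energy, 0)
  expect_equal(r$force, c(0, 0, 0))

  # two unit charges at the Bjerrum length in water: exactly 1 kT
  lB <- coulomb_constant() / 80
  expect_gt(lB, 0.70); expect_lt(lB, 0.72)  # ~0.71 nm at ambient conditions
  r <- electrostatic_pair(c(0, 0, 0), c(lB, 0, 0), 1, 1, kappa = 0, eps_r = 80)
  expect_equal(r$energy, 1, tolerance = 1e-12)

  # burial depths exempt B = b_i + b_k from screening
  kappa <- 1
  r0 <- electrostatic_pair(c(0, 0, 0), c(2, 0, 0), 1, 1, b_i = 0.3, b_k = 0.2,
                           kappa = kappa)
  rB <- electrostatic_pair(c(0, 0, 0), c(2, 0, 0), 1, 1, kappa = kappa)
  expect_equal(r0$energy, rB$energy * exp(kappa * 0.5), tolerance = 1e-12)

  expect_error(electrostatic_pair(c(0, 0, 0), c(0, 0, 0), 1, 1),
               class = "brownsim_singular")
})

test_that("electrostatic force is -grad U and antisymmetric (property)", {
  set.seed(42)
  for (case in 1:100) {
    x <- runif(3, -3, 3)
    x <- x / sqrt(sum(x^2)) * runif(1, 0.5, 6)
    qi <- runif(1, -3, 3); qk <- runif(1, -3, 3)
    bi <- runif(1, 0, 0.5); bk <- runif(1, 0, 0.5)
    kap <- runif(1, 0, 2)
    f <- electrostatic_pair(x, c(0, 0, 0), qi, qk, bi, bk, kappa = kap)
    g <- fd_gradient(function(y)
      electrostatic_pair(y, c(0, 0, 0), qi, qk, bi, bk, kappa = kap)$energy, x)
    expect_equal(f$force, -g, tolerance = 1e-6)
    # equal and opposite
    f2 <- electrostatic_pair(c(0, 0, 0), x, qk, qi, bk, bi, kappa = kap)
    expect_equal(f$force, -f2$force, tolerance = 1e-12)
  }
})

test_that("vdW pair: cutoff, minimum, linearisation continuity, gradient", {
  p_att <- colour_pair(1, 1, epsilon = 2, sigma = 0.5, attractive = TRUE)
  # beyond cutoff: exactly zero
  r <- vdw_pair(c(0, 0, 0), c(1 + 1 + 3 * 0.5 + 0.01, 0, 0), 1, 1, p_att)
  expect_identical(r$energy, 0)
  # at the minimum s = sigma: energy -epsilon, zero force
  r <- vdw_pair(c(0, 0, 0), c(2.5, 0, 0), 1, 1, p_att)
  expect_equal(r$energy, -2, tolerance = 1e-12)
  expect_equal(r$force, c(0, 0, 0), tolerance = 1e-9)
  # repulsive-only pairs keep the s^-12 branch: monotone, positive
  p_rep <- colour_pair(1, 1, epsilon = 1, sigma = 0.5)
  e <- vapply(seq(0.3, 1.4, by = 0.1),
              function(s) vdw_pair(c(0, 0, 0), c(2 + s, 0, 0), 1, 1, p_rep)$energy,
              1.0)
  expect_true(all(diff(e) < 0) && all(e > 0))
  # energy and force continuous at the linearisation threshold
  h <- 1e-9
  for (p in list(p_att, p_rep)) {
    rl <- p$r_lin
    above <- vdw_pair(c(0, 0, 0), c(2 + rl + h, 0, 0), 1, 1, p)
    below <- vdw_pair(c(0, 0, 0), c(2 + rl - h, 0, 0), 1, 1, p)
    expect_equal(above$energy, below$energy, tolerance = 1e-6)
    expect_equal(above$force, below$force, tolerance = 1e-4)
    # force constant below the threshold
    deep1 <- vdw_pair(c(0, 0, 0), c(2 + rl / 2, 0, 0), 1, 1, p)
    deep2 <- vdw_pair(c(0, 0, 0), c(2 + rl / 4, 0, 0), 1, 1, p)
    expect_equal(deep1$force, deep2$force, tolerance = 1e-12)
  }
  # force = -grad U away from the joint (property over random geometries)
  set.seed(7)
  for (case in 1:60) {
    p <- colour_pair(1, 1, epsilon = runif(1, 0.5, 3), sigma = runif(1, 0.3, 1),
                     attractive = runif(1) > 0.5)
    s <- runif(1, p$r_lin * 1.2, p$cutoff * 0.95)
    dirv <- rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
    x <- (2 + s) * dirv
    f <- vdw_pair(x, c(0, 0, 0), 1, 1, p)
    g <- fd_gradient(function(y) vdw_pair(y, c(0, 0, 0), 1, 1, p)$energy, x,
                     h = 1e-7)
    expect_equal(f$force, -g, tolerance = 1e-5 * max(1, sqrt(sum(g^2))))
  }
})

test_that("bond forces: closed form, eccentric torque, tie-break", {
  b <- bond(1, 2, k2 = 1000, L0 = 2.5)
  # at rest length: no force, no torque
  r <- bond_forces(b, c(0, 0, 0), c(2.5, 0, 0))
  expect_equal(r$force_a, c(0, 0, 0))
  expect_equal(r$torque_a, c(0, 0, 0))
  # stretched by 0.1: |F| = k2 * 0.1 = 100 kT/nm along the bond axis
  r <- bond_forces(b, c(0, 0, 0), c(2.6, 0, 0))
  expect_equal(r$force_a, c(100, 0, 0), tolerance = 1e-12)
  expect_equal(r$force_b, -r$force_a)
  expect_equal(r$energy, 0.5 * 1000 * 0.1^2)
  # quartic term
  bq <- bond(1, 2, k2 = 10, k4 = 5, L0 = 1)
  r <- bond_forces(bq, c(0, 0, 0), c(1.3, 0, 0))
  expect_equal(sqrt(sum(r$force_a^2)), 10 * 0.3 + 5 * 0.3^3, tolerance = 1e-12)
  expect_equal(r$energy, 0.5 * 10 * 0.09 + 0.25 * 5 * 0.3^4, tolerance = 1e-12)
  # centered hooks never generate torque; eccentric hooks give offset x F
  be <- bond(1, 2, k2 = 100, L0 = 1, hook_a = c(0, 1, 0))
  r <- bond_forces(be, c(0, 0, 0), c(3, 1, 0))
  expect_equal(r$torque_a, cross3(c(0, 1, 0), r$force_a), tolerance = 1e-12)
  expect_equal(r$torque_b, c(0, 0, 0))
  # d = 0 with L0 > 0: documented +x tie-break
  r <- bond_forces(b, c(0, 0, 0), c(0, 0, 0))
  expect_equal(r$force_a / sqrt(sum(r$force_a^2)), c(1, 0, 0))
})

test_that("external restraints: harmonic center and constant force", {
  h <- restraint_harmonic(k = 10, x0 = c(1, 1, 1))
  expect_equal(external_force(h, c(1, 1, 1)), c(0, 0, 0))
  expect_equal(sqrt(sum(external_force(h, c(1.5, 1, 1))^2)), 5)
  cst <- restraint_constant(c(0, 0, -1))
  for (p in list(c(0, 0, 0), c(5, -3, 2)))
    expect_equal(external_force(cst, p), c(0, 0, -1))
})

test_that("accumulator: pair count N_p(N_p-1)/2 + N_p N_o and Newton's third law", {
  cfg <- simulation_config(dt = 1, steps = 1, seed = 1)
  # two mobile beads, no obstacles -> 1 pair
  sys <- free_bead_ensemble(2)
  expect_identical(accumulate_forces(sys, cfg)$n_int, 1)
  # 20 mobile + 18 obstacle spheres -> 190 + 360 = 550
  sys <- example_transport_system(layers = c(-10, 10), A_o = 5)
  bead <- build_simple_bead()
  set.seed(11)
  sys <- instantiate_random(sys, bead, 20, min_dist = 4.2)
  acc <- accumulate_forces(sys, cfg)
  expect_identical(acc$n_int, 20 * 19 / 2 + 20 * 18)
  # conservative mobile-mobile forces sum to zero (walls excluded):
  # rebuild without the wall to isolate the mobile-mobile part
  sys2 <- example_transport_system()
  set.seed(11)
  sys2 <- instantiate_random(sys2, bead, 20, min_dist = 4.2)
  acc2 <- accumulate_forces(sys2, cfg)
  expect_lt(max(abs(colSums(as.matrix(acc2$forces[, c("Fx", "Fy", "Fz")])))),
            1e-10)
})

test_that("energy is invariant under rigid translation and rotation", {
  cfg <- simulation_config(dt = 1, steps = 1, seed = 1, kappa = 0.5)
  g <- gestalt_template(geom_spec(1, 0.01),
                        vdw = list(vdw_sphere(c(0.3, 0, 0), 0.5, 1L)),
                        charges = list(point_charge(c(0, 0.2, 0), q = 2, b = 0.1)))
  tpl <- protein_template("blob", list(g))
  base <- new_system(simulation_box(),
                     colour_pair(1, 1, epsilon = 1.5, sigma = 0.4,
                                 attractive = TRUE))
  set.seed(3)
  sys0 <- base
  pos <- list(c(0, 0, 0), c(1.7, 0.4, -0.2), c(-0.5, 1.9, 0.8))
  for (p in pos) sys0 <- instantiate(sys0, tpl, p, random_quaternion_test())
  e0 <- accumulate_forces(sys0, cfg)$energy
  # rigid translation
  sys1 <- sys0
  sys1$state$x <- sys1$state$x + 11.3
  sys1$state$z <- sys1$state$z - 4.2
  expect_equal(accumulate_forces(sys1, cfg)$energy, e0, tolerance = 1e-10)
  # rigid rotation about the origin
  q <- quat_axis_angle(c(1, 2, 0.5), 1.1)
  sys2 <- sys0
  newp <- quat_rotate(q, cbind(sys0$state$x, sys0$state$y, sys0$state$z))
  sys2$state$x <- newp[, 1]; sys2$state$y <- newp[, 2]; sys2$state$z <- newp[, 3]
  for (i in seq_len(nrow(sys2$state))) {
    qi <- c(sys0$state$qw[i], sys0$state$qx[i], sys0$state$qy[i], sys0$state$qz[i])
    qn <- quat_multiply_test(q, qi)
    sys2$state$qw[i] <- qn[1]; sys2$state$qx[i] <- qn[2]
    sys2$state$qy[i] <- qn[3]; sys2$state$qz[i] <- qn[4]
  }
  expect_equal(accumulate_forces(sys2, cfg)$energy, e0, tolerance = 1e-10)
})

test_that("missing colour pairs are rejected with the pair named", {
  g <- gestalt_template(geom_spec(1), vdw = list(vdw_sphere(radius = 1, colour = 2L)))
  sys <- instantiate(new_system(simulation_box(), colour_pair(1, 1, 1, 0.4)),
                     protein_template("odd", list(g)))
  expect_error(accumulate_forces(sys, simulation_config(dt = 1, steps = 1)),
               "\\(2, 2\\)", class = "brownsim_config_error")
})
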