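# Rotne-Prager tensor assembly, TEA coefficients and correlated noise,
# and the exact Cholesky oracle.

test_that("RPY tensor: closed-form entries, limits, symmetry, PD", {
  # single sphere: D_self * I
  D1 <- rpy_tensor(rbind(c(0, 0, 0)), a = 2, D = 3e-4)
  expect_equal(unclass(D1), diag(3) * 3e-4)
  # two equal spheres at r = 4a: longitudinal coupling 3a/(2r) - a^3/r^3
  a <- 1.5; D <- 2e-4; r <- 4 * a
  Dm <- rpy_tensor(rbind(c(0, 0, 0), c(r, 0, 0)), a, D)
  expect_equal(Dm[1, 4], 0.359375 * D, tolerance = 1e-12)
  expect_equal(Dm[1, 4], rpy_longitudinal(r, a, D), tolerance = 1e-12)
  expect_equal(Dm[2, 5], rpy_transverse(r, a, D), tolerance = 1e-12)
  # coupling vanishes at large separation
  Dfar <- rpy_tensor(rbind(c(0, 0, 0), c(1e5, 0, 0)), a, D)
  expect_lt(max(abs(Dfar[1:3, 4:6])), 2 * D * a / 1e5)   # ~ 3c/(2r) -> 0
  # engine block agrees with the R assembly (independent implementations)
  blk <- brownsim:::cpp_rpy_block(c(r, 0, 0), a, a, D, D)$block
  expect_equal(blk, Dm[1:3, 4:6], tolerance = 1e-12)
  # overlap regularisation is continuous at contact and PD inside
  at <- rpy_tensor(rbind(c(0, 0, 0), c(2 * a + 1e-9, 0, 0)), a, D)
  ins <- rpy_tensor(rbind(c(0, 0, 0), c(2 * a - 1e-9, 0, 0)), a, D)
  expect_equal(unclass(at), unclass(ins), tolerance = 1e-6)
  expect_error(rpy_tensor(rbind(c(0, 0, 0), c(0, 0, 0)), a, D),
               class = "brownsim_singular")
  # symmetry + positive definiteness on random non-overlapping configurations
  set.seed(5)
  for (rep in 1:5) {
    pos <- random_spheres(12, a = 1, phi = 0.15)
    M <- unclass(rpy_tensor(pos, 1, 1))
    expect_equal(M, t(M), tolerance = 1e-12)
    expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("TEA coefficients: uncoupled limit, beta_ii = 1 convention, dimer", {
  # far-apart spheres: epsilon ~ 0, beta -> 1/2, C -> 1, output = input
  far <- rbind(c(0, 0, 0), c(1e5, 0, 0), c(0, 1e5, 0))
  co <- tea_coefficients(far, 1, 1)
  expect_lt(co$epsilon, 1e-4)
  expect_equal(co$beta, 0.5, tolerance = 1e-3)
  expect_equal(co$C, rep(1, 9), tolerance = 1e-6)
  raw <- matrix(rnorm(9), 3, 3)
  expect_equal(tea_random_forces(far, 1, 1, raw), raw, tolerance = 1e-4)
  expect_equal(tea_effective_forces(far, 1, 1, raw), raw, tolerance = 1e-4)
  # touching dimer: epsilon is the block-trace coupling at contact
  co2 <- tea_coefficients(rbind(c(0, 0, 0), c(2, 0, 0)), 1, 1)
  expect_equal(co2$epsilon, (0.625 + 2 * 0.4375) / 3, tolerance = 1e-12)
  expect_true(co2$beta > 0.5 && co2$beta < 1)
  expect_length(co2$C, 6)
  expect_true(all(co2$C > 0 & co2$C <= 1))
})

test_that("TEA effective forces implement F_i^eff = sum_k (D_ik/D_ii) F_k", {
  a <- 1; D <- 1; r <- 4 * a
  pos <- rbind(c(0, 0, 0), c(r, 0, 0))
  # force only on particle 2, along the axis: particle 1 receives the
  # longitudinal coupling fraction 0.359375
  F <- rbind(c(0, 0, 0), c(1, 0, 0))
  Fe <- tea_effective_forces(pos, a, D, F)
  expect_equal(Fe[1, 1], 0.359375, tolerance = 1e-12)
  expect_equal(Fe[2, ], c(1, 0, 0))  # own force unchanged
  # transverse component picks up the transverse coupling
  F2 <- rbind(c(0, 0, 0), c(0, 1, 0))
  expect_equal(tea_effective_forces(pos, a, D, F2)[1, 2],
               rpy_transverse(r, a, D), tolerance = 1e-12)
  # direct block evaluation on a random 5-sphere configuration
  set.seed(8)
  pos5 <- random_spheres(5, 1, 0.1)
  F5 <- matrix(rnorm(15), 5, 3)
  Dm <- unclass(rpy_tensor(pos5, 1, 1))
  # the tensor acts on the stacked (x1, y1, z1, x2, ...) force vector;
  # D_ii = 1 here so no normalisation is needed
  expected <- matrix(Dm %*% as.vector(t(F5)), ncol = 3, byrow = TRUE)
  expect_equal(tea_effective_forces(pos5, 1, 1, F5), expected,
               tolerance = 1e-10)
})

test_that("Cholesky oracle reproduces the tensor covariance exactly", {
  set.seed(21)
  pos <- random_spheres(6, 1, 0.12)
  Dm <- rpy_tensor(pos, 1, 1)
  # diagonal tensor: scales each component by sqrt(2 D dt)
  Dd <- rpy_tensor(rbind(c(0, 0, 0)), 2, 0.25)
  z <- rnorm(3)
  expect_equal(cholesky_correlate(Dd, z, dt = 2), sqrt(2 * 2 * 0.25) * z,
               tolerance = 1e-12)
  # covariance of correlated draws equals 2 D dt (definitional, by algebra)
  L <- t(chol(2 * unclass(Dm)))
  expect_equal(L %*% t(L), 2 * unclass(Dm), tolerance = 1e-12)
  # non-PD input (deep multi-overlap) raises the factorization error
  bad <- rpy_tensor(rbind(c(0, 0, 0), c(0.3, 0, 0), c(0, 0.3, 0)), 1, 1)
  if (min(eigen(unclass(bad), only.values = TRUE)$values) < 0)
    expect_error(cholesky_correlate(bad, rnorm(9)), class = "brownsim_not_pd")
})

test_that("TEA-vs-oracle: dimer error <= 5%, self-covariance preserved", {
  rep <- tea_accuracy(separations = c(2, 3, 4), n_random = integer(0))
  dimer <- rep[rep$case == "dimer", ]
  expect_lt(max(dimer$max_err_pct), 5)            # worst case: touching
  expect_gt(min(dimer$recovery_pct), 95)
  # errors shrink with separation
  expect_true(all(diff(dimer$max_err_pct) <= 0))
})

test_that("TEA correlated displacements conserve temperature (MC)", {
  set.seed(31)
  pos <- random_spheres(10, a = 1, phi = 0.12)
  D <- 0.3; dt <- 1
  n <- 2e4
  acc <- matrix(0, 10, 3)
  for (r in seq_len(n)) {
    raw <- matrix(rnorm(30, sd = sqrt(2 * D * dt)), 10, 3)
    Rc <- tea_random_forces(pos, 1, D, raw)
    acc <- acc + Rc^2
  }
  v <- acc / n
  # per-particle, per-axis displacement variance = 2 D dt within 2%
  expect_lt(max(abs(v - 2 * D * dt)) / (2 * D * dt), 0.02 + 3 * sqrt(2 / n))
})

test_that("TEA recovers >= 90% of pairwise correlations on dense systems", {
  set.seed(77)
  rep <- tea_accuracy(separations = numeric(0), n_random = c(10, 20, 30),
                      phi = 0.10, n_rep = 2)
  expect_gt(mean(rep$recovery_pct), 90)
})

test_that("step cost of the TEA path scales O(N^2)", {
  pos1 <- random_spheres(50, 1, 0.05)
  pos2 <- random_spheres(100, 1, 0.05)
  F1 <- matrix(0, 50, 3); F2 <- matrix(0, 100, 3)
  t1 <- min(vapply(1:5, function(i)
    system.time(for (r in 1:40) tea_random_forces(pos1, 1, 1, F1))[3], 1.0))
  t2 <- min(vapply(1:5, function(i)
    system.time(for (r in 1:40) tea_random_forces(pos2, 1, 1, F2))[3], 1.0))
  expect_lt(t2 / t1, 4.5)  # 4x for pure O(N^2) pair work
})
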