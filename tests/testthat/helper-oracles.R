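# Shared oracles: finite-difference gradients, closed-form RPY entries,
# and small-system constructors used across the test files.

# central-difference gradient of a scalar energy function at x (length 3)
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(1:3, function(i) {
    e <- numeric(3); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, 1.0)
}

# closed-form RPY couplings for two equal spheres (radius a, self-diffusion D)
rpy_longitudinal <- function(r, a, D) D * (3 * a / (2 * r) - a^3 / r^3)
rpy_transverse <- function(r, a, D) D * (3 * a / (4 * r) + a^3 / (2 * r^3))

# random non-overlapping sphere configuration at a given volume fraction
random_spheres <- function(n, a = 1, phi = 0.1) {
  L <- (n * 4 / 3 * pi * a^3 / phi)^(1 / 3)
  pos <- matrix(NA_real_, n, 3)
  i <- 1
  while (i <= n) {
    p <- runif(3, 0, L)
    ok <- i == 1 ||
      min(sqrt(colSums((t(pos[seq_len(i - 1), , drop = FALSE]) - p)^2))) >= 2 * a
    if (ok) { pos[i, ] <- p; i <- i + 1 }
  }
  pos
}

# one-bead system with optional restraint, for propagator tests
single_bead_system <- function(D = 1, radius = 1, restraints = list(),
                               mass = NULL, D_rot = 0, box = simulation_box()) {
  g <- gestalt_template(geom_spec(D_tr = D, D_rot = D_rot, mass = mass),
                        vdw = list(vdw_sphere(radius = radius, colour = 1L)),
                        restraints = restraints)
  tpl <- protein_template("bead", list(g))
  instantiate(new_system(box, colour_pair(1, 1, epsilon = 1, sigma = 0.4)),
              tpl, position = box$L / 2)
}

# M independent free beads in one system (ensemble statistics)
free_bead_ensemble <- function(M, D = 1, mass = NULL) {
  g <- gestalt_template(geom_spec(D_tr = D, mass = mass),
                        vdw = list(vdw_sphere(radius = 0.1, colour = 1L)))
  tpl <- protein_template("bead", list(g))
  sys <- new_system(simulation_box(),
                    colour_pair(1, 1, epsilon = 0, sigma = 0.01, cutoff = 0.02))
  for (i in seq_len(M))
    sys <- instantiate(sys, tpl, position = c(100 * i, 0, 0))
  sys
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}

# local quaternion helpers (independent of package internals)
quat_multiply_test <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

random_quaternion_test <- function() {
  u <- runif(3)
  c(sqrt(u[1]) * cos(2 * pi * u[3]),
    sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
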