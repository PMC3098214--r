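# Rotne-Prager-Yamakawa diffusion tensor, the truncated expansion
# approximation (TEA) of its square root, and the exact Cholesky oracle.

#' Assemble the Rotne-Prager-Yamakawa diffusion tensor
#'
#' Dense 3N x 3N mobility matrix over a set of hydrodynamic spheres.
#' Diagonal blocks are `D_self * I`; off-diagonal blocks use the
#' unequal-radii RPY far-field form for `r >= a_i + a_k` and the
#' regularised overlap form (with the mean radius for unequal spheres, a
#' working ansatz exact for equal radii) for closer centers.
#'
#' @param positions n x 3 matrix of sphere centers (nm).
#' @param a Radii (nm), recycled.
#' @param D Self-diffusion coefficients (nm^2/ps), recycled.
#' @param box Optional [simulation_box()] for minimum-image separations.
#' @return A 3n x 3n symmetric matrix (class `rpy_tensor`), nm^2/ps.
#' @examples
#' D <- rpy_tensor(rbind(c(0, 0, 0), c(8, 0, 0)), a = 2, D = 1e-4)
#' D[1, 4] / D[1, 1] # longitudinal coupling 3a/(2r) - a^3/r^3
#' @export
rpy_tensor <- function(positions, a, D, box = NULL) {
  positions <- rbind(positions)[, 1:3, drop = FALSE]
  n <- nrow(positions)
  a <- rep_len(a, n); D <- rep_len(D, n)
  M <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) {
    M[3 * i - 2:0, 3 * i - 2:0] <- diag(3) * D[i]
    if (i < n) for (k in (i + 1):n) {
      d <- positions[i, ] - positions[k, ]
      if (!is.null(box)) d <- as.numeric(minimum_image(d, box))
      r <- sqrt(sum(d^2))
      if (r < 1e-9)
        abort("singular configuration: coincident hydrodynamic centers",
              class = "brownsim_singular")
      e <- d / r
      P <- outer(e, e)
      cc <- sqrt(D[i] * a[i] * D[k] * a[k])  # kT / (6 pi eta)
      if (r >= a[i] + a[k]) {
        a2 <- a[i]^2 + a[k]^2
        B <- 0.75 * cc / r * ((1 + a2 / (3 * r^2)) * diag(3) +
                                (1 - a2 / r^2) * P)
      } else {
        ab <- (a[i] + a[k]) / 2
        B <- cc / ab * ((1 - 9 * r / (32 * ab)) * diag(3) +
                          (3 * r / (32 * ab)) * P)
      }
      M[3 * i - 2:0, 3 * k - 2:0] <- B
      M[3 * k - 2:0, 3 * i - 2:0] <- B
    }
  }
  structure(M, class = c("rpy_tensor", "matrix", "array"))
}

#' TEA coupling coefficients of a diffusion tensor
#'
#' The truncated expansion approximation replaces the matrix square root
#' needed for correlated random displacements by normalised pairwise
#' couplings: `epsilon` is the mean block-trace-normalised off-diagonal
#' coupling `<tr(D_ik) / (3 sqrt(D_ii D_kk))>` over particle pairs; the
#' uniform off-diagonal weight `beta` (with `beta_ii = 1`) solves
#' `a beta^2 + 2 beta - 1 = 0`, `a = epsilon ((N-2) - (N-1) epsilon)`,
#' taking the root continuous with `beta -> 1/2` as `epsilon -> 0`; and
#' the per-coordinate factors `C_i` normalise the correlated displacements
#' so their self-covariance stays exactly `2 D_ii dt` ("temperature
#' conservation"). If the quadratic has no real root, `beta = 1` is used
#' with a warning.
#'
#' @param positions,a,D,box As in [rpy_tensor()].
#' @return List with `epsilon`, `beta`, `C` (length 3n) and `fallback`.
#' @export
tea_coefficients <- function(positions, a, D, box = NULL) {
  positions <- rbind(positions)[, 1:3, drop = FALSE]
  n <- nrow(positions)
  res <- cpp_tea_coefficients(positions, rep_len(a, n), rep_len(D, n))
  if (isTRUE(res$fallback))
    warn("TEA quadratic has no real root; falling back to beta = 1")
  res
}

#' Hydrodynamically corrected deterministic forces
#'
#' `F_i^eff = sum_k (D_ik / D_ii) F_k`: the velocity coupling of the
#' diffusion tensor applied to the deterministic forces, normalised by
#' the self-mobility.
#'
#' @param positions,a,D As in [rpy_tensor()].
#' @param F n x 3 matrix of per-particle forces.
#' @return n x 3 matrix of effective forces.
#' @export
tea_effective_forces <- function(positions, a, D, F) {
  positions <- rbind(positions)[, 1:3, drop = FALSE]
  n <- nrow(positions)
  cpp_tea_apply(positions, rep_len(a, n), rep_len(D, n), rbind(F),
                matrix(0, n, 3))$F_eff
}

#' TEA-correlated random displacements
#'
#' `R_i = C_i (r_i + beta sum_k (D_ik / D_kk) r_k)` applied to raw
#' uncorrelated Gaussian displacements `r_k` (per-coordinate variance
#' `2 D_kk dt`). Evaluated streaming over two-body tensor blocks; the
#' full tensor is never materialised.
#'
#' @param positions,a,D As in [rpy_tensor()].
#' @param raw n x 3 matrix of raw Gaussian displacements.
#' @return n x 3 matrix of correlated displacements.
#' @export
tea_random_forces <- function(positions, a, D, raw) {
  positions <- rbind(positions)[, 1:3, drop = FALSE]
  n <- nrow(positions)
  cpp_tea_apply(positions, rep_len(a, n), rep_len(D, n), matrix(0, n, 3),
                rbind(raw))$R_corr
}

#' Exactly correlated random displacements (Cholesky oracle)
#'
#' The Ermak-McCammon reference: correlates raw standard-normal draws with
#' the Cholesky factor of the diffusion tensor so the displacement
#' covariance equals `2 D dt` exactly. Numerically expensive; used as the
#' accuracy oracle for the TEA path.
#'
#' @param tensor A [rpy_tensor()] (positive definite).
#' @param raw 3n-vector (or 3n x m matrix) of standard-normal draws.
#' @param dt Timestep, ps.
#' @return Correlated displacements, same shape as `raw` (nm).
#' @export
cholesky_correlate <- function(tensor, raw, dt = 1) {
  Lf <- tryCatch(t(chol(2 * dt * unclass(tensor))),
                 error = function(e)
                   abort("diffusion tensor is not positive definite (overlapping or invalid geometry)",
                         class = "brownsim_not_pd"))
  was_vec <- !is.matrix(raw)
  out <- Lf %*% (if (was_vec) matrix(raw, ncol = 1) else raw)
  if (was_vec) as.numeric(out) else as.matrix(out)
}

# Analytic TEA displacement covariance (per 2*dt), via the coefficient
# definitions; small n only.
tea_covariance <- function(positions, a, D, box = NULL) {
  positions <- rbind(positions)[, 1:3, drop = FALSE]
  n <- nrow(positions)
  a <- rep_len(a, n); D <- rep_len(D, n)
  Dm <- unclass(rpy_tensor(positions, a, D, box))
  co <- cpp_tea_coefficients(positions, a, D)
  n3 <- 3 * n
  Dii <- rep(D, each = 3)
  Bmat <- matrix(co$beta, n3, n3)
  diag(Bmat) <- 1
  M <- (co$C * Bmat * Dm) / rep(Dii, each = n3)  # rows i: C_i beta_ik D_ik / D_kk
  M %*% (2 * diag(Dii)) %*% t(M)
}

#' TEA accuracy against the exact factorization
#'
#' Compares the analytic TEA displacement covariance with the exact tensor
#' (the covariance the Cholesky factorization reproduces identically) for
#' a dimer across separations and for random non-overlapping
#' configurations, reporting the maximum elementwise error (normalised by
#' the self term) and the recovered fraction of the off-diagonal
#' covariance (magnitude-weighted mean ratio of TEA to exact).
#'
#' @param a Sphere radius, nm.
#' @param D Self-diffusion coefficient, nm^2/ps.
#' @param separations Dimer center distances (units of `a`).
#' @param n_random Sphere counts of the random configurations.
#' @param phi Volume fraction of the random configurations.
#' @param n_rep Random configurations per size.
#' @return Tibble with columns `case`, `n`, `separation`, `max_err_pct`,
#'   `recovery_pct`.
#' @export
tea_accuracy <- function(a = 1, D = 1, separations = c(2, 2.5, 3, 4, 6),
                         n_random = c(10, 20, 30, 40, 50), phi = 0.10,
                         n_rep = 3) {
  one <- function(positions) {
    Dm <- unclass(rpy_tensor(positions, a, D))
    exact <- 2 * Dm
    cv <- tea_covariance(positions, a, D)
    off <- row(Dm) != col(Dm)
    tibble(
      max_err_pct = 100 * max(abs(cv - exact)) / (2 * D),
      recovery_pct = 100 * sum(cv[off] * exact[off]) / sum(exact[off]^2))
  }
  dimer <- purrr::map_dfr(separations, function(s) {
    dplyr::mutate(one(rbind(c(0, 0, 0), c(s * a, 0, 0))),
                  case = "dimer", n = 2, separation = s, .before = 1)
  })
  rand <- purrr::map_dfr(n_random, function(n) {
    purrr::map_dfr(seq_len(n_rep), function(rep) {
      L <- (n * 4 / 3 * pi * a^3 / phi)^(1 / 3)
      pos <- matrix(NA_real_, n, 3)
      i <- 1
      while (i <= n) {
        p <- runif(3, 0, L)
        if (i == 1 || min(sqrt(colSums((t(pos[seq_len(i - 1), , drop = FALSE]) - p)^2))) >= 2 * a) {
          pos[i, ] <- p; i <- i + 1
        }
      }
      dplyr::mutate(one(pos), case = "random", n = n, separation = NA_real_,
                    .before = 1)
    })
  })
  dplyr::bind_rows(dimer, rand)
}
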