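# Independent oracles used across the suite. These deliberately re-derive
# quantities through routes different from the implementation.

# Unit-conversion oracle: rebuilds the Bohr radius and fine-structure
# constant from SI constants (the package stores them as CODATA numbers)
# and evaluates the closed-form conversion factors.
oracle_mpa_constants <- function() {
  e <- 1.602176634e-19; me <- 9.1093837015e-31; c <- 2.99792458e8
  eps0 <- 8.8541878128e-12; hbar <- 1.054571817e-34
  a0 <- 4 * pi * eps0 * hbar^2 / (me * e^2)
  alpha <- e^2 / (4 * pi * eps0 * hbar * c)
  list(
    k_tpa = 8 * pi^3 * alpha * (a0 * 100)^5 / (c * 100) / 1e-50,
    k_3pa = 16 * pi^4 * alpha * (a0 * 100)^8 / (c * 100)^2 / 1e-80
  )
}

# single-state record table
one_state_records <- function(energy_eV, fosc = 0, delta_tpa = 0,
                              delta_3pa = 0) {
  tibble::tibble(snapshot = 1L, time_fs = 0, chromophore = "TEST",
                 state = 1L, energy_eV = energy_eV, fosc = fosc,
                 delta_tpa_au = delta_tpa, delta_3pa_au = delta_3pa)
}

# brute-force lagged autocorrelation, Eq-style biased normalization
oracle_acf <- function(x, k) {
  n <- length(x); mu <- mean(x); s2 <- mean((x - mu)^2)
  acc <- 0
  for (t in seq_len(n - k)) acc <- acc + (x[t] - mu) * (x[t + k] - mu)
  acc / (n * s2)
}

# brute-force pairwise Coulomb energy and env-point forces (a.u.)
oracle_coulomb <- function(cloud_pos, cloud_q, env_pos, env_q) {
  energy <- 0
  forces <- matrix(0, nrow(env_pos), 3)
  for (i in seq_len(nrow(cloud_pos))) {
    for (j in seq_len(nrow(env_pos))) {
      d <- env_pos[j, ] - cloud_pos[i, ]
      r <- sqrt(sum(d^2))
      energy <- energy + cloud_q[i] * env_q[j] / r
      forces[j, ] <- forces[j, ] + cloud_q[i] * env_q[j] * d / r^3
    }
  }
  list(energy = energy, forces = forces)
}

# term-by-term static multipole field oracle (charge + dipole + traceless
# quadrupole of one site at the origin, evaluated at r)
oracle_site_field <- function(r, q, mu, Q) {
  rn <- sqrt(sum(r^2))
  f <- q * r / rn^3
  f <- f + 3 * sum(mu * r) * r / rn^5 - mu / rn^3
  Qr <- as.vector(Q %*% r)
  f + 2.5 * sum(r * Qr) * r / rn^7 - Qr / rn^5
}

# seeded random env shell around the origin
random_env_shell <- function(n, r_min, r_max) {
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  r <- runif(n, r_min, r_max)
  tibble::tibble(x = u[, 1] * r, y = u[, 2] * r, z = u[, 3] * r,
                 q = runif(n, -1, 1))
}

rotation_matrix_xyz <- function(ax, ay, az) {
  Rx <- matrix(c(1, 0, 0, 0, cos(ax), -sin(ax), 0, sin(ax), cos(ax)),
               3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(ay), 0, sin(ay), 0, 1, 0, -sin(ay), 0, cos(ay)),
               3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(az), -sin(az), 0, sin(az), cos(az), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}
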