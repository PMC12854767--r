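#' Point-charge clouds (atomic units)
#'
#' The surrogate for a quantum charge distribution in the toy coupling
#' model: point charges at fixed positions, all in atomic units (bohr, e).
#' The expansion/cutoff center is the geometric centroid of the positions,
#' recomputed on construction.
#'
#' @param positions n x 3 matrix (bohr), or a data frame with columns
#'   `x`, `y`, `z` (and optionally `q`).
#' @param charges Charges in e (taken from column `q` if omitted).
#' @return An `mpa_cloud` list: `positions`, `charges`, `centroid`.
#' @export
charge_cloud <- function(positions, charges = NULL) {
  if (is.data.frame(positions)) {
    charges <- charges %||% positions$q
    positions <- as.matrix(positions[, c("x", "y", "z")])
  }
  positions <- as.matrix(positions)
  if (nrow(positions) < 1L || is.null(charges) ||
      length(charges) != nrow(positions) || any(!is.finite(positions)) ||
      any(!is.finite(charges))) {
    abort("cloud needs >= 1 finite position with matching charges",
          class = "mpaspec_validation_error")
  }
  structure(list(positions = positions, charges = as.numeric(charges),
                 centroid = colMeans(positions)),
            class = "mpa_cloud")
}

as_env_points <- function(env) {
  if (inherits(env, "mpa_cloud")) {
    return(list(positions = env$positions, charges = env$charges))
  }
  if (is.data.frame(env)) {
    return(list(positions = as.matrix(env[, c("x", "y", "z")]),
                charges = env$q))
  }
  abort("environment must be a data frame with x, y, z, q or an mpa_cloud",
        class = "mpaspec_validation_error")
}

#' Exact Coulomb interaction between a cloud and environment charges
#'
#' All pairwise electrostatic interactions, no cutoff:
#' \eqn{E = \sum_{i \in cloud} \sum_{j \in env} q_i q_j / r_{ij}} with
#' analytic forces on the environment points,
#' \eqn{F_j = q_j \sum_i q_i (r_j - r_i)/r_{ij}^3}. The cloud is rigid; only
#' environment forces are reported. Atomic units throughout.
#'
#' @param cloud An `mpa_cloud`.
#' @param env Environment charges: data frame `x`, `y`, `z`, `q` (bohr, e)
#'   or an `mpa_cloud`.
#' @return List `energy` (hartree), `forces` (n_env x 3, hartree/bohr).
#' @export
exact_interaction <- function(cloud, env) {
  ep <- as_env_points(env)
  energy <- 0
  forces <- matrix(0, nrow(ep$positions), 3)
  for (j in seq_len(nrow(ep$positions))) {
    dr <- sweep(cloud$positions, 2, ep$positions[j, ], `-`)  # r_i - r_j
    r2 <- rowSums(dr^2)
    if (any(r2 == 0)) {
      abort("coincident cloud/environment points",
            class = "mpaspec_validation_error")
    }
    r <- sqrt(r2)
    energy <- energy + ep$charges[j] * sum(cloud$charges / r)
    # F_j = q_j sum_i q_i (r_j - r_i) / r^3
    forces[j, ] <- -ep$charges[j] *
      colSums(dr * (cloud$charges / r^3))
  }
  list(energy = energy, forces = forces)
}

double_factorial <- function(n) if (n <= 0) 1 else prod(seq(n, 1, by = -2))

# Cartesian derivative tensors D_{tuv} = d^t/dx d^u/dy d^v/dz (1/R),
# evaluated at displacement dr, for all t+u+v <= N, by the
# McMurchie-Davidson recursion on auxiliary tensors R^n.
rtensor <- function(dr, N) {
  r2 <- sum(dr^2)
  r <- sqrt(r2)
  # R[[n+1]][t+1, u+1, v+1]; valid entries satisfy n + t + u + v <= N
  R <- lapply(0:N, function(n) array(0, dim = rep(N + 1L, 3)))
  for (n in 0:N) {
    R[[n + 1L]][1, 1, 1] <- (-1)^n * double_factorial(2 * n - 1) / r^(2 * n + 1)
  }
  if (N == 0L) return(R[[1L]])
  for (j in 1:N) {
    for (t in 0:j) for (u in 0:(j - t)) {
      v <- j - t - u
      for (n in 0:(N - j)) {
        val <- if (t > 0) {
          (if (t > 1) (t - 1) * R[[n + 2L]][t - 1, u + 1, v + 1] else 0) +
            dr[1] * R[[n + 2L]][t, u + 1, v + 1]
        } else if (u > 0) {
          (if (u > 1) (u - 1) * R[[n + 2L]][1, u - 1, v + 1] else 0) +
            dr[2] * R[[n + 2L]][1, u, v + 1]
        } else {
          (if (v > 1) (v - 1) * R[[n + 2L]][1, 1, v - 1] else 0) +
            dr[3] * R[[n + 2L]][1, 1, v]
        }
        R[[n + 1L]][t + 1L, u + 1L, v + 1L] <- val
      }
    }
  }
  R[[1L]]
}

#' Cartesian multipole expansion of a charge cloud
#'
#' Symmetric Cartesian moments \eqn{M_{tuv} = \sum_i q_i\, dx_i^t dy_i^u
#' dz_i^v} about the cloud centroid, for all total orders up to `order`
#' (maximum 8). The far field is evaluated by contracting the moments with
#' the derivative tensors of 1/R; those tensors are harmonic (traceless in
#' every index pair), so trace components of the raw moments contribute
#' nothing and the result equals the traceless-tensor formulation.
#'
#' @param cloud An `mpa_cloud`.
#' @param order Maximum total multipole order p, 0 to 8.
#' @return An `mpa_multipoles` list: `center`, `order`, `moments`
#'   (array indexed \[t+1, u+1, v+1\]).
#' @export
multipole_expansion <- function(cloud, order) {
  if (order < 0 || order > 8) {
    abort("multipole order must be between 0 and 8",
          class = "mpaspec_validation_error")
  }
  dr <- sweep(cloud$positions, 2, cloud$centroid, `-`)
  M <- array(0, dim = rep(order + 1L, 3))
  for (t in 0:order) for (u in 0:(order - t)) for (v in 0:(order - t - u)) {
    M[t + 1L, u + 1L, v + 1L] <-
      sum(cloud$charges * dr[, 1]^t * dr[, 2]^u * dr[, 3]^v)
  }
  structure(list(center = cloud$centroid, order = order, moments = M),
            class = "mpa_multipoles")
}

#' Far-field potential and field of a multipole expansion
#'
#' Taylor-expansion evaluation: \eqn{V(R) = \sum_{|\alpha| \le p}
#' \frac{(-1)^{|\alpha|}}{\alpha!} M_\alpha D_\alpha(1/|R - C|)}; the field
#' is the negative gradient, obtained from derivative tensors one order
#' higher.
#'
#' @param mp An `mpa_multipoles`.
#' @param points m x 3 matrix of evaluation points (bohr).
#' @return `multipole_potential()`: numeric vector (hartree/e);
#'   `multipole_field()`: m x 3 matrix (a.u.).
#' @export
multipole_potential <- function(mp, points) {
  points <- rbind(points)
  vapply(seq_len(nrow(points)), function(j) {
    D <- rtensor(points[j, ] - mp$center, mp$order)
    acc <- 0
    for (t in 0:mp$order) for (u in 0:(mp$order - t)) {
      for (v in 0:(mp$order - t - u)) {
        acc <- acc + (-1)^(t + u + v) / (factorial(t) * factorial(u) *
                                           factorial(v)) *
          mp$moments[t + 1L, u + 1L, v + 1L] * D[t + 1L, u + 1L, v + 1L]
      }
    }
    acc
  }, numeric(1))
}

#' @rdname multipole_potential
#' @export
multipole_field <- function(mp, points) {
  points <- rbind(points)
  out <- matrix(0, nrow(points), 3)
  for (j in seq_len(nrow(points))) {
    D <- rtensor(points[j, ] - mp$center, mp$order + 1L)
    for (t in 0:mp$order) for (u in 0:(mp$order - t)) {
      for (v in 0:(mp$order - t - u)) {
        cf <- (-1)^(t + u + v) / (factorial(t) * factorial(u) * factorial(v)) *
          mp$moments[t + 1L, u + 1L, v + 1L]
        out[j, 1] <- out[j, 1] - cf * D[t + 2L, u + 1L, v + 1L]
        out[j, 2] <- out[j, 2] - cf * D[t + 1L, u + 2L, v + 1L]
        out[j, 3] <- out[j, 3] - cf * D[t + 1L, u + 1L, v + 2L]
      }
    }
  }
  out
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' ESP-fitted atom-centered charges
#'
#' Least-squares charges at the cloud's own atom positions that reproduce
#' the cloud's electrostatic potential on a shell grid, with the total
#' charge constrained exactly (Lagrange multiplier). The grid places
#' `n_per_shell` points on spheres of radius `shell_radii * scale` around
#' every atom, pruned of points closer than `prune_radius` to any atom.
#'
#' @param cloud An `mpa_cloud`.
#' @param shell_radii Shell radii in bohr (default 2, 3, 4).
#' @param scale Multiplier applied to the shell radii (default 1).
#' @param prune_radius Minimum distance of a grid point to any atom (bohr).
#' @param n_per_shell Points per shell before pruning.
#' @return List `charges` (fitted, summing exactly to the cloud total),
#'   `rms_residual` (potential RMS error on the grid), `grid` (m x 3).
#' @export
espf_fit <- function(cloud, shell_radii = c(2, 3, 4), scale = 1,
                     prune_radius = 1.5, n_per_shell = 32) {
  n <- nrow(cloud$positions)
  sph <- fibonacci_sphere(n_per_shell)
  grid <- do.call(rbind, lapply(seq_len(n), function(a) {
    do.call(rbind, lapply(shell_radii * scale, function(r0) {
      sweep(sph * r0, 2, cloud$positions[a, ], `+`)
    }))
  }))
  keep <- vapply(seq_len(nrow(grid)), function(g) {
    min(sqrt(rowSums(sweep(cloud$positions, 2, grid[g, ], `-`)^2))) >=
      prune_radius
  }, logical(1))
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) <= n) {
    abort("ESP grid has fewer points than unknowns after pruning",
          class = "mpaspec_validation_error")
  }
  A <- matrix(0, nrow(grid), n)
  for (a in seq_len(n)) {
    A[, a] <- 1 / sqrt(rowSums(sweep(grid, 2, cloud$positions[a, ], `-`)^2))
  }
  if (qr(A)$rank < n) {
    abort("rank-deficient ESP design matrix (degenerate grid)",
          class = "mpaspec_validation_error")
  }
  b <- as.vector(A %*% cloud$charges)  # exact potential of the point cloud
  # KKT system for min |Aq - b|^2 subject to sum(q) = Q_tot
  K <- rbind(cbind(2 * crossprod(A), rep(1, n)),
             c(rep(1, n), 0))
  rhs <- c(2 * crossprod(A, b), sum(cloud$charges))
  sol <- solve(K, rhs)
  q <- sol[seq_len(n)]
  list(charges = q,
       rms_residual = sqrt(mean((A %*% q - b)^2)),
       grid = grid)
}

#' Hybrid exact/approximate electrostatic interaction
#'
#' Environment points within `r_exact` of the cloud centroid interact
#' exactly (pairwise Coulomb); points beyond interact through the chosen
#' approximation: a single-center multipole expansion of the cloud
#' (`"single_center"`) or ESP-fitted atom-centered charges (`"espf"`).
#' The partition is a disjoint cover of the environment; the energy is
#' continuous in the positions except exactly at the `r_exact` shell, where
#' the representation switches.
#'
#' @param cloud An `mpa_cloud`.
#' @param env Environment charges (data frame `x`, `y`, `z`, `q`).
#' @param r_exact Cutoff radius (bohr) from the cloud centroid.
#' @param scheme `"single_center"` or `"espf"`.
#' @param order Multipole order p for `"single_center"` (0-8).
#' @param ... Passed to [espf_fit()] for the `"espf"` scheme.
#' @return List `energy`, `forces` (n_env x 3), `assignment` tibble
#'   (`point`, `distance`, `method`).
#' @export
hybrid_interaction <- function(cloud, env, r_exact,
                               scheme = c("single_center", "espf"),
                               order = 4, ...) {
  scheme <- match.arg(scheme)
  if (r_exact < 0) {
    abort("r_exact must be >= 0", class = "mpaspec_validation_error")
  }
  ep <- as_env_points(env)
  dist <- sqrt(rowSums(sweep(ep$positions, 2, cloud$centroid, `-`)^2))
  near <- dist <= r_exact
  energy <- 0
  forces <- matrix(0, length(dist), 3)
  if (any(near)) {
    ex <- exact_interaction(cloud, tibble(x = ep$positions[near, 1],
                                          y = ep$positions[near, 2],
                                          z = ep$positions[near, 3],
                                          q = ep$charges[near]))
    energy <- energy + ex$energy
    forces[near, ] <- ex$forces
  }
  if (any(!near)) {
    far_pos <- ep$positions[!near, , drop = FALSE]
    far_q <- ep$charges[!near]
    if (scheme == "single_center") {
      mp <- multipole_expansion(cloud, order)
      energy <- energy + sum(far_q * multipole_potential(mp, far_pos))
      forces[!near, ] <- far_q * multipole_field(mp, far_pos)
    } else {
      fit <- espf_fit(cloud, ...)
      fit_cloud <- charge_cloud(cloud$positions, fit$charges)
      ap <- exact_interaction(fit_cloud,
                              tibble(x = far_pos[, 1], y = far_pos[, 2],
                                     z = far_pos[, 3], q = far_q))
      energy <- energy + ap$energy
      forces[!near, ] <- ap$forces
    }
  }
  list(energy = energy, forces = forces,
       assignment = tibble(point = seq_along(dist), distance = dist,
                           method = ifelse(near, "exact", scheme)))
}

#' Cutoff/order convergence scan against the exact reference
#'
#' For every combination of cutoff radius and multipole order, evaluates the
#' hybrid interaction and reports the absolute energy error and the absolute
#' error of the maximum Cartesian force component relative to the
#' no-approximation pairwise reference.
#'
#' @param cloud An `mpa_cloud`.
#' @param env Environment charges.
#' @param r_values Cutoff radii (bohr).
#' @param p_values Multipole orders.
#' @param scheme Approximation scheme beyond the cutoff.
#' @return An `mpa_error_scan` tibble: `r_exact`, `order`, `abs_dE`,
#'   `abs_dFmax` (a.u.).
#' @export
convergence_scan <- function(cloud, env, r_values, p_values,
                             scheme = "single_center") {
  if (!length(r_values) || !length(p_values)) {
    abort("empty scan lists", class = "mpaspec_validation_error")
  }
  ref <- exact_interaction(cloud, env)
  grid <- tidyr::expand_grid(r_exact = r_values, order = p_values)
  out <- purrr::pmap_dfr(grid, function(r_exact, order) {
    h <- hybrid_interaction(cloud, env, r_exact, scheme = scheme,
                            order = order)
    tibble(r_exact = r_exact, order = order,
           abs_dE = abs(h$energy - ref$energy),
           abs_dFmax = max(abs(h$forces - ref$forces)))
  })
  structure(out, class = c("mpa_error_scan", class(out)))
}

#' Read / write charge layouts as delimited text
#'
#' Tab-separated columns `x`, `y`, `z`, `q` in atomic units; `#` comments
#' ignored.
#'
#' @param path File path.
#' @param points Data frame with `x`, `y`, `z`, `q`.
#' @return `read_charges()`: a tibble; writers return `path` invisibly.
#' @export
read_charges <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("charge file not found: ", path), class = "mpaspec_io_error")
  }
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' @rdname read_charges
#' @export
write_charges <- function(points, path) {
  writeLines("# mpaspec charges; columns x y z q in atomic units", path)
  readr::write_tsv(as_tibble(points), path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}
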