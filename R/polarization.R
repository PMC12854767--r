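#' Polarizable site tables (atomic units)
#'
#' A polarizable-embedding environment is a table of atom-centered sites,
#' one row per site, all in atomic units: position (`x`, `y`, `z`, bohr),
#' permanent charge `q`, permanent dipole (`mux`, `muy`, `muz`), traceless
#' symmetric quadrupole (`qxx`, `qxy`, `qxz`, `qyy`, `qyz`, `qzz`),
#' symmetric polarizability (`axx`, `axy`, `axz`, `ayy`, `ayz`, `azz`) and
#' an integer `fragment` id. Pairs of sites within the same fragment do not
#' interact (neither static fields nor induced-dipole coupling) — the
#' standard exclusion of polarizable-embedding practice.
#'
#' `polarizable_sites()` validates/completes a data frame (missing multipole
#' or polarizability columns are filled with zeros; a scalar `alpha` column
#' expands to an isotropic tensor). Polarizabilities must be symmetric with
#' non-negative eigenvalues.
#'
#' @param sites A data frame with at least `x`, `y`, `z`, `q`.
#' @return A validated `mpa_sites` tibble.
#' @export
polarizable_sites <- function(sites) {
  sites <- as_tibble(sites)
  needed <- c("x", "y", "z", "q")
  if (!all(needed %in% names(sites))) {
    abort("sites need columns x, y, z, q", class = "mpaspec_validation_error")
  }
  zero_cols <- c("mux", "muy", "muz", "qxx", "qxy", "qxz", "qyy", "qyz",
                 "qzz", "axx", "axy", "axz", "ayy", "ayz", "azz")
  if ("alpha" %in% names(sites)) {
    sites$axx <- sites$ayy <- sites$azz <- sites$alpha
    sites$alpha <- NULL
  }
  for (cl in zero_cols) if (!cl %in% names(sites)) sites[[cl]] <- 0
  if (!"fragment" %in% names(sites)) sites$fragment <- seq_len(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    a <- site_alpha(sites, i)
    ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < -1e-12)) {
      abort("polarizability tensors must have non-negative eigenvalues",
            class = "mpaspec_validation_error")
    }
  }
  pos <- as.matrix(sites[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  if (any(d == 0)) {
    abort("coincident polarizable sites", class = "mpaspec_validation_error")
  }
  structure(sites, class = c("mpa_sites", class(sites)))
}

site_alpha <- function(sites, i) {
  matrix(c(sites$axx[i], sites$axy[i], sites$axz[i],
           sites$axy[i], sites$ayy[i], sites$ayz[i],
           sites$axz[i], sites$ayz[i], sites$azz[i]), 3, 3)
}

site_quad <- function(sites, i) {
  matrix(c(sites$qxx[i], sites$qxy[i], sites$qxz[i],
           sites$qxy[i], sites$qyy[i], sites$qyz[i],
           sites$qxz[i], sites$qyz[i], sites$qzz[i]), 3, 3)
}

# field at point r from one site at r0: charge + dipole + traceless
# quadrupole terms, a.u.
site_field_at <- function(r, r0, q, mu, Q) {
  d <- r - r0
  r2 <- sum(d^2)
  if (r2 == 0) {
    abort("field evaluation point coincides with a site",
          class = "mpaspec_validation_error")
  }
  rn <- sqrt(r2)
  f <- q * d / rn^3
  if (any(mu != 0)) {
    f <- f + (3 * sum(mu * d) * d / rn^5 - mu / rn^3)
  }
  if (any(Q != 0)) {
    Qd <- as.vector(Q %*% d)
    f <- f + (5 / 2) * sum(d * Qd) * d / rn^7 - Qd / rn^5
  }
  f
}

#' Static multipole field of a site table
#'
#' Sum of charge, dipole and quadrupole fields of the permanent site
#' multipoles. When evaluated at the sites themselves (`at = NULL`), the
#' self term and all same-fragment contributions are excluded; at external
#' points every site contributes.
#'
#' @param sites An `mpa_sites` table.
#' @param at Optional m x 3 matrix of evaluation points (bohr); default:
#'   the site positions with intra-fragment exclusion.
#' @return m x 3 matrix of field vectors (a.u.).
#' @export
static_field <- function(sites, at = NULL) {
  sites <- polarizable_sites(sites)
  pos <- as.matrix(sites[, c("x", "y", "z")])
  at_sites <- is.null(at)
  pts <- if (at_sites) pos else rbind(at)
  out <- matrix(0, nrow(pts), 3)
  for (j in seq_len(nrow(pts))) {
    for (i in seq_len(nrow(sites))) {
      if (at_sites && sites$fragment[i] == sites$fragment[j]) next
      out[j, ] <- out[j, ] + site_field_at(
        pts[j, ], pos[i, ], sites$q[i],
        c(sites$mux[i], sites$muy[i], sites$muz[i]), site_quad(sites, i))
    }
  }
  out
}

# dipole-dipole interaction tensor T_ab = (3 rr^T - r^2 I) / r^5
dipole_tensor <- function(d) {
  r2 <- sum(d^2)
  (3 * outer(d, d) - r2 * diag(3)) / r2^2.5
}

#' Self-consistent induced dipoles
#'
#' Solves the coupled induced-dipole equations \eqn{\mu_a = \alpha_a
#' (F^{ext}_a + F^{static}_a + \sum_{b \ne a} T_{ab} \mu_b)} with
#' intra-fragment interactions excluded. Sites up to `direct_max` are solved
#' by a dense linear solve of the 3N x 3N system; larger systems (or
#' `method = "iterative"`) use damped-free fixed-point iteration to the
#' residual tolerance. A diverging iteration (polarization catastrophe) is
#' reported as an error together with an estimate of the spectral radius of
#' the \eqn{\alpha T} iteration matrix.
#'
#' No Thole-style damping is applied: close, highly polarizable site pairs
#' that are physically unstable surface as a diagnosed error rather than
#' being masked.
#'
#' @param sites An `mpa_sites` table.
#' @param external_field Either a single field vector (applied to every
#'   site), an n x 3 matrix, or NULL (zero external field).
#' @param method `"auto"` (direct for <= `direct_max` sites), `"direct"`,
#'   or `"iterative"`.
#' @param tol Residual tolerance (a.u.) for the iterative path and the
#'   staleness check, default 1e-8.
#' @param max_iter Iteration cap.
#' @param direct_max Largest site count solved directly.
#' @return An `mpa_polarization` list: `induced` (n x 3), `energy`
#'   (induction energy, hartree), `iterations`, `residual`,
#'   `permanent_field`.
#' @export
solve_induced <- function(sites, external_field = NULL,
                          method = c("auto", "direct", "iterative"),
                          tol = 1e-8, max_iter = 500, direct_max = 3000) {
  method <- match.arg(method)
  sites <- polarizable_sites(sites)
  n <- nrow(sites)
  pos <- as.matrix(sites[, c("x", "y", "z")])
  f_ext <- if (is.null(external_field)) matrix(0, n, 3)
    else if (is.matrix(external_field)) external_field
    else matrix(external_field, n, 3, byrow = TRUE)
  f_perm <- f_ext + static_field(sites)
  alphas <- lapply(seq_len(n), function(i) site_alpha(sites, i))
  # interaction blocks, zero within a fragment
  Tblocks <- vector("list", n * n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    Tblocks[[(a - 1) * n + b]] <-
      if (a == b || sites$fragment[a] == sites$fragment[b]) matrix(0, 3, 3)
      else dipole_tensor(pos[a, ] - pos[b, ])
  }
  apply_T <- function(mu) {
    out <- matrix(0, n, 3)
    for (a in seq_len(n)) {
      acc <- numeric(3)
      for (b in seq_len(n)) {
        acc <- acc + Tblocks[[(a - 1) * n + b]] %*% mu[b, ]
      }
      out[a, ] <- acc
    }
    out
  }
  residual_of <- function(mu) {
    ftot <- f_perm + apply_T(mu)
    tgt <- t(vapply(seq_len(n), function(a) as.vector(alphas[[a]] %*% ftot[a, ]),
                    numeric(3)))
    max(abs(mu - tgt))
  }
  use_direct <- method == "direct" || (method == "auto" && n <= direct_max)
  if (use_direct) {
    # (I - A T) mu = A f_perm, A = blockdiag(alpha)
    AT <- matrix(0, 3 * n, 3 * n)
    rhs <- numeric(3 * n)
    for (a in seq_len(n)) {
      ia <- (3 * (a - 1) + 1):(3 * a)
      rhs[ia] <- alphas[[a]] %*% f_perm[a, ]
      for (b in seq_len(n)) {
        ib <- (3 * (b - 1) + 1):(3 * b)
        AT[ia, ib] <- alphas[[a]] %*% Tblocks[[(a - 1) * n + b]]
      }
    }
    mu <- matrix(solve(diag(3 * n) - AT, rhs), n, 3, byrow = TRUE)
    iters <- 0L
    res <- residual_of(mu)
  } else {
    mu <- matrix(0, n, 3)
    res <- Inf
    iters <- 0L
    prev <- Inf
    while (iters < max_iter) {
      iters <- iters + 1L
      ftot <- f_perm + apply_T(mu)
      mu_new <- t(vapply(seq_len(n),
                         function(a) as.vector(alphas[[a]] %*% ftot[a, ]),
                         numeric(3)))
      res <- max(abs(mu_new - mu))
      mu <- mu_new
      if (!is.finite(res)) break
      if (res < tol) break
      if (res > 10 * prev && iters > 3L) break
      prev <- res
    }
    if (!is.finite(res) || res >= tol) {
      rho <- estimate_spectral_radius(alphas, Tblocks, n)
      abort(sprintf(paste0("induced-dipole iteration did not converge ",
                           "(residual %.3g); spectral radius of alpha*T ",
                           "approximately %.3f >= 1 indicates a polarization ",
                           "catastrophe"), res, rho),
            class = "mpaspec_polarization_error")
    }
  }
  energy <- -0.5 * sum(mu * f_perm)
  structure(list(induced = mu, energy = energy, iterations = iters,
                 residual = res, permanent_field = f_perm),
            class = "mpa_polarization")
}

estimate_spectral_radius <- function(alphas, Tblocks, n, iters = 30) {
  v <- matrix(1, n, 3) / sqrt(3 * n)
  lam <- 0
  for (k in seq_len(iters)) {
    w <- matrix(0, n, 3)
    for (a in seq_len(n)) {
      acc <- numeric(3)
      for (b in seq_len(n)) {
        acc <- acc + Tblocks[[(a - 1) * n + b]] %*% v[b, ]
      }
      w[a, ] <- alphas[[a]] %*% acc
    }
    lam <- sqrt(sum(w^2))
    if (lam == 0) return(0)
    v <- w / lam
  }
  lam
}

#' @export
print.mpa_polarization <- function(x, ...) {
  cat(sprintf(paste0("mpa_polarization: %d sites, induction energy %.8g ",
                     "hartree (residual %.2g, %d iterations)\n"),
              nrow(x$induced), x$energy, x$residual, x$iterations))
  invisible(x)
}

#' Induction energy of a converged polarization solution
#'
#' \eqn{U_{ind} = -\tfrac{1}{2} \sum_a \mu_a \cdot F^{perm}_a} over the
#' permanent (external + static) fields — the standard classical induction
#' energy contract. Refuses stale solutions whose residual exceeds the
#' tolerance.
#'
#' @param solution An `mpa_polarization`.
#' @param tol Staleness tolerance on the stored residual.
#' @return Energy in hartree (<= 0 for PSD polarizabilities in a purely
#'   external field).
#' @export
induction_energy <- function(solution, tol = 1e-6) {
  if (solution$residual > tol) {
    abort("stale polarization solution: residual above tolerance",
          class = "mpaspec_validation_error")
  }
  -0.5 * sum(solution$induced * solution$permanent_field)
}

#' Read / write polarizable-site potential files
#'
#' A minimal tab-separated "potential file" dialect: one row per site with
#' the 20 columns documented in [polarizable_sites()] (position, charge,
#' dipole, 6 quadrupole components, 6 polarizability components, fragment).
#'
#' @param path File path.
#' @param sites An `mpa_sites` table.
#' @return `read_sites()`: a validated `mpa_sites` tibble; the writer
#'   returns `path` invisibly.
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("site file not found: ", path), class = "mpaspec_io_error")
  }
  polarizable_sites(readr::read_tsv(path, comment = "#",
                                    show_col_types = FALSE, progress = FALSE))
}

#' @rdname read_sites
#' @export
write_sites <- function(sites, path) {
  writeLines("# mpaspec polarizable sites; atomic units", path)
  readr::write_tsv(as_tibble(sites), path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}
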