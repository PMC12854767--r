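#' Default per-state ensemble parameters
#'
#' Stationary means and spreads of the per-snapshot excited-state
#' observables for the synthetic ensemble generator. State means follow the
#' one-photon peak positions of the chromophore study conditions (2.81 and
#' 4.13 eV for the two bright states, plus a weak third state); spreads and
#' transition strengths are chosen to give realistic band widths and
#' cross-section magnitudes (first TPA band a few hundred GM).
#'
#' @return Tibble with one row per state: `state`, `mean_energy_eV`,
#'   `sd_energy_eV`, `mean_fosc`, `sd_fosc`, `mean_tpa_au`, `sd_tpa_au`,
#'   `mean_3pa_au`, `sd_3pa_au`.
#' @export
default_state_params <- function() {
  tibble(
    state = 1:3,
    mean_energy_eV = c(2.81, 4.13, 4.90),
    sd_energy_eV   = c(0.15, 0.15, 0.20),
    mean_fosc      = c(1.00, 0.35, 0.10),
    sd_fosc        = c(0.10, 0.05, 0.03),
    mean_tpa_au    = c(3.0e4, 6.5e4, 1.0e4),
    sd_tpa_au      = c(5.0e3, 1.0e4, 3.0e3),
    mean_3pa_au    = c(5.0e5, 2.0e7, 5.0e6),
    sd_3pa_au      = c(1.0e5, 5.0e6, 1.0e6)
  )
}

ar1_series <- function(n, mean, sd, phi) {
  if (sd == 0) return(rep(mean, n))
  x <- numeric(n)
  x[1] <- mean + sd * rnorm(1)
  innov_sd <- sd * sqrt(1 - phi^2)
  if (n >= 2) {
    for (t in 2:n) {
      x[t] <- mean + phi * (x[t - 1] - mean) + innov_sd * rnorm(1)
    }
  }
  x
}

#' Generate a temporally correlated excited-state ensemble
#'
#' Every observable (per state: excitation energy, oscillator strength,
#' two- and three-photon transition strengths) follows an independent
#' stationary first-order autoregressive process with the configured
#' stationary mean/sd and lag-1 coefficient \eqn{\exp(-\Delta t/\tau)} —
#' the minimal stationary process with the fast-decaying exponential
#' autocorrelation seen in the underlying trajectories. Strengths are
#' truncated at zero after generation.
#'
#' @param n_snapshots Number of snapshots.
#' @param dt_fs Snapshot spacing in fs.
#' @param state_params Per-state parameter tibble, see
#'   [default_state_params()].
#' @param correlation_time_fs AR decay time tau in fs.
#' @param chromophore Label attached to every record.
#' @param seed Integer seed; all randomness flows from it.
#' @return List `records` (snapshot record tibble) and `truth` (generating
#'   parameters, machine-readable sidecar).
#' @export
make_ensemble <- function(n_snapshots = 200, dt_fs = 200,
                          state_params = default_state_params(),
                          correlation_time_fs = 15,
                          chromophore = "LYR-472", seed = 1) {
  if (n_snapshots < 1 || dt_fs <= 0 || correlation_time_fs <= 0 ||
      any(state_params$mean_energy_eV <= 0) ||
      any(unlist(state_params[grep("^sd_", names(state_params))]) < 0)) {
    abort("invalid ensemble configuration",
          class = "mpaspec_validation_error")
  }
  phi <- exp(-dt_fs / correlation_time_fs)
  records <- withr::with_seed(seed, {
    purrr::pmap_dfr(state_params, function(state, mean_energy_eV,
                                           sd_energy_eV, mean_fosc, sd_fosc,
                                           mean_tpa_au, sd_tpa_au,
                                           mean_3pa_au, sd_3pa_au) {
      tibble(
        snapshot = seq_len(n_snapshots),
        time_fs = (seq_len(n_snapshots) - 1) * dt_fs,
        chromophore = chromophore,
        state = state,
        energy_eV = pmax(ar1_series(n_snapshots, mean_energy_eV,
                                    sd_energy_eV, phi), 1e-6),
        fosc = pmax(ar1_series(n_snapshots, mean_fosc, sd_fosc, phi), 0),
        delta_tpa_au = pmax(ar1_series(n_snapshots, mean_tpa_au, sd_tpa_au,
                                       phi), 0),
        delta_3pa_au = pmax(ar1_series(n_snapshots, mean_3pa_au, sd_3pa_au,
                                       phi), 0)
      )
    })
  }) |> dplyr::arrange(.data$snapshot, .data$state)
  truth <- list(generator = "make_ensemble", n_snapshots = n_snapshots,
                dt_fs = dt_fs, correlation_time_fs = correlation_time_fs,
                lag1_coefficient = phi, seed = seed,
                state_params = state_params)
  list(records = validate_records(records), truth = truth)
}

# place atom D given A, B, C, bond length |CD|, angle B-C-D (deg) and
# torsion A-B-C-D (deg): the standard internal-coordinate (NeRF) step.
place_atom <- function(A, B, C, length, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- length * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

wrap_angle <- function(theta) {
  w <- (theta + 180) %% 360 - 180
  ifelse(w == -180, 180, w)
}

#' Build a retinal-like conjugated chain trajectory with known geometry
#'
#' Constructs, frame by frame, a 13-atom backbone chain by
#' internal-coordinate placement: per-frame sampled bond lengths
#' (alternating double/single along the conjugation path), fixed 120 degree
#' bond angles, and per-frame sampled dihedrals about each of the ten
#' conjugation bonds. Thirteen backbone atoms carry twelve consecutive
#' bonds; bonds 2-11 form the five double (pi) / five single (sigma)
#' conjugation path and each has a well-defined dihedral whose central pair
#' is that bond, with the two terminal bonds acting as caps. The exact
#' sampled lengths and dihedrals are recorded per frame in the ground-truth
#' sidecar.
#'
#' @param n_frames Number of frames.
#' @param dt_fs Frame spacing in fs.
#' @param sigma_length,pi_length Mean single-/double-bond lengths
#'   (Angstrom).
#' @param bond_sd Bond-length spread (Angstrom).
#' @param dihedral_mean,dihedral_sd Dihedral mean and spread (degrees);
#'   sampled values are wrapped to (-180, 180].
#' @param bond_angle Backbone angle in degrees (default 120).
#' @param seed Integer seed.
#' @return List `trajectory` (`mpa_trajectory`), `topology`
#'   (`mpa_topology`), `truth` (tibble of per-frame sigma/pi lengths,
#'   dihedrals, `bla_true`, `planarity_true`).
#' @export
make_chain_trajectory <- function(n_frames = 200, dt_fs = 200,
                                  sigma_length = 1.46, pi_length = 1.36,
                                  bond_sd = 0.01, dihedral_mean = 180,
                                  dihedral_sd = 10, bond_angle = 120,
                                  seed = 1) {
  if (sigma_length <= 0 || pi_length <= 0 || bond_sd < 0 ||
      dihedral_sd < 0 || n_frames < 1) {
    abort("invalid chain configuration", class = "mpaspec_validation_error")
  }
  n_atoms <- 13L
  cap_len <- 1.45
  # bonds 2..11 alternate pi, sigma, pi, sigma, ...
  conj_bonds <- 2:11
  is_pi <- (conj_bonds %% 2) == 0
  topo <- new_topology(
    sigma_bonds = cbind(conj_bonds[!is_pi], conj_bonds[!is_pi] + 1L),
    pi_bonds = cbind(conj_bonds[is_pi], conj_bonds[is_pi] + 1L),
    dihedrals = cbind(conj_bonds - 1L, conj_bonds, conj_bonds + 1L,
                      conj_bonds + 2L),
    n_atoms = n_atoms
  )
  res <- withr::with_seed(seed, {
    coords <- array(NA_real_, c(n_atoms, 3, n_frames))
    truth <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      lengths <- numeric(12)
      lengths[1] <- cap_len; lengths[12] <- cap_len
      lengths[conj_bonds] <- ifelse(is_pi, pi_length, sigma_length) +
        (if (bond_sd > 0) rnorm(10, 0, bond_sd) else 0)
      if (any(lengths <= 0)) {
        abort("sampled non-positive bond length: reduce bond_sd",
              class = "mpaspec_validation_error")
      }
      torsions <- wrap_angle(dihedral_mean +
                               (if (dihedral_sd > 0) rnorm(10, 0, dihedral_sd)
                                else rep(0, 10)))
      fr <- matrix(0, n_atoms, 3)
      fr[2, ] <- c(lengths[1], 0, 0)
      a2 <- (180 - bond_angle) * pi / 180
      fr[3, ] <- fr[2, ] + lengths[2] * c(cos(a2), sin(a2), 0)
      for (k in 4:n_atoms) {
        fr[k, ] <- place_atom(fr[k - 3, ], fr[k - 2, ], fr[k - 1, ],
                              lengths[k - 1], bond_angle, torsions[k - 3])
      }
      coords[, , f] <- fr
      truth[[f]] <- tibble(
        frame = f,
        sigma_true = list(lengths[conj_bonds][!is_pi]),
        pi_true = list(lengths[conj_bonds][is_pi]),
        theta_true = list(torsions),
        bla_true = (sum(lengths[conj_bonds][!is_pi]) -
                      sum(lengths[conj_bonds][is_pi])) / 5,
        planarity_true = sum(planarity_component(torsions))
      )
    }
    list(coords = coords, truth = dplyr::bind_rows(truth))
  })
  elements <- c(rep("C", n_atoms - 1L), "N")
  traj <- new_trajectory(elements, res$coords,
                         (seq_len(n_frames) - 1) * dt_fs)
  truth <- dplyr::mutate(res$truth,
                         time_fs = (seq_len(n_frames) - 1) * dt_fs)
  list(trajectory = traj, topology = topo, truth = truth)
}

#' Structure-coupled synthetic dataset
#'
#' Couples a synthetic chain trajectory to per-snapshot first excitation
#' energies via the linear model \eqn{E_1 = c_0 + c_{bla}\,BLA_t +
#' c_{pl}\,(10 - P_t) + \epsilon}: with both coefficients positive, lower
#' bond-length alternation and higher planarity give lower excitation
#' energies. The sidecar stores the exact coefficients and the per-frame
#' true descriptors.
#'
#' @inheritParams make_chain_trajectory
#' @param c0 Baseline energy (eV).
#' @param c_bla Energy per unit BLA (eV/Angstrom), > 0 for the
#'   lower-BLA/lower-energy trend.
#' @param c_planarity Energy per unit of twist 10 - P (eV), > 0 for the
#'   more-planar/lower-energy trend.
#' @param noise_sd Gaussian noise on the energy (eV).
#' @param mean_fosc,mean_tpa_au,mean_3pa_au State-1 strength means.
#' @return List `trajectory`, `topology`, `records`, `truth`.
#' @export
make_coupled_dataset <- function(n_frames = 200, dt_fs = 200,
                                 c0 = 2.30, c_bla = 4.0, c_planarity = 0.04,
                                 noise_sd = 0.05,
                                 sigma_length = 1.46, pi_length = 1.36,
                                 bond_sd = 0.02, dihedral_mean = 180,
                                 dihedral_sd = 12,
                                 mean_fosc = 1.0, mean_tpa_au = 3.0e4,
                                 mean_3pa_au = 5.0e5, seed = 1) {
  chain <- make_chain_trajectory(n_frames = n_frames, dt_fs = dt_fs,
                                 sigma_length = sigma_length,
                                 pi_length = pi_length, bond_sd = bond_sd,
                                 dihedral_mean = dihedral_mean,
                                 dihedral_sd = dihedral_sd, seed = seed)
  records <- withr::with_seed(seed + 1L, {
    e1 <- c0 + c_bla * chain$truth$bla_true +
      c_planarity * (10 - chain$truth$planarity_true) +
      (if (noise_sd > 0) rnorm(n_frames, 0, noise_sd) else 0)
    tibble(
      snapshot = seq_len(n_frames),
      time_fs = chain$truth$time_fs,
      chromophore = "SYN-CHAIN",
      state = 1L,
      energy_eV = pmax(e1, 1e-6),
      fosc = pmax(mean_fosc + rnorm(n_frames, 0, 0.05 * mean_fosc), 0),
      delta_tpa_au = pmax(mean_tpa_au +
                            rnorm(n_frames, 0, 0.1 * mean_tpa_au), 0),
      delta_3pa_au = pmax(mean_3pa_au +
                            rnorm(n_frames, 0, 0.1 * mean_3pa_au), 0)
    )
  })
  truth <- c(list(generator = "make_coupled_dataset", c0 = c0,
                  c_bla = c_bla, c_planarity = c_planarity,
                  noise_sd = noise_sd, seed = seed),
             list(frames = chain$truth))
  list(trajectory = chain$trajectory, topology = chain$topology,
       records = validate_records(records), truth = truth)
}

#' Random point-charge cloud
#'
#' Uniform positions in a cube of the given edge, centred at the origin;
#' charges uniform in (-1, 1) then shifted so the total equals `net_charge`
#' exactly.
#'
#' @param n Number of charges (>= 1).
#' @param extent Cube edge length (bohr).
#' @param net_charge Exact total charge (e).
#' @param seed Integer seed.
#' @return An `mpa_cloud`.
#' @export
make_charge_cloud <- function(n, extent = 4, net_charge = 0, seed = 1) {
  if (n < 1) abort("n must be >= 1", class = "mpaspec_validation_error")
  withr::with_seed(seed, {
    pos <- matrix(runif(3 * n, -extent / 2, extent / 2), n, 3)
    q <- runif(n, -1, 1)
    q <- q - mean(q) + net_charge / n
    charge_cloud(pos, q)
  })
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Random water-like polarizable-site layout
#'
#' `n_fragments` charge-neutral three-site fragments (one O-like and two
#' H-like sites at the water geometry: O-H 1.81 bohr, 104.5 degrees) at
#' random, non-overlapping positions and orientations, with isotropic
#' polarizabilities (O 5.7, H 2.7 a.u.) and small random permanent dipoles
#' to exercise the dipole field terms.
#'
#' @param n_fragments Number of fragments (>= 1).
#' @param min_separation Minimum distance between fragment centres (bohr).
#' @param seed Integer seed.
#' @return An `mpa_sites` tibble of `3 * n_fragments` rows.
#' @export
make_sites <- function(n_fragments, min_separation = 5.5, seed = 1) {
  if (n_fragments < 1) {
    abort("n_fragments must be >= 1", class = "mpaspec_validation_error")
  }
  withr::with_seed(seed, {
    box <- max(8, ceiling(n_fragments^(1 / 3)) * (min_separation + 2))
    centers <- matrix(NA_real_, n_fragments, 3)
    placed <- 0L; tries <- 0L
    while (placed < n_fragments && tries < 10000L) {
      tries <- tries + 1L
      cand <- runif(3, -box / 2, box / 2)
      ok <- placed == 0L ||
        min(sqrt(rowSums(sweep(centers[seq_len(placed), , drop = FALSE], 2,
                               cand, `-`)^2))) >= min_separation
      if (ok) { placed <- placed + 1L; centers[placed, ] <- cand }
    }
    if (placed < n_fragments) {
      abort("could not place fragments: reduce n_fragments or separation",
            class = "mpaspec_validation_error")
    }
    half <- 104.5 / 2 * pi / 180
    local_geom <- rbind(c(0, 0, 0),
                        1.81 * c(sin(half), 0, cos(half)),
                        1.81 * c(-sin(half), 0, cos(half)))
    rows <- purrr::map_dfr(seq_len(n_fragments), function(fr) {
      R <- random_rotation()
      pos <- sweep(local_geom %*% t(R), 2, centers[fr, ], `+`)
      mu_o <- 0.05 * rnorm(3)
      tibble(x = pos[, 1], y = pos[, 2], z = pos[, 3],
             q = c(-0.834, 0.417, 0.417),
             mux = c(mu_o[1], 0, 0), muy = c(mu_o[2], 0, 0),
             muz = c(mu_o[3], 0, 0),
             alpha = c(5.7, 2.7, 2.7),
             fragment = fr)
    })
    polarizable_sites(rows)
  })
}

#' Write a ground-truth sidecar as JSON
#'
#' Serialises a generator's `truth` component (parameters and, where
#' present, per-frame true descriptors) so downstream recovery tests can
#' read the generating values without touching the generator internals.
#'
#' @param truth A `truth` list or tibble from a generator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_sidecar <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
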