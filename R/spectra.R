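#' Unit-area Lorentzian lineshape
#'
#' \eqn{g(x; x_0, \gamma) = (1/\pi)\,\gamma / ((x - x_0)^2 + \gamma^2)},
#' the normalized Lorentzian with half-width at half-maximum `gamma`,
#' expressed per unit of whatever `x` is measured in.
#'
#' @param x Evaluation points.
#' @param x0 Line center (same units as `x`).
#' @param gamma HWHM, > 0 (same units as `x`).
#' @return Density values, units 1/\[x\].
#' @examples
#' lorentzian(2.81, 2.81, 0.1)  # peak = 1 / (0.1 * pi)
#' @export
lorentzian <- function(x, x0, gamma) {
  if (any(!is.finite(gamma)) || any(gamma <= 0)) {
    abort("gamma (HWHM) must be finite and > 0",
          class = "mpaspec_validation_error")
  }
  (gamma / pi) / ((x - x0)^2 + gamma^2)
}

new_spectrum <- function(grid, intensity, process, units, gamma,
                         n_snapshots, refractive_index = 1) {
  out <- tibble(energy_eV = grid, intensity = intensity)
  structure(out,
            class = c("mpa_spectrum", class(out)),
            process = process, units = units, gamma = gamma,
            n_snapshots = n_snapshots, refractive_index = refractive_index)
}

check_grid <- function(grid) {
  if (length(grid) < 2L || any(!is.finite(grid)) || any(diff(grid) <= 0)) {
    abort("grid must be a finite, strictly increasing energy axis (eV)",
          class = "mpaspec_validation_error")
  }
  grid
}

# gamma may be scalar or per-state vector (indexed by state number)
gamma_for_state <- function(gamma, state) {
  if (length(gamma) == 1L) rep(gamma, length(state)) else gamma[state]
}

# Shared ensemble loop: mean over snapshots of the per-snapshot state sum.
# state_term(energy_i, strength_i, gamma_i) must return a grid-length vector.
ensemble_mean_spectrum <- function(records, grid, state_term) {
  records <- validate_records(records)
  keys <- dplyr::distinct(records, .data$snapshot, .data$chromophore)
  acc <- numeric(length(grid))
  for (k in seq_len(nrow(keys))) {
    snap <- records[records$snapshot == keys$snapshot[k] &
                      records$chromophore == keys$chromophore[k], ]
    per_snap <- numeric(length(grid))
    for (i in seq_len(nrow(snap))) {
      per_snap <- per_snap + state_term(snap[i, ])
    }
    acc <- acc + per_snap
  }
  list(intensity = acc / nrow(keys), n = nrow(keys))
}

#' One-photon molar absorption spectrum
#'
#' Assembles the ensemble-averaged molar absorption coefficient
#' \eqn{\epsilon(\omega)} on a photon-energy grid. Per snapshot the state sum
#' is \eqn{(e^2 \pi N_A) / (2 \ln 10\, \epsilon_0 n m_e c) \sum_i
#' (\omega/\omega_i) f_i\, g(\omega; \omega_i, \gamma_i)} with a unit-area
#' Lorentzian `g` per angular frequency; the ensemble spectrum is the
#' arithmetic mean over snapshots, so intensity is per chromophore and
#' independent of ensemble size. The SI result (m^2/mol) is converted to
#' L mol^-1 cm^-1 by the factor 10 (1 m^2/mol = 1e4 cm^2/mol =
#' 10 L mol^-1 cm^-1).
#'
#' The \eqn{(\omega/\omega_i) f_i} weighting is one of two readings of the
#' conventional formula; it is the one adopted here (see the package
#' vignette) and reduces to plain \eqn{f_i} at the line center.
#'
#' @param records A snapshot record table (see [snapshot_records]).
#' @param grid Photon-energy axis in eV, strictly increasing.
#' @param gamma Lorentzian HWHM in eV; scalar or per-state vector.
#' @param refractive_index Medium refractive index n (default 1).
#' @return An `mpa_spectrum` tibble (`energy_eV`, `intensity` in
#'   L mol^-1 cm^-1) with process/units metadata attributes.
#' @export
opa_spectrum <- function(records, grid = default_grid(), gamma = 0.1,
                         refractive_index = 1) {
  check_grid(grid)
  const <- fundamental_constants()
  pref_si <- const$elementary_charge^2 * pi * const$avogadro /
    (2 * log(10) * const$vacuum_permittivity * refractive_index *
       const$electron_mass * const$speed_of_light)
  # pref_si has units m^2/(s mol) against a per-angular-frequency lineshape;
  # with g in 1/eV the lineshape conversion is hbar/e (eV s), and the final
  # factor 10 converts m^2/mol to L mol^-1 cm^-1.
  scale <- 10 * pref_si * const$hbar / const$elementary_charge
  res <- ensemble_mean_spectrum(records, grid, function(st) {
    g <- gamma_for_state(gamma, st$state)
    scale * (grid / st$energy_eV) * st$fosc *
      lorentzian(grid, st$energy_eV, g)
  })
  new_spectrum(grid, res$intensity, "OPA", "L mol-1 cm-1", gamma, res$n,
               refractive_index)
}

#' Two-photon absorption spectrum in Goeppert-Mayer units
#'
#' Assembles the ensemble-averaged two-photon cross section
#' \eqn{\sigma^{TPA}(\omega) = k_{TPA} \sum_i \omega^2\, \delta_i^{TPA}\,
#' g(2\omega; \omega_i, \gamma_i)} with every factor in atomic units and
#' \eqn{k_{TPA}} the frozen conversion constant of [mpa_constants()]
#' (about 2.50547e-2 GM per atomic-unit sum). The grid is the photon
#' energy, so an isolated state peaks near \eqn{\omega_i / 2}.
#'
#' @inheritParams opa_spectrum
#' @return An `mpa_spectrum` tibble with intensity in GM.
#' @export
tpa_spectrum <- function(records, grid = default_grid(), gamma = 0.1) {
  check_grid(grid)
  w_au <- ev_to_au(grid)
  res <- ensemble_mean_spectrum(records, grid, function(st) {
    g_au <- ev_to_au(gamma_for_state(gamma, st$state))
    .k_tpa * w_au^2 * st$delta_tpa_au *
      lorentzian(2 * w_au, ev_to_au(st$energy_eV), g_au)
  })
  new_spectrum(grid, res$intensity, "TPA", "GM", gamma, res$n)
}

#' Three-photon absorption spectrum
#'
#' Assembles \eqn{\sigma^{3PA}(\omega) = k_{3PA} \sum_i \omega^3\,
#' \delta_i^{3PA}\, g(3\omega; \omega_i, \gamma_i)} in atomic units with
#' \eqn{k_{3PA}} from [mpa_constants()] (about 7.78131e-7); intensities are
#' reported on the conventional scale of 1e-80 cm^6 s^2 / photon^2, i.e.
#' the numeric values pair directly with the 7.78e-7 prefactor. An isolated
#' state peaks near \eqn{\omega_i / 3} photon energy.
#'
#' @inheritParams opa_spectrum
#' @return An `mpa_spectrum` tibble with intensity in
#'   1e-80 cm^6 s^2 photon^-2.
#' @export
threepa_spectrum <- function(records, grid = default_grid(), gamma = 0.1) {
  check_grid(grid)
  w_au <- ev_to_au(grid)
  res <- ensemble_mean_spectrum(records, grid, function(st) {
    g_au <- ev_to_au(gamma_for_state(gamma, st$state))
    .k_3pa * w_au^3 * st$delta_3pa_au *
      lorentzian(3 * w_au, ev_to_au(st$energy_eV), g_au)
  })
  new_spectrum(grid, res$intensity, "3PA", "1e-80 cm6 s2 photon-2", gamma,
               res$n)
}

#' Default photon-energy grid
#'
#' 0.002 to 6 eV in 0.002 eV steps (zero excluded: cross sections carry
#' positive powers of the photon energy).
#' @return Numeric vector of energies in eV.
#' @export
default_grid <- function() seq(0.002, 6, by = 0.002)

#' @export
print.mpa_spectrum <- function(x, ...) {
  cat(sprintf("# %s spectrum [%s]; gamma = %s eV; N = %d snapshots\n",
              attr(x, "process"), attr(x, "units"),
              paste(signif(attr(x, "gamma"), 4), collapse = ","),
              attr(x, "n_snapshots")))
  NextMethod()
}
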