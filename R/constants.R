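#' Fundamental physical constants (CODATA 2018, SI)
#'
#' The named set of fundamental constants used throughout the package for
#' unit conversion. Exact SI defining constants are exact; derived quantities
#' (Bohr radius, Hartree energy, atomic time) carry CODATA 2018 precision.
#'
#' @return A named list with elements `elementary_charge` (C),
#'   `electron_mass` (kg), `speed_of_light` (m/s), `vacuum_permittivity`
#'   (F/m), `avogadro` (1/mol), `hbar` (J s), `fine_structure`
#'   (dimensionless), `bohr_radius` (m), `hartree_J` (J), `hartree_eV` (eV),
#'   `atomic_time_s` (s).
#' @examples
#' fundamental_constants()$hartree_eV
#' @export
fundamental_constants <- function() {
  list(
    elementary_charge   = 1.602176634e-19,    # C, exact
    electron_mass       = 9.1093837015e-31,   # kg
    speed_of_light      = 2.99792458e8,       # m/s, exact
    vacuum_permittivity = 8.8541878128e-12,   # F/m
    avogadro            = 6.02214076e23,      # 1/mol, exact
    hbar                = 1.054571817e-34,    # J s, exact (h/2pi)
    fine_structure      = 7.2973525693e-3,
    bohr_radius         = 5.29177210903e-11,  # m
    hartree_J           = 4.3597447222071e-18,
    hartree_eV          = 27.211386245988,
    atomic_time_s       = 2.4188843265857e-17
  )
}

#' Derive the multiphoton cross-section conversion constants
#'
#' Computes, from fundamental constants alone, the numeric factors that turn
#' the atomic-unit sums over states into physical cross-section units:
#'
#' * `k_tpa`: multiplies \eqn{\sum_i \omega^2 \delta_i^{TPA} g(2\omega)}
#'   (everything in atomic units) to give the two-photon cross section in
#'   Goeppert-Mayer units (1 GM = 1e-50 cm^4 s / photon). Closed form
#'   \eqn{8\pi^3 \alpha a_0^5 / c} expressed in GM.
#' * `k_3pa`: multiplies \eqn{\sum_i \omega^3 \delta_i^{3PA} g(3\omega)} to
#'   give the three-photon cross section in units of 1e-80 cm^6 s^2 /
#'   photon^2. Closed form \eqn{16\pi^4 \alpha a_0^8 / c^2}.
#'
#' These derived values are frozen into [mpa_constants()] and used by the
#' spectral assembly functions.
#'
#' @param const A constant set, as returned by [fundamental_constants()].
#' @return A named list with `k_tpa` (GM per a.u. sum) and `k_3pa`
#'   (1e-80 cm^6 s^2 photon^-2 per a.u. sum).
#' @examples
#' derive_mpa_constants()
#' @export
derive_mpa_constants <- function(const = fundamental_constants()) {
  alpha <- const$fine_structure
  a0_cm <- const$bohr_radius * 100
  c_cms <- const$speed_of_light * 100
  k_tpa_cgs <- 8 * pi^3 * alpha * a0_cm^5 / c_cms        # cm^4 s
  k_3pa_cgs <- 16 * pi^4 * alpha * a0_cm^8 / c_cms^2     # cm^6 s^2
  list(
    k_tpa = k_tpa_cgs / 1e-50,
    k_3pa = k_3pa_cgs / 1e-80
  )
}

# Frozen values of derive_mpa_constants(), re-verified at test time against
# an independent SI-route oracle. Used by the spectrum assemblers.
.k_tpa <- 2.505473978088353e-2
.k_3pa <- 7.781305400328875e-7

#' Conversion constants used by the spectral assembly
#'
#' Returns the frozen multiphoton conversion constants together with the
#' eV/atomic-unit energy conversion. `k_tpa` and `k_3pa` are the values of
#' [derive_mpa_constants()] frozen as named constants.
#'
#' @return Named list with `k_tpa`, `k_3pa`, `hartree_eV`.
#' @export
mpa_constants <- function() {
  list(k_tpa = .k_tpa, k_3pa = .k_3pa,
       hartree_eV = fundamental_constants()$hartree_eV)
}

ev_to_au <- function(ev) ev / fundamental_constants()$hartree_eV
au_to_ev <- function(au) au * fundamental_constants()$hartree_eV
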