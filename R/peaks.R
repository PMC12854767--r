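#' Band windows around ensemble-mean state energies
#'
#' Builds one energy window per requested state: the ensemble-mean excitation
#' energy of that state, scaled to the photon-energy axis of the process
#' (divided by 2 for TPA, 3 for 3PA), plus/minus `half_width` (default
#' 3 gamma).
#'
#' @param records Snapshot record table.
#' @param process One of "OPA", "TPA", "3PA".
#' @param states Integer states to include (default: all present).
#' @param gamma HWHM in eV used to size the window.
#' @param half_width Window half width in eV (default `3 * gamma`).
#' @return Tibble with columns `band`, `lo`, `hi` (eV, photon-energy axis).
#' @export
default_bands <- function(records, process = c("OPA", "TPA", "3PA"),
                          states = NULL, gamma = 0.1,
                          half_width = 3 * max(gamma)) {
  process <- match.arg(process)
  records <- validate_records(records)
  div <- c(OPA = 1, TPA = 2, `3PA` = 3)[[process]]
  means <- records |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(center = mean(.data$energy_eV) / div, .groups = "drop")
  if (!is.null(states)) means <- means[means$state %in% states, ]
  tibble(band = means$state,
         lo = means$center - half_width,
         hi = means$center + half_width)
}

#' Locate band maxima of a spectrum
#'
#' For each energy window, reports the grid point of maximum intensity.
#' Ties are broken toward the lower energy. A window whose maximum is not
#' strictly positive (flat zero spectrum) is an error.
#'
#' @param spectrum An `mpa_spectrum` (or any data frame with `energy_eV`,
#'   `intensity`).
#' @param bands Tibble with columns `band`, `lo`, `hi`, or a list of
#'   two-element `c(lo, hi)` windows.
#' @return A peak table tibble: `band`, `peak_energy_eV`, `peak_intensity`.
#' @export
find_peaks <- function(spectrum, bands) {
  if (is.list(bands) && !is.data.frame(bands)) {
    bands <- tibble(band = seq_along(bands),
                    lo = vapply(bands, `[`, numeric(1), 1),
                    hi = vapply(bands, `[`, numeric(1), 2))
  }
  grid <- spectrum$energy_eV
  rows <- vector("list", nrow(bands))
  for (b in seq_len(nrow(bands))) {
    band <- bands$band[b]; lo <- bands$lo[b]; hi <- bands$hi[b]
    if (!is.finite(lo) || !is.finite(hi) || hi <= lo) {
      abort("empty band window", class = "mpaspec_validation_error")
    }
    if (lo < min(grid) || hi > max(grid)) {
      abort(sprintf("band window [%.3f, %.3f] outside grid range", lo, hi),
            class = "mpaspec_validation_error")
    }
    sel <- which(grid >= lo & grid <= hi)
    if (!length(sel)) {
      abort("band window contains no grid points",
            class = "mpaspec_validation_error")
    }
    ints <- spectrum$intensity[sel]
    if (max(ints) <= 0) {
      abort("no peak above zero in band window",
            class = "mpaspec_peak_error")
    }
    j <- sel[which.max(ints)]   # first max = lowest energy on increasing grid
    rows[[b]] <- tibble(band = band, peak_energy_eV = grid[j],
                        peak_intensity = spectrum$intensity[j])
  }
  dplyr::bind_rows(rows)
}

#' Band-wise deviation between two peak tables
#'
#' Absolute energy differences and signed intensity differences between two
#' peak tables, matched by band index — the arithmetic used to compare peak
#' positions of different ensembles (or theory vs experiment).
#'
#' @param peaks_a,peaks_b Peak tables (see [find_peaks()]); `peaks_b` may
#'   omit `peak_intensity`, in which case intensity differences are `NA`.
#' @return Tibble `band`, `delta_energy_eV` (= |E_a - E_b|),
#'   `delta_intensity` (signed, a - b).
#' @examples
#' a <- tibble::tibble(band = 1, peak_energy_eV = 2.81, peak_intensity = 1)
#' b <- tibble::tibble(band = 1, peak_energy_eV = 2.64, peak_intensity = 1)
#' peak_deviation(a, b)  # 0.17 eV
#' @export
peak_deviation <- function(peaks_a, peaks_b) {
  if (!setequal(peaks_a$band, peaks_b$band)) {
    abort("peak tables cover different bands",
          class = "mpaspec_validation_error")
  }
  if (!"peak_intensity" %in% names(peaks_b)) peaks_b$peak_intensity <- NA_real_
  j <- dplyr::inner_join(peaks_a, peaks_b, by = "band",
                         suffix = c("_a", "_b"))
  tibble(band = j$band,
         delta_energy_eV = abs(j$peak_energy_eV_a - j$peak_energy_eV_b),
         delta_intensity = j$peak_intensity_a - j$peak_intensity_b)
}
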