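test_that("lorentzian is a unit-area HWHM lineshape", {
  expect_equal(lorentzian(2, 2, 0.1), 1 / (0.1 * pi), tolerance = 1e-12)
  expect_equal(lorentzian(2 + 0.1, 2, 0.1), lorentzian(2, 2, 0.1) / 2,
               tolerance = 1e-12)
  expect_equal(lorentzian(2 - 0.1, 2, 0.1), lorentzian(2 + 0.1, 2, 0.1),
               tolerance = 1e-12)
  x <- seq(-400, 404, by = 0.01)
  expect_equal(sum(lorentzian(x, 2, 0.1)) * 0.01, 1, tolerance = 0.01)
  expect_error(lorentzian(1, 1, 0), class = "mpaspec_validation_error")
  expect_error(lorentzian(1, 1, -0.1), class = "mpaspec_validation_error")
})

test_that("one-photon peak value matches the constant-by-constant SI oracle", {
  # frozen oracle: 10 * e^2 pi N_A / (2 ln10 eps0 me c) * hbar/e * 1/(pi*0.1)
  # evaluated with CODATA-2018 numbers, for one state at its line center
  # with f = 1, gamma = 0.1 eV, n = 1
  rec <- one_state_records(2.81, fosc = 1)
  grid <- seq(2.0, 3.6, by = 0.002)  # 2.81 falls on the grid
  sp <- opa_spectrum(rec, grid, gamma = 0.1)
  peak <- sp$intensity[sp$energy_eV == 2.81]
  expect_equal(peak, 91376.25275656361, tolerance = 1e-9)
})

test_that("two- and three-photon hand-evaluation examples reproduce", {
  Eh <- fundamental_constants()$hartree_eV
  grid <- sort(unique(c(seq(0.5, 5, 0.01), 0.05 * Eh)))
  # omega_i = 0.10 a.u., delta = 1000 a.u., gamma = 0.1 eV, photon 0.05 a.u.
  tpa <- tpa_spectrum(one_state_records(0.10 * Eh, delta_tpa = 1000),
                      grid, gamma = 0.1)
  expect_equal(tpa$intensity[tpa$energy_eV == 0.05 * Eh],
               5.425386688655772, tolerance = 1e-7)
  # omega_i = 0.15 a.u., delta = 1e6 a.u., photon 0.05 a.u.
  pa3 <- threepa_spectrum(one_state_records(0.15 * Eh, delta_3pa = 1e6),
                          grid, gamma = 0.1)
  expect_equal(pa3$intensity[pa3$energy_eV == 0.05 * Eh],
               0.008424871093065044, tolerance = 1e-7)
})

test_that("zero strengths give identically zero spectra", {
  rec <- one_state_records(2.81)
  grid <- seq(1, 4, 0.01)
  expect_true(all(opa_spectrum(rec, grid)$intensity == 0))
  expect_true(all(tpa_spectrum(rec, grid)$intensity == 0))
  expect_true(all(threepa_spectrum(rec, grid)$intensity == 0))
})

test_that("ensemble mean is idempotent on duplicated snapshots and permutation invariant", {
  ens <- make_ensemble(n_snapshots = 6, dt_fs = 200, seed = 11)
  grid <- seq(1, 5, 0.01)
  base <- tpa_spectrum(ens$records, grid)
  dup <- ens$records
  dup2 <- dplyr::mutate(dup, snapshot = snapshot + 100L,
                        time_fs = time_fs + 2000)
  both <- dplyr::bind_rows(dup, dup2)
  expect_equal(tpa_spectrum(both, grid)$intensity, base$intensity,
               tolerance = 1e-12)
  shuffled <- dplyr::arrange(ens$records, dplyr::desc(snapshot), state)
  expect_equal(tpa_spectrum(shuffled, grid)$intensity, base$intensity,
               tolerance = 1e-12)
})

test_that("spectra are additive in states and homogeneous in strengths", {
  grid <- seq(1, 5, 0.01)
  r1 <- one_state_records(2.8, fosc = 0.5, delta_tpa = 100, delta_3pa = 1e4)
  r2 <- dplyr::mutate(one_state_records(4.1, fosc = 0.2, delta_tpa = 50,
                                        delta_3pa = 5e3), state = 2L)
  joint <- dplyr::bind_rows(r1, r2)
  expect_equal(tpa_spectrum(joint, grid)$intensity,
               tpa_spectrum(r1, grid)$intensity +
                 tpa_spectrum(dplyr::mutate(r2, state = 1L), grid)$intensity,
               tolerance = 1e-12)
  scaled <- dplyr::mutate(r1, fosc = 3 * fosc, delta_tpa_au = 3 * delta_tpa_au,
                          delta_3pa_au = 3 * delta_3pa_au)
  expect_equal(opa_spectrum(scaled, grid)$intensity,
               3 * opa_spectrum(r1, grid)$intensity, tolerance = 1e-12)
  expect_equal(threepa_spectrum(scaled, grid)$intensity,
               3 * threepa_spectrum(r1, grid)$intensity, tolerance = 1e-12)
})

test_that("doubling gamma halves the peak of an isolated band", {
  grid <- seq(1, 2, 0.002)
  rec <- one_state_records(3.0, delta_tpa = 1000)
  s1 <- tpa_spectrum(rec, grid, gamma = 0.1)
  s2 <- tpa_spectrum(rec, grid, gamma = 0.2)
  at_center <- grid == 1.5   # photon energy at the line center
  expect_equal(s2$intensity[at_center] / s1$intensity[at_center], 0.5,
               tolerance = 1e-12)
})

test_that("spectra are non-negative and reject bad grids / empty records", {
  ens <- make_ensemble(n_snapshots = 4, seed = 2)
  grid <- seq(0.5, 5.5, 0.01)
  expect_true(all(opa_spectrum(ens$records, grid)$intensity >= 0))
  expect_true(all(tpa_spectrum(ens$records, grid)$intensity >= 0))
  expect_error(opa_spectrum(ens$records, c(2, 1, 3)),
               class = "mpaspec_validation_error")
  expect_error(opa_spectrum(ens$records[0, ], grid),
               class = "mpaspec_validation_error")
})

test_that("band maxima of multiphoton spectra sit at the scaled transition energies", {
  # gamma -> 0 limit: TPA maximum at omega_i/2, 3PA at omega_i/3,
  # within one 0.002 eV grid step at gamma = 1e-3 eV
  rec <- one_state_records(3.0, delta_tpa = 1000, delta_3pa = 1e6)
  grid <- default_grid()
  tp <- find_peaks(tpa_spectrum(rec, grid, gamma = 1e-3),
                   list(c(1.3, 1.7)))
  expect_lte(abs(tp$peak_energy_eV - 1.5), 0.002 + 1e-12)
  p3 <- find_peaks(threepa_spectrum(rec, grid, gamma = 1e-3),
                   list(c(0.8, 1.2)))
  expect_lte(abs(p3$peak_energy_eV - 1.0), 0.002 + 1e-12)
})

test_that("find_peaks matches dense brute-force evaluation of the shifted Lorentzian", {
  Eh <- fundamental_constants()$hartree_eV
  rec <- one_state_records(3.0, delta_tpa = 1000)
  grid <- seq(1, 2, by = 0.002)
  pk <- find_peaks(tpa_spectrum(rec, grid, gamma = 0.1), list(c(1.2, 1.8)))
  # independent brute force on a 1e5-point grid, scalar arithmetic
  dense <- seq(1.2, 1.8, length.out = 1e5)
  w <- dense / Eh; wi <- 3.0 / Eh; g <- 0.1 / Eh
  dense_val <- w^2 * (g / pi) / ((2 * w - wi)^2 + g^2)
  expect_lte(abs(pk$peak_energy_eV - dense[which.max(dense_val)]), 0.002)
})

test_that("find_peaks breaks ties toward lower energy and rejects flat spectra", {
  sp <- tibble::tibble(energy_eV = seq(1, 2, 0.1),
                       intensity = c(0, 1, 0, 0, 1, 0, 0, 0, 0, 0, 0))
  pk <- find_peaks(sp, list(c(1, 2)))
  expect_equal(pk$peak_energy_eV, 1.1)
  flat <- tibble::tibble(energy_eV = seq(1, 2, 0.1), intensity = 0)
  expect_error(find_peaks(flat, list(c(1, 2))), class = "mpaspec_peak_error")
  expect_error(find_peaks(sp, list(c(2, 1))),
               class = "mpaspec_validation_error")
  expect_error(find_peaks(sp, list(c(0, 3))),
               class = "mpaspec_validation_error")
})

test_that("peak deviations reproduce band-wise differences", {
  a <- tibble::tibble(band = 1:2, peak_energy_eV = c(2.81, 4.13),
                      peak_intensity = c(10, 5))
  b <- tibble::tibble(band = 1:2, peak_energy_eV = c(2.64, 5.17),
                      peak_intensity = c(9, 6))
  dev <- peak_deviation(a, b)
  expect_equal(dev$delta_energy_eV, c(0.17, 1.04), tolerance = 1e-12)
  expect_equal(dev$delta_intensity, c(1, -1))
  same <- peak_deviation(a, a)
  expect_true(all(same$delta_energy_eV == 0))
  expect_error(peak_deviation(a, b[1, ]), class = "mpaspec_validation_error")
})

test_that("spectrum files round-trip with metadata", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  sp <- tpa_spectrum(one_state_records(3, delta_tpa = 100),
                     seq(1, 2, 0.01))
  write_spectrum(sp, tmp)
  rt <- read_spectrum(tmp)
  expect_equal(rt$intensity, sp$intensity, tolerance = 1e-10)
  expect_equal(attr(rt, "process"), "TPA")
  expect_equal(attr(rt, "units"), attr(sp, "units"))
})
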