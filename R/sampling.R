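#' Per-snapshot two-photon cross-section series
#'
#' The scalar observable used for the decorrelation analysis: for each
#' snapshot, the peak two-photon cross section of one state, i.e. the value
#' of the single-state TPA expression at its own line center,
#' \eqn{k_{TPA}\,(\omega_i/2)^2\, \delta_i\, /(\pi\gamma)} in atomic units,
#' reported in GM.
#'
#' @param records Snapshot record table.
#' @param state Which electronic state (default 1, the lowest transition).
#' @param gamma HWHM in eV.
#' @return Tibble `time_fs`, `value` (GM), one row per snapshot, time-ordered.
#' @export
tpa_strength_series <- function(records, state = 1L, gamma = 0.1) {
  records <- validate_records(records)
  st <- records[records$state == state, ]
  if (nrow(st) == 0L) {
    abort(sprintf("no state %d in records", state),
          class = "mpaspec_validation_error")
  }
  g_au <- ev_to_au(gamma)
  w_au <- ev_to_au(st$energy_eV)
  tibble(time_fs = st$time_fs,
         value = .k_tpa * (w_au / 2)^2 * st$delta_tpa_au / (pi * g_au)) |>
    dplyr::arrange(.data$time_fs)
}

check_series <- function(series) {
  if (!all(c("time_fs", "value") %in% names(series))) {
    abort("series needs columns time_fs, value",
          class = "mpaspec_validation_error")
  }
  if (nrow(series) < 3L) {
    abort("series needs at least 3 points", class = "mpaspec_validation_error")
  }
  dt <- diff(series$time_fs)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt)) {
    abort("series times must be strictly increasing with uniform spacing",
          class = "mpaspec_validation_error")
  }
  series
}

#' Autocorrelation of a uniformly sampled observable
#'
#' \eqn{C(k) = \frac{1}{n\sigma^2} \sum_{t=1}^{n-k} (x_t - \mu)(x_{t+k} -
#' \mu)} with the population mean and variance — the biased (1/n) estimator,
#' kept exactly in this form. `C(0) = 1` exactly; at lag k > 0 the truncated
#' sum carries an O(k/n) downward bias, which is documented rather than
#' corrected.
#'
#' @param series Tibble with `time_fs` (uniform spacing) and `value`.
#' @param max_lag Largest lag in frames (must be < n); default `n %/% 4`.
#' @return An `mpa_acf` tibble: `lag` (frames), `lag_fs`, `c`.
#' @examples
#' s <- tibble::tibble(time_fs = c(0, 5, 10, 15), value = c(1, -1, 1, -1))
#' autocorrelation(s, max_lag = 1)$c   # 1, -0.75
#' @export
autocorrelation <- function(series, max_lag = NULL) {
  series <- check_series(series)
  x <- series$value
  n <- length(x)
  max_lag <- max_lag %||% (n %/% 4L)
  if (max_lag >= n) {
    abort("max_lag must be smaller than the series length",
          class = "mpaspec_validation_error")
  }
  mu <- mean(x)
  s2 <- mean((x - mu)^2)
  if (s2 == 0) {
    abort("constant series: zero variance, autocorrelation undefined",
          class = "mpaspec_validation_error")
  }
  dt <- mean(diff(series$time_fs))
  xc <- x - mu
  cvals <- vapply(0:max_lag, function(k) {
    sum(xc[seq_len(n - k)] * xc[seq_len(n - k) + k]) / (n * s2)
  }, numeric(1))
  out <- tibble(lag = 0:max_lag, lag_fs = (0:max_lag) * dt, c = cvals)
  structure(out, class = c("mpa_acf", class(out)), dt_fs = dt, n = n)
}

#' Exponential decay fit of an autocorrelation function
#'
#' Nonlinear least squares of \eqn{C(t) = A \exp(-t/\tau)} to the lagged
#' autocorrelation. Initialization: `A` from the first positive lag's value,
#' `tau` from the first lag where C drops below C(0)/e. The default fit
#' window spans lags up to ten times that initial tau estimate.
#'
#' @param acf An `mpa_acf` result from [autocorrelation()].
#' @param fit_window Optional `c(lo, hi)` lag range in fs.
#' @return An `mpa_acf_fit` object: list with `A`, `tau_fs`, the `nls` fit,
#'   the fitted window, and the input acf. Has [tidy()] and [glance()]
#'   methods.
#' @export
fit_acf_decay <- function(acf, fit_window = NULL) {
  dt <- attr(acf, "dt_fs") %||% mean(diff(acf$lag_fs))
  pos <- acf[acf$lag > 0, ]
  if (nrow(pos) == 0 || all(diff(acf$c) >= 0)) {
    abort("no decay detected in autocorrelation",
          class = "mpaspec_fit_error")
  }
  below <- which(acf$c < acf$c[1] / exp(1))
  tau0 <- if (length(below)) max(acf$lag_fs[min(below)], dt / 2) else
    max(acf$lag_fs) / 3
  a0 <- max(pos$c[1], 1e-3)
  fit_window <- fit_window %||% c(0, 10 * tau0)
  win <- acf[acf$lag_fs >= fit_window[1] & acf$lag_fs <= fit_window[2], ]
  if (nrow(win) < 4L) {
    abort("fit window must contain at least 4 lags",
          class = "mpaspec_fit_error")
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(c ~ A * exp(-lag_fs / tau),
                      data = win, start = list(A = a0, tau = tau0),
                      lower = c(A = 0, tau = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) abort(paste0("exponential fit failed: ",
                                     conditionMessage(e)),
                              class = "mpaspec_fit_error"))
  est <- coef(fit)
  if (est[["tau"]] < dt) {
    warn(sprintf(paste0("fitted tau (%.3g fs) is below one frame spacing ",
                        "(%.3g fs): series is effectively uncorrelated"),
                 est[["tau"]], dt))
  }
  structure(list(A = unname(est[["A"]]), tau_fs = unname(est[["tau"]]),
                 fit = fit, window_fs = fit_window, acf = acf),
            class = "mpa_acf_fit")
}

#' @export
print.mpa_acf_fit <- function(x, ...) {
  cat(sprintf("Exponential ACF fit: C(t) = A exp(-t/tau), A = %.3f, tau = %.3g fs\n",
              x$A, x$tau_fs))
  invisible(x)
}

#' @rdname fit_acf_decay
#' @param x An `mpa_acf_fit` object.
#' @param ... Unused.
#' @export
tidy.mpa_acf_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = c("A", "tau_fs"),
         estimate = c(x$A, x$tau_fs),
         std.error = s[, "Std. Error"])
}

#' @rdname fit_acf_decay
#' @export
glance.mpa_acf_fit <- function(x, ...) {
  tibble(A = x$A, tau_fs = x$tau_fs,
         n_lags = nrow(x$acf),
         sigma = summary(x$fit)$sigma)
}

#' Recommended snapshot spacing from an exponential decorrelation model
#'
#' The smallest integer multiple of the trajectory frame interval at which
#' the fitted correlation \eqn{A \exp(-t/\tau)} falls strictly below the
#' tolerance; closed form \eqn{t^* = \tau \ln(A/\mathrm{tol})} rounded up to
#' the frame grid.
#'
#' @param A Fitted amplitude (dimensionless).
#' @param tau_fs Fitted decay time in fs.
#' @param tolerance Residual-correlation tolerance (default 0.01); must be
#'   < A.
#' @param frame_interval_fs Trajectory frame interval in fs.
#' @return Spacing in fs.
#' @examples
#' decorrelation_spacing(0.86, 15, 1e-5, 5)  # 175 fs
#' @export
decorrelation_spacing <- function(A, tau_fs, tolerance = 0.01,
                                  frame_interval_fs) {
  if (tolerance >= A) {
    abort("tolerance must be below the amplitude A",
          class = "mpaspec_validation_error")
  }
  if (tau_fs <= 0 || frame_interval_fs <= 0) {
    abort("tau and frame interval must be positive",
          class = "mpaspec_validation_error")
  }
  t_star <- tau_fs * log(A / tolerance)
  k <- max(1L, ceiling(t_star / frame_interval_fs))
  while (A * exp(-(k * frame_interval_fs) / tau_fs) >= tolerance) k <- k + 1L
  k * frame_interval_fs
}

moment_summary <- function(x) {
  tibble(mean = mean(x), sd = sd(x),
         skewness = e1071::skewness(x, type = 2),
         excess_kurtosis = e1071::kurtosis(x, type = 2))
}

#' Down-sampling convergence study
#'
#' Re-derives ensemble spectra and peak tables after thinning the snapshot
#' ensemble at each requested spacing, and summarises how the per-snapshot
#' distributions (excitation energy, oscillator strength, peak TPA cross
#' section of the chosen state) change. Peak drift is reported against the
#' densest spacing.
#'
#' @param records Snapshot record table with uniform snapshot spacing.
#' @param spacings_fs Spacings in fs, each an integer multiple of the record
#'   interval.
#' @param process Spectrum type for the peak tables.
#' @param grid,gamma Passed to the spectrum assembler.
#' @param states States for the band windows (default 1).
#' @return List with `peaks` (tibble: spacing_fs, band, peak columns, drift
#'   vs densest), and `summaries` (tibble of moment summaries per spacing and
#'   observable).
#' @export
downsample_convergence <- function(records, spacings_fs,
                                   process = c("TPA", "OPA", "3PA"),
                                   grid = default_grid(), gamma = 0.1,
                                   states = 1L) {
  process <- match.arg(process)
  records <- validate_records(records)
  times <- sort(unique(records$time_fs))
  if (length(times) < 2L) {
    abort("need at least 2 snapshots", class = "mpaspec_validation_error")
  }
  dt <- mean(diff(times))
  spec_fun <- switch(process, OPA = opa_spectrum, TPA = tpa_spectrum,
                     `3PA` = threepa_spectrum)
  per_spacing <- lapply(sort(spacings_fs), function(sp) {
    step <- sp / dt
    if (abs(step - round(step)) > 1e-6) {
      abort(sprintf("spacing %g fs is not a multiple of the %g fs interval",
                    sp, dt), class = "mpaspec_validation_error")
    }
    keep <- times[seq(1L, length(times), by = round(step))]
    sub <- records[records$time_fs %in% keep, ]
    if (dplyr::n_distinct(sub$snapshot) < 2L) {
      abort("insufficient snapshots after downsampling",
            class = "mpaspec_validation_error")
    }
    bands <- default_bands(sub, process, states = states, gamma = gamma)
    spec <- if (process == "OPA") spec_fun(sub, grid, gamma) else
      spec_fun(sub, grid, gamma)
    peaks <- find_peaks(spec, bands) |>
      dplyr::mutate(spacing_fs = sp, n_snapshots = dplyr::n_distinct(sub$snapshot))
    st <- sub[sub$state == states[1], ]
    tpa_vals <- tpa_strength_series(sub, state = states[1], gamma = gamma)$value
    summaries <- dplyr::bind_rows(
      dplyr::mutate(moment_summary(st$energy_eV), observable = "energy_eV"),
      dplyr::mutate(moment_summary(st$fosc), observable = "fosc"),
      dplyr::mutate(moment_summary(tpa_vals), observable = "sigma_tpa_GM")
    ) |> dplyr::mutate(spacing_fs = sp)
    list(peaks = peaks, summaries = summaries)
  })
  peaks <- purrr::map_dfr(per_spacing, "peaks")
  densest <- peaks[peaks$spacing_fs == min(peaks$spacing_fs),
                   c("band", "peak_energy_eV")]
  names(densest)[2] <- "peak_ref"
  peaks <- dplyr::left_join(peaks, densest, by = "band") |>
    dplyr::mutate(peak_drift_eV = .data$peak_energy_eV - .data$peak_ref,
                  peak_ref = NULL)
  list(peaks = peaks,
       summaries = purrr::map_dfr(per_spacing, "summaries"))
}
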