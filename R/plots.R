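#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the package's result objects: spectra,
#' autocorrelation fits, structural timelines, descriptor correlations and
#' coupling error scans.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name mpaspec-plots
NULL

#' @rdname mpaspec-plots
#' @export
autoplot.mpa_spectrum <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$energy_eV, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "photon energy (eV)",
                  y = attr(object, "units"),
                  title = sprintf("%s spectrum (N = %d)",
                                  attr(object, "process"),
                                  attr(object, "n_snapshots"))) +
    ggplot2::theme_minimal()
}

#' @rdname mpaspec-plots
#' @export
autoplot.mpa_acf <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$lag_fs, y = .data$c)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "lag (fs)", y = "C(t)") +
    ggplot2::theme_minimal()
}

#' @rdname mpaspec-plots
#' @export
autoplot.mpa_acf_fit <- function(object, ...) {
  acf_tbl <- as_tibble(object$acf)
  curve <- tibble(lag_fs = seq(0, max(acf_tbl$lag_fs), length.out = 200))
  curve$c <- object$A * exp(-curve$lag_fs / object$tau_fs)
  autoplot(object$acf) +
    ggplot2::geom_line(data = curve, colour = "red") +
    ggplot2::labs(subtitle = sprintf("A = %.2f, tau = %.3g fs",
                                     object$A, object$tau_fs))
}

#' @rdname mpaspec-plots
#' @export
autoplot.mpa_timeline <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("time_fs", "bla", "planarity")],
    -"time_fs", names_to = "descriptor", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_fs, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~descriptor, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (fs)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname mpaspec-plots
#' @export
autoplot.mpa_correlation <- function(object, ...) {
  d <- attr(object, "data")
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[object$x[1]]],
                                  y = .data[[object$y[1]]])) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = object$slope[1],
                         intercept = object$intercept[1], colour = "red") +
    ggplot2::labs(subtitle = sprintf("r = %.2f, rho = %.2f, slope = %.3g",
                                     object$pearson_r[1],
                                     object$spearman_rho[1],
                                     object$slope[1])) +
    ggplot2::theme_minimal()
}

#' @rdname mpaspec-plots
#' @export
autoplot.mpa_error_scan <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("abs_dE", "abs_dFmax"),
                              names_to = "metric", values_to = "error")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$order, y = .data$error,
                                     colour = factor(.data$r_exact))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "multipole order p", y = "absolute error (a.u.)",
                  colour = "R_exact (bohr)") +
    ggplot2::theme_minimal()
}
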