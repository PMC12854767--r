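#' Join structural descriptors with excited-state records
#'
#' Matches each timeline frame to the nearest-in-time snapshot within a
#' tolerance (default: half the structural frame interval) and returns one
#' row per matched (snapshot, chromophore) with the first excitation energy.
#' Unmatched rows are dropped with an informational message carrying the
#' count.
#'
#' @param timeline An `mpa_timeline` (see [structure_timeline()]).
#' @param records Snapshot record table.
#' @param tolerance_fs Maximum |time difference| for a match; default half
#'   the timeline frame interval.
#' @param state Which excitation energy to carry (default 1).
#' @return Tibble `snapshot`, `chromophore`, `time_fs`, `bla`, `planarity`,
#'   `e1_eV`.
#' @export
join_structure_spectra <- function(timeline, records, tolerance_fs = NULL,
                                   state = 1L) {
  records <- validate_records(records)
  st <- records[records$state == state, ]
  if (nrow(st) == 0L) {
    abort(sprintf("no state %d in records", state),
          class = "mpaspec_validation_error")
  }
  if (max(timeline$time_fs) < min(st$time_fs) ||
      min(timeline$time_fs) > max(st$time_fs)) {
    abort("timeline and records have no overlapping time range",
          class = "mpaspec_validation_error")
  }
  if (is.null(tolerance_fs)) {
    dts <- diff(sort(unique(timeline$time_fs)))
    tolerance_fs <- if (length(dts)) mean(dts) / 2 else Inf
  }
  j <- purrr::map_dfr(seq_len(nrow(st)), function(i) {
    d <- abs(timeline$time_fs - st$time_fs[i])
    k <- which.min(d)
    if (d[k] > tolerance_fs) return(NULL)
    tibble(snapshot = st$snapshot[i], chromophore = st$chromophore[i],
           time_fs = st$time_fs[i], bla = timeline$bla[k],
           planarity = timeline$planarity[k], e1_eV = st$energy_eV[i])
  })
  dropped <- nrow(st) - nrow(j)
  if (nrow(j) == 0L) {
    abort("no snapshot matched a frame within the join tolerance",
          class = "mpaspec_validation_error")
  }
  if (dropped > 0L) {
    inform(sprintf("join dropped %d of %d snapshots (no frame within %.3g fs)",
                   dropped, nrow(st), tolerance_fs))
  }
  j
}

#' Descriptor-energy correlation
#'
#' Pearson and Spearman correlation of a structural descriptor with the
#' first excitation energy, plus the ordinary least-squares slope and
#' intercept. No p-values are reported: consecutive snapshots are
#' autocorrelated, so nominal OLS inference would overstate certainty; the
#' coefficients are descriptive.
#'
#' @param joined A joined table from [join_structure_spectra()].
#' @param x Descriptor column name (e.g. `"bla"`, `"planarity"`).
#' @param y Response column name (default `"e1_eV"`).
#' @return An `mpa_correlation` object: one-row tibble `x`, `y`,
#'   `pearson_r`, `spearman_rho`, `slope`, `intercept`, `n`, carrying the
#'   joined data for plotting. Has [tidy()] and [glance()] methods.
#' @export
descriptor_correlation <- function(joined, x, y = "e1_eV") {
  xv <- joined[[x]]; yv <- joined[[y]]
  if (is.null(xv) || is.null(yv)) {
    abort("descriptor column not found", class = "mpaspec_validation_error")
  }
  if (length(xv) < 3L) {
    abort("need at least 3 joined rows", class = "mpaspec_validation_error")
  }
  if (sd(xv) == 0 || sd(yv) == 0) {
    abort("zero variance in x or y: correlation undefined",
          class = "mpaspec_validation_error")
  }
  fit <- lm(yv ~ xv)
  out <- tibble(x = x, y = y,
                pearson_r = cor(xv, yv),
                spearman_rho = cor(xv, yv, method = "spearman"),
                slope = unname(coef(fit)[2]),
                intercept = unname(coef(fit)[1]),
                n = length(xv))
  structure(out, class = c("mpa_correlation", class(out)),
            data = tibble(!!x := xv, !!y := yv))
}

#' Tidy a descriptor-energy correlation
#' @param x An `mpa_correlation` object.
#' @param ... Unused.
#' @return One-row tibble of coefficients.
#' @export
tidy.mpa_correlation <- function(x, ...) {
  as_tibble(x)[, c("x", "y", "pearson_r", "spearman_rho", "slope",
                   "intercept", "n")]
}

#' @rdname tidy.mpa_correlation
#' @export
glance.mpa_correlation <- function(x, ...) tidy.mpa_correlation(x)
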