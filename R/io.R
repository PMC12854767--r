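#' Read / write spectrum files
#'
#' Two-column tab-separated files (`energy_eV`, `intensity`) with a comment
#' header carrying the process, units, broadening and snapshot count, so a
#' spectrum round-trips with its metadata.
#'
#' @param spectrum An `mpa_spectrum`.
#' @param path File path.
#' @return `read_spectrum()`: an `mpa_spectrum`; the writer returns `path`
#'   invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  hdr <- sprintf("# process=%s units=%s gamma_eV=%s n_snapshots=%d",
                 attr(spectrum, "process"),
                 gsub(" ", "_", attr(spectrum, "units")),
                 paste(attr(spectrum, "gamma"), collapse = ","),
                 attr(spectrum, "n_snapshots"))
  writeLines(hdr, path)
  readr::write_tsv(tibble(energy_eV = spectrum$energy_eV,
                          intensity = spectrum$intensity),
                   path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("spectrum file not found: ", path),
          class = "mpaspec_io_error")
  }
  hdr <- readLines(path, n = 1L)
  kv <- regmatches(hdr, gregexpr("[a-zA-Z_]+=[^ ]+", hdr))[[1]]
  meta <- setNames(sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  new_spectrum(df$energy_eV, df$intensity,
               process = meta[["process"]] %||% "OPA",
               units = gsub("_", " ", meta[["units"]] %||% ""),
               gamma = as.numeric(strsplit(meta[["gamma_eV"]] %||% "0.1",
                                           ",")[[1]]),
               n_snapshots = as.integer(meta[["n_snapshots"]] %||% NA))
}

#' Write an autocorrelation table and fit report
#'
#' `write_acf()` writes the lag table as TSV; `write_acf_report()` writes
#' the JSON fit report with amplitude, decay time and recommended spacing.
#'
#' @param acf An `mpa_acf`.
#' @param fit An `mpa_acf_fit`.
#' @param spacing_fs Recommended spacing (fs) from
#'   [decorrelation_spacing()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_acf <- function(acf, path) {
  writeLines("# mpaspec autocorrelation; biased 1/n normalization", path)
  readr::write_tsv(as_tibble(acf), path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_acf
#' @export
write_acf_report <- function(fit, spacing_fs, path) {
  jsonlite::write_json(list(A = fit$A, tau_fs = fit$tau_fs,
                            spacing_fs = spacing_fs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
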