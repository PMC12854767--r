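#' Per-snapshot excited-state record tables
#'
#' The central tabular container of the pipeline: one row per electronic
#' state per snapshot, with columns
#' `snapshot` (integer id), `time_fs`, `chromophore` (label, e.g.
#' "LYR-472"), `state` (integer >= 1), `energy_eV` (> 0), `fosc` (>= 0,
#' oscillator strength), `delta_tpa_au` (>= 0, two-photon transition
#' strength, atomic units), `delta_3pa_au` (>= 0, three-photon transition
#' strength, atomic units).
#'
#' `read_snapshot_records()` reads the tab-separated on-disk form (comment
#' lines starting with `#` ignored); `write_snapshot_records()` writes it.
#' `validate_records()` checks the invariants and is called by every consumer.
#'
#' @param path File path of a tab-separated record table.
#' @param records A records data frame.
#' @return A validated tibble of records.
#' @name snapshot_records
NULL

#' @rdname snapshot_records
#' @export
read_snapshot_records <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("record file not found: ", path), class = "mpaspec_io_error")
  }
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  validate_records(df)
}

#' @rdname snapshot_records
#' @export
write_snapshot_records <- function(records, path) {
  records <- validate_records(records)
  header <- sprintf("# mpaspec snapshot records; n_snapshots=%d",
                    dplyr::n_distinct(records$snapshot))
  writeLines(header, path)
  readr::write_tsv(records, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' @rdname snapshot_records
#' @export
validate_records <- function(records) {
  needed <- c("snapshot", "time_fs", "chromophore", "state", "energy_eV",
              "fosc", "delta_tpa_au", "delta_3pa_au")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    abort(paste0("record table missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "mpaspec_validation_error")
  }
  records <- as_tibble(records)
  if (nrow(records) == 0L) {
    abort("record table is empty", class = "mpaspec_validation_error")
  }
  if (any(!is.finite(records$energy_eV)) || any(records$energy_eV <= 0)) {
    abort("excitation energies must be finite and > 0",
          class = "mpaspec_validation_error")
  }
  for (col in c("fosc", "delta_tpa_au", "delta_3pa_au")) {
    if (any(!is.finite(records[[col]])) || any(records[[col]] < 0)) {
      abort(paste0(col, " must be finite and >= 0"),
            class = "mpaspec_validation_error")
    }
  }
  bad <- records |>
    dplyr::group_by(.data$snapshot, .data$chromophore) |>
    dplyr::summarise(
      ok = all(.data$state == seq_along(.data$state)) && min(.data$state) == 1L,
      .groups = "drop"
    )
  if (any(!bad$ok)) {
    abort("state indices must increase 1, 2, ... within each snapshot",
          class = "mpaspec_validation_error")
  }
  records
}
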