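# CSV I/O for the pipeline's tabular interchange formats. All readers
# validate the schema and report offending rows; all writers emit plain
# UTF-8 CSV with a header and full numeric precision.

read_checked_csv <- function(path, col_types, required, what) {
  # readr's parse warning is superseded by the structured error below
  out <- suppressWarnings(
    readr::read_csv(path, col_types = col_types, progress = FALSE)
  )
  missing_cols <- setdiff(required, names(out))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s file '%s' lacks column(s): %s", what, path,
                  paste(missing_cols, collapse = ", ")),
          class = "cypivive_input_error")
  }
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    abort(sprintf("%s file '%s': parse failure at row %d, column %d (%s).",
                  what, path, probs$row[1], probs$col[1], probs$expected[1]),
          class = "cypivive_input_error")
  }
  out
}

#' Read and write long-format activity tables
#'
#' Schema: `subject_id`, `cyp`, `parameter` (`vmax`/`km`/`clint`), `value`.
#' Values round-trip at full double precision.
#'
#' @param path File path.
#' @param data The activity tibble to write.
#' @return The tibble (readers) or `path`, invisibly (writers).
#' @export
read_activity_table <- function(path) {
  out <- read_checked_csv(
    path, readr::cols(subject_id = "c", cyp = "c", parameter = "c",
                      value = "d"),
    c("subject_id", "cyp", "parameter", "value"), "Activity table"
  )
  bad <- which(!out$parameter %in% kinetic_parameters())
  if (length(bad) > 0) {
    # + 1 converts the data row to the file line (header occupies line 1)
    abort(sprintf("Activity table '%s': unknown parameter '%s' at row %d.",
                  path, out$parameter[bad[1]], bad[1] + 1L),
          class = "cypivive_input_error")
  }
  out
}

#' @rdname read_activity_table
#' @export
write_activity_table <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Read and write per-subject physiology tables
#'
#' Schema: `subject_id`, `bw_kg`, `cardiac_output_ml_min`, `mppgl_mg_g`, and
#' optionally the derivable `qh_ml_min` and `lw_g`.
#'
#' @inheritParams read_activity_table
#' @export
read_physiology <- function(path) {
  read_checked_csv(
    path, readr::cols(subject_id = "c", .default = "d"),
    c("subject_id", "bw_kg", "cardiac_output_ml_min", "mppgl_mg_g"),
    "Physiology"
  )
}

#' @rdname read_physiology
#' @export
write_physiology <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Read and write microsomal velocity tables
#'
#' Schema: `subject_id`, `cyp`, `substrate_conc_uM`, `velocity_pmol_min_mg`
#' (long format, one row per incubation point).
#'
#' @inheritParams read_activity_table
#' @export
read_velocity_table <- function(path) {
  read_checked_csv(
    path, readr::cols(subject_id = "c", cyp = "c", probe = "c",
                      .default = "d"),
    c("subject_id", "cyp", "substrate_conc_uM", "velocity_pmol_min_mg"),
    "Velocity table"
  )
}

#' @rdname read_velocity_table
#' @export
write_velocity_table <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}
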