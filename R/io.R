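# Reading and writing the three event CSVs (patients.csv,
# prescriptions.csv, tests.csv) with ISO-8601 dates.

.patient_date_cols <- c("date_of_birth", "registration_start", "death_date")

#' Write a dataset to CSV files
#'
#' Writes `patients.csv`, `prescriptions.csv` and `tests.csv` into
#' `dir` (created if needed), with header rows and ISO-8601 dates.
#'
#' @param data a `dmard_ehr` dataset.
#' @param dir output directory.
#' @return (invisibly) the paths written.
#' @export
write_ehr_csv <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("patients.csv", "prescriptions.csv", "tests.csv"))
  readr::write_csv(data$patients, paths[1], na = "")
  readr::write_csv(data$prescriptions, paths[2], na = "")
  readr::write_csv(data$tests, paths[3], na = "")
  invisible(paths)
}

#' Read a dataset from CSV files
#'
#' Reads the three event CSVs written by [write_ehr_csv()] (or
#' user-supplied files with the same schema) and validates columns and
#' dates.
#'
#' @param dir directory containing `patients.csv`, `prescriptions.csv`
#'   and `tests.csv`.
#' @return a `dmard_ehr` dataset.
#' @export
read_ehr_data <- function(dir) {
  paths <- file.path(dir, c("patients.csv", "prescriptions.csv", "tests.csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("missing input file(s): ", paste(missing, collapse = ", ")),
          class = "dmardmon_data_error")
  }
  pat <- readr::read_csv(paths[1], show_col_types = FALSE, progress = FALSE)
  rx <- readr::read_csv(paths[2], show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(patient_id = "c", drug = "c",
                                                issue_date = readr::col_date()))
  tst <- readr::read_csv(paths[3], show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(patient_id = "c",
                                                 test_type = "c",
                                                 date = readr::col_date()))
  for (col in intersect(.patient_date_cols, names(pat))) {
    pat[[col]] <- as.Date(pat[[col]])
  }
  if (any(is.na(rx$issue_date))) {
    abort("prescriptions.csv contains unparseable issue dates",
          class = "dmardmon_data_error")
  }
  if (any(is.na(tst$date))) {
    abort("tests.csv contains unparseable test dates",
          class = "dmardmon_data_error")
  }
  ehr_data(pat, rx, tst)
}
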