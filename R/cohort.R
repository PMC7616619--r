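# Cohort selection: who is eligible, and who counts as "on" a drug, at a
# given index month.
#
# A patient is on a drug at an index month if they have at least two
# issues: one within the 3 months before the search date and one between
# 3 and 6 months before it (repeat prescriptions in England are mostly
# issued for 3 months or less, so two issues across these windows imply
# an active repeat course). Window boundaries use calendar-month
# subtraction with end-of-month clamping; both windows are half-open on
# the left: (index - 6m, index - 3m] and (index - 3m, index].

#' Patient eligibility at an index month
#'
#' A patient is eligible when alive at the index date (no recorded death
#' on or before it), aged 18 to 120 at the index date, registered on or
#' before it, and with none of age, sex, IMD quintile or rural-urban
#' classification missing (missing core fields flag poor data quality).
#'
#' @param patients patient tibble (see [generate_population()]). Age is
#'   taken from `date_of_birth` when present, otherwise a non-missing
#'   `age_band` (whose bands all lie inside 18-120) satisfies the age
#'   criterion.
#' @param index an index month (anything [as_index_month()] accepts).
#' @return logical vector, one element per patient row.
#' @export
is_eligible <- function(patients, index) {
  index <- as_index_month(index)
  idx <- index$index_date

  if (any(is.na(patients$registration_start))) {
    bad <- patients$patient_id[is.na(patients$registration_start)]
    abort(paste0("malformed registration date for patient(s): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "dmardmon_data_error")
  }
  alive <- is.na(patients$death_date) | patients$death_date > idx
  registered <- patients$registration_start <= idx

  if ("date_of_birth" %in% names(patients)) {
    age <- floor(as.numeric(idx - patients$date_of_birth) / 365.25)
    age_ok <- !is.na(age) & age >= 18 & age <= 120
  } else {
    age_ok <- !is.na(patients$age_band)
  }
  core_ok <- !is.na(patients$sex) & !is.na(patients$imd_quintile) &
    !is.na(patients$rural_urban)
  alive & registered & age_ok & core_ok
}

on_drug_windows <- function(index) {
  index <- as_index_month(index)
  idx <- index$index_date
  list(recent_start = idx %m-% months(3), # exclusive
       earlier_start = idx %m-% months(6), # exclusive
       index_date = idx)
}

#' Is a single patient on a drug at an index month?
#'
#' Requires at least one issue in the 3 months up to the index date and
#' at least one in the 3 months before that (both windows half-open on
#' the left, calendar-month arithmetic with end-of-month clamping).
#'
#' @param prescriptions prescription tibble filtered to one patient.
#' @param drug a drug label.
#' @param index an index month.
#' @return `TRUE` or `FALSE`.
#' @seealso [on_drug_ids()] for the vectorised version over a whole
#'   prescription table.
#' @export
on_drug <- function(prescriptions, drug, index) {
  required_tests(drug) # validates the label
  if ("patient_id" %in% names(prescriptions) &&
      length(unique(prescriptions$patient_id)) > 1L) {
    abort("on_drug() expects prescriptions for a single patient; use on_drug_ids()",
          class = "dmardmon_argument_error")
  }
  w <- on_drug_windows(index)
  d <- prescriptions$issue_date[prescriptions$drug == drug]
  any(d > w$recent_start & d <= w$index_date) &&
    any(d > w$earlier_start & d <= w$recent_start)
}

#' Patients on a drug at an index month
#'
#' @param prescriptions full prescription tibble.
#' @param drug a drug label.
#' @param index an index month.
#' @return character vector of patient ids satisfying the two-window
#'   repeat-prescription rule, sorted.
#' @export
on_drug_ids <- function(prescriptions, drug, index) {
  required_tests(drug)
  w <- on_drug_windows(index)
  px <- prescriptions |>
    filter(drug == !!drug,
           issue_date > w$earlier_start, issue_date <= w$index_date)
  recent <- unique(px$patient_id[px$issue_date > w$recent_start])
  earlier <- unique(px$patient_id[px$issue_date <= w$recent_start])
  sort(intersect(recent, earlier))
}

#' The denominator for one drug at one index month
#'
#' Patients who are both eligible and on the drug at the index month.
#'
#' @param data a `dmard_ehr` dataset (or list with `patients` and
#'   `prescriptions` tibbles).
#' @param drug a drug label.
#' @param index an index month.
#' @return character vector of patient ids (possibly empty), sorted.
#' @export
drug_denominator <- function(data, drug, index) {
  index <- as_index_month(index)
  elig <- data$patients$patient_id[is_eligible(data$patients, index)]
  on <- on_drug_ids(data$prescriptions, drug, index)
  sort(intersect(elig, on))
}
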