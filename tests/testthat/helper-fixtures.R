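# Small in-code fixtures used across the unit tests.

suppressMessages(library(lubridate))

make_patients <- function(n = 1, ...) {
  base <- tibble::tibble(
    patient_id = sprintf("p%06d", seq_len(n)),
    practice_id = "gp0001",
    age_band = "50-59",
    date_of_birth = as.Date("1968-06-15"),
    sex = "female",
    ethnicity = "White",
    region = "East",
    imd_quintile = 3L,
    rural_urban = 3L,
    care_home = FALSE,
    dementia = FALSE,
    housebound = FALSE,
    learning_disability = FALSE,
    serious_mental_illness = FALSE,
    registration_start = as.Date("2010-01-01"),
    death_date = as.Date(NA)
  )
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

# issues spaced ~84 days apart ending near `last`, reaching back `k` issues
make_issues <- function(patient_id, drug, last, k = 4, gap = 84) {
  tibble::tibble(
    patient_id = patient_id, drug = drug,
    issue_date = as.Date(last) - gap * (seq_len(k) - 1)
  )
}

# one test event per required type for a drug, all on `date`
make_panel <- function(patient_id, drug, date) {
  tibble::tibble(patient_id = patient_id,
                 test_type = required_tests(drug),
                 date = as.Date(date))
}

empty_tests <- function() {
  tibble::tibble(patient_id = character(), test_type = character(),
                 date = as.Date(character()))
}

empty_rx <- function() {
  tibble::tibble(patient_id = character(), drug = character(),
                 issue_date = as.Date(character()))
}

# a fast, small simulation configuration for engine-vs-oracle checks
micro_config <- function(seed, n_patients = 120, ...) {
  args <- utils::modifyList(list(n_patients = n_patients, n_practices = 8,
                                 seed = seed),
                            list(...))
  do.call(sim_config, args)
}
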