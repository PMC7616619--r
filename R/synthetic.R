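# Synthetic primary-care EHR generator.
#
# Emulates the event structure the monitoring analysis consumes: a DMARD
# cohort with ~3-monthly repeat prescribing, monitoring attendances on a
# three-monthly due-window cycle anchored at each patient's first
# prescription, and a per-window miss probability
#   pi = plogis(baseline + practice effect + subgroup offsets + frailty
#               + shock(t)),
# where shock(t) equals `lockdown_shock_logit` inside the shock window
# and decays linearly (logit scale) to zero by `recovery_end`. All blood
# tests from one attendance share a single date (panels are drawn
# together); the blood-pressure check for leflunomide is a separate draw
# with its own extra miss offset. Attendance is decided by comparing a
# uniform draw against pi, so runs sharing a seed are coupled: raising
# the shock can only turn attendances into misses, never the reverse.

new_ehr_data <- function(patients, prescriptions, tests, config = NULL) {
  structure(list(patients = patients, prescriptions = prescriptions,
                 tests = tests),
            config = config, class = "dmard_ehr")
}

#' Bundle patient, prescription and test tables into one dataset
#'
#' @param patients tibble with one row per patient (see
#'   [generate_population()] for the schema).
#' @param prescriptions tibble with columns `patient_id`, `drug`,
#'   `issue_date`.
#' @param tests tibble with columns `patient_id`, `test_type`, `date`.
#' @return an object of class `dmard_ehr` (a named list of the three
#'   tibbles).
#' @export
ehr_data <- function(patients, prescriptions, tests) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) {
      abort(paste0(what, " table is missing column(s): ",
                   paste(miss, collapse = ", ")),
            class = "dmardmon_data_error")
    }
  }
  need(patients, c("patient_id", "practice_id", "age_band", "sex",
                   "imd_quintile", "rural_urban", "registration_start"),
       "patients")
  need(prescriptions, c("patient_id", "drug", "issue_date"), "prescriptions")
  need(tests, c("patient_id", "test_type", "date"), "tests")
  if (anyDuplicated(patients$patient_id) > 0) {
    abort("patient identifiers must be unique", class = "dmardmon_data_error")
  }
  new_ehr_data(as_tibble(patients), as_tibble(prescriptions), as_tibble(tests))
}

#' @export
print.dmard_ehr <- function(x, ...) {
  cat("<dmard_ehr> ", nrow(x$patients), " patients, ",
      nrow(x$prescriptions), " prescriptions, ",
      nrow(x$tests), " test events\n", sep = "")
  invisible(x)
}

sample_cat <- function(p, n) sample(names(p), n, replace = TRUE, prob = p)

#' Generate a synthetic patient table
#'
#' Draws `n_patients` records with demographics sampled independently
#' from the configured categorical distributions, uniform practice
#' assignment, a registration start predating the study, and a small
#' fraction of deaths during the study window. Ethnicity and region may
#' be recorded missing; core fields (sex, IMD, rurality, date of birth)
#' are complete unless `missing_core_frac > 0`.
#'
#' @param config a [sim_config()].
#' @return a tibble, one row per patient.
#' @export
generate_population <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  dd <- config$demographic_distributions

  age_band <- sample_cat(dd$age_band, n)
  idx <- match(age_band, .age_bands)
  # exact fractional age at study start, uniform within the band
  age_frac <- runif(n, .age_band_lo[idx], .age_band_hi[idx] + 1)
  dob <- config$study_start - round(age_frac * 365.25)

  pat <- tibble(
    patient_id = sprintf("p%06d", seq_len(n)),
    practice_id = sprintf("gp%04d", sample.int(config$n_practices, n, replace = TRUE)),
    age_band = age_band,
    date_of_birth = dob,
    sex = sample_cat(dd$sex, n),
    ethnicity = sample_cat(dd$ethnicity, n),
    region = sample_cat(dd$region, n),
    imd_quintile = as.integer(sample_cat(dd$imd_quintile, n)),
    rural_urban = as.integer(sample_cat(dd$rural_urban, n)),
    care_home = sample_cat(dd$care_home, n) == "TRUE",
    dementia = sample_cat(dd$dementia, n) == "TRUE",
    housebound = sample_cat(dd$housebound, n) == "TRUE",
    learning_disability = sample_cat(dd$learning_disability, n) == "TRUE",
    serious_mental_illness = sample_cat(dd$serious_mental_illness, n) == "TRUE",
    registration_start = config$study_start - sample(365:7300, n, replace = TRUE)
  )
  pat$ethnicity[runif(n) < config$missing_ethnicity_frac] <- NA_character_
  pat$region[runif(n) < config$missing_region_frac] <- NA_character_

  span <- as.integer(config$study_end - config$study_start)
  dies <- runif(n) < config$death_prob
  death_cand <- config$study_start + sample.int(span, n, replace = TRUE)
  pat$death_date <- as.Date(ifelse(dies, death_cand, NA),
                            origin = "1970-01-01")

  if (config$missing_core_frac > 0) {
    hit <- which(runif(n) < config$missing_core_frac)
    which_field <- sample(c("sex", "imd_quintile", "rural_urban", "date_of_birth"),
                          length(hit), replace = TRUE)
    for (f in unique(which_field)) {
      pat[[f]][hit[which_field == f]] <- NA
    }
    pat$age_band[is.na(pat$date_of_birth)] <- NA_character_
  }
  pat
}

#' Generate synthetic repeat-prescribing events
#'
#' Each patient is put on each drug independently with the configured
#' prevalence. A course starts at a uniform date within the first
#' prescribing interval of the study, then repeats every
#' `prescription_interval_days` (with Gaussian jitter, rounded to whole
#' days, floored at 1) until discontinuation (per-interval hazard),
#' death, or the study end.
#'
#' @param patients tibble from [generate_population()].
#' @param config a [sim_config()].
#' @return a tibble with columns `patient_id`, `drug`, `issue_date`.
#' @export
generate_prescribing <- function(patients, config) {
  config <- validate_sim_config(config)
  set.seed(config$seed + 1L)
  interval <- config$prescription_interval_days
  sdv <- config$prescription_interval_sd
  h <- config$discontinuation_hazard

  pairs <- purrr::map_dfr(dmard_drugs(), function(d) {
    prev <- unname(config$drug_prevalence[d])
    if (is.na(prev) || prev <= 0) return(tibble())
    on <- runif(nrow(patients)) < prev
    tibble(patient_id = patients$patient_id[on],
           death_date = patients$death_date[on],
           drug = d)
  })
  if (nrow(pairs) == 0) {
    return(tibble(patient_id = character(), drug = character(),
                  issue_date = as.Date(character())))
  }
  m <- nrow(pairs)
  pairs$first_issue <- config$study_start +
    sample.int(max(1L, floor(interval)), m, replace = TRUE) - 1L
  # issues before discontinuation: 1 + geometric(h) (h = 1 forces a
  # single issue; h = 0 continues to the study end)
  pairs$n_issues <- if (h >= 1) 1L else if (h <= 0) .Machine$integer.max else
    1L + rgeom(m, h)

  span <- as.numeric(config$study_end - config$study_start)
  K <- ceiling(span / max(1, interval - 3 * sdv)) + 2L
  gaps <- matrix(pmax(1, round(rnorm(m * (K - 1L), interval, sdv))),
                 nrow = m)
  offsets <- cbind(0, t(apply(gaps, 1L, cumsum)))

  long <- tibble(
    patient_id = rep(pairs$patient_id, each = K),
    drug = rep(pairs$drug, each = K),
    death_date = rep(pairs$death_date, each = K),
    n_issues = rep(pairs$n_issues, each = K),
    k = rep(seq_len(K), times = m),
    issue_date = rep(pairs$first_issue, each = K) + as.vector(t(offsets))
  )
  long |>
    filter(k <= n_issues,
           issue_date <= config$study_end,
           is.na(death_date) | issue_date <= death_date) |>
    select(patient_id, drug, issue_date) |>
    arrange(patient_id, drug, issue_date)
}

#' Monitoring due-window schedule implied by prescribing
#'
#' One monitoring cycle per patient: due dates are anchored at the
#' patient's first prescription (of any drug) and repeat every
#' `monitoring_interval_days` (default 91) while any course is active
#' (up to one interval past the last issue, clipped at the study end).
#' A single cycle per patient reflects that the blood panels required
#' by the different drugs are identical and drawn at one attendance.
#'
#' @param prescriptions tibble from [generate_prescribing()].
#' @param config a [sim_config()].
#' @return a tibble with columns `patient_id`, `window_index`,
#'   `due_date`.
#' @export
monitoring_schedule <- function(prescriptions, config) {
  interval <- config$monitoring_interval_days
  courses <- prescriptions |>
    group_by(patient_id) |>
    summarise(first_issue = min(issue_date), last_issue = max(issue_date),
              .groups = "drop") |>
    mutate(limit = pmin(last_issue + interval, config$study_end),
           n_windows = pmax(0L, floor(as.numeric(limit - first_issue) / interval)))
  courses <- filter(courses, n_windows > 0L)
  if (nrow(courses) == 0) {
    return(tibble(patient_id = character(),
                  window_index = integer(), due_date = as.Date(character())))
  }
  courses |>
    tidyr::uncount(n_windows, .id = "window_index") |>
    mutate(window_index = as.integer(window_index),
           due_date = first_issue + interval * window_index) |>
    select(patient_id, window_index, due_date) |>
    arrange(patient_id, window_index)
}

# additive logit shock at date(s) d: full inside the shock window,
# linear decay to zero across the recovery span
shock_logit_at <- function(d, config) {
  s <- numeric(length(d))
  inside <- d >= config$shock_start & d <= config$shock_end
  s[inside] <- config$lockdown_shock_logit
  span <- as.numeric(config$recovery_end - config$shock_end)
  if (span > 0) {
    dec <- d > config$shock_end & d <= config$recovery_end
    s[dec] <- config$lockdown_shock_logit *
      (1 - as.numeric(d[dec] - config$shock_end) / span)
  }
  s
}

patient_offsets <- function(patients, config) {
  off <- numeric(nrow(patients))
  for (g in names(config$subgroup_effects)) {
    eff <- config$subgroup_effects[[g]]
    val <- as.character(patients[[g]])
    hit <- !is.na(val) & val %in% names(eff)
    off[hit] <- off[hit] + unname(eff[val[hit]])
  }
  off
}

#' Generate synthetic monitoring-test events
#'
#' For every due window of every patient's monitoring cycle, attendance
#' is decided by a single uniform draw against the miss probability; an
#' attended window yields one event per required blood test (FBC, LFT,
#' UE) on one shared date near the due date. The blood-pressure check
#' is an independent draw with the extra BP miss offset added on the
#' logit scale, made only at windows where a leflunomide course is
#' active.
#'
#' @param patients tibble from [generate_population()].
#' @param prescriptions tibble from [generate_prescribing()].
#' @param config a [sim_config()].
#' @return a tibble with columns `patient_id`, `test_type`, `date`.
#' @export
generate_tests <- function(patients, prescriptions, config) {
  config <- validate_sim_config(config)
  set.seed(config$seed + 2L)

  practice_eff <- setNames(
    rnorm(config$n_practices) * config$practice_effect_sd,
    sprintf("gp%04d", seq_len(config$n_practices)))
  frailty <- setNames(rnorm(nrow(patients)) * config$patient_frailty_sd,
                      patients$patient_id)
  offs <- setNames(patient_offsets(patients, config), patients$patient_id)
  prac_of <- setNames(patients$practice_id, patients$patient_id)
  death_of <- setNames(patients$death_date, patients$patient_id)

  sched <- monitoring_schedule(prescriptions, config)
  if (nrow(sched) == 0) {
    return(tibble(patient_id = character(), test_type = character(),
                  date = as.Date(character())))
  }
  nr <- nrow(sched)
  jit <- round(rnorm(nr, 0, config$test_date_jitter_sd))
  u_blood <- runif(nr)
  u_bp <- runif(nr)

  lef_rx <- filter(prescriptions, drug == "leflunomide")
  lef_span <- if (nrow(lef_rx) > 0) {
    lef_rx |>
      group_by(patient_id) |>
      summarise(lef_first = min(issue_date),
                lef_limit = max(issue_date) + config$monitoring_interval_days,
                .groups = "drop")
  } else {
    tibble(patient_id = character(), lef_first = as.Date(character()),
           lef_limit = as.Date(character()))
  }

  sched <- sched |>
    left_join(lef_span, by = "patient_id") |>
    mutate(
      event_date = pmin(pmax(due_date + jit, config$study_start),
                        config$study_end),
      lin = config$baseline_miss_logit +
        unname(practice_eff[prac_of[patient_id]]) +
        unname(offs[patient_id]) +
        unname(frailty[patient_id]) +
        shock_logit_at(due_date, config),
      dd = as.Date(unname(death_of[patient_id])),
      alive = is.na(dd) | event_date <= dd,
      attend_blood = u_blood >= plogis(lin) & alive,
      attend_bp = !is.na(lef_first) &
        due_date >= lef_first & due_date <= lef_limit &
        u_bp >= plogis(lin + config$bp_extra_miss_logit) & alive
    )

  blood <- sched |>
    filter(attend_blood) |>
    select(patient_id, date = event_date) |>
    tidyr::crossing(test_type = c("FBC", "LFT", "UE"))
  bp <- sched |>
    filter(attend_bp) |>
    transmute(patient_id, date = event_date, test_type = "BP")

  bind_rows(blood, bp) |>
    distinct(patient_id, test_type, date) |>
    arrange(patient_id, date, test_type)
}

#' Simulate a complete synthetic EHR dataset
#'
#' Runs the three generators in sequence under the configured seed.
#' Identical configurations (including seed) give identical datasets.
#'
#' @param config a [sim_config()].
#' @return a `dmard_ehr` dataset with the configuration attached as the
#'   `"config"` attribute.
#' @export
simulate_ehr <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  patients <- generate_population(config)
  prescriptions <- generate_prescribing(patients, config)
  tests <- generate_tests(patients, prescriptions, config)
  new_ehr_data(patients, prescriptions, tests, config = config)
}
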