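# Simulation configuration: one declarative object holding every knob of
# the synthetic EHR generator. Defaults emulate the published cohort: a
# DMARD population with ~3-monthly repeat prescribing, three-monthly
# monitoring cycles, a transient lockdown disruption from 23 March 2020
# with linear recovery on the logit scale, practice-level random
# intercepts and demographic marginals matching the published cohort
# description.

.age_bands <- c("18-29", "30-39", "40-49", "50-59", "60-69", "70-79", "80+")
.age_band_lo <- c(18, 30, 40, 50, 60, 70, 80)
.age_band_hi <- c(29, 39, 49, 59, 69, 79, 94)
.ethnicities <- c("Black", "Mixed", "Other", "South Asian", "White")
.regions <- c("East", "East Midlands", "London", "North East", "North West",
              "South East", "South West", "West Midlands",
              "Yorkshire and The Humber")

default_demographics <- function() {
  norm <- function(x) x / sum(x)
  list(
    age_band = setNames(norm(c(3.7, 6.2, 10.1, 19.1, 23.7, 24.8, 12.4)), .age_bands),
    sex = c(female = 0.609, male = 0.391),
    ethnicity = setNames(norm(c(1.1, 0.7, 0.8, 5.5, 91.1)), .ethnicities),
    region = setNames(norm(c(24.4, 17.3, 3.2, 5.3, 8.3, 7.0, 16.1, 3.1, 15.0)),
                      .regions),
    imd_quintile = setNames(norm(c(16.0, 18.6, 22.4, 22.3, 20.7)), as.character(1:5)),
    rural_urban = setNames(norm(c(15.3, 6.5, 52.1, 0.3, 13.9, 0.7, 10.4, 0.9)),
                           as.character(1:8)),
    care_home = c(`TRUE` = 0.006, `FALSE` = 0.994),
    dementia = c(`TRUE` = 0.015, `FALSE` = 0.985),
    housebound = c(`TRUE` = 0.036, `FALSE` = 0.964),
    learning_disability = c(`TRUE` = 0.004, `FALSE` = 0.996),
    serious_mental_illness = c(`TRUE` = 0.010, `FALSE` = 0.990)
  )
}

default_subgroup_effects <- function() {
  # persistent logit offsets on the miss probability; younger patients,
  # London and more deprived quintiles miss more, mirroring the direction
  # of the between-group differences seen in national audits.
  list(
    age_band = c("18-29" = 0.5, "30-39" = 0.35, "40-49" = 0.2, "50-59" = 0.1,
                 "60-69" = 0, "70-79" = -0.05, "80+" = 0),
    region = c(London = 0.3, "North East" = -0.1, "North West" = 0.1),
    imd_quintile = c("1" = 0.2, "2" = 0.1, "3" = 0, "4" = -0.05, "5" = -0.1)
  )
}

#' Configuration for the synthetic EHR generator
#'
#' Bundles every parameter of the simulation into a single validated
#' object. All random behaviour of [simulate_ehr()] and the individual
#' generators is determined by `seed` together with these fields.
#'
#' @param n_patients,n_practices cohort size and number of GP practices.
#' @param study_start,study_end study window (Dates or `"YYYY-MM-DD"`).
#'   The defaults give a first full measure month of November 2019 and a
#'   final month of July 2022.
#' @param drug_prevalence named probabilities that a patient is on each
#'   drug (independent draws; a patient may be on several). Defaults
#'   mirror the relative per-drug denominator sizes of the published
#'   cohort (methotrexate dominant, leflunomide smallest).
#' @param prescription_interval_days,prescription_interval_sd mean and SD
#'   (days) of the gap between repeat issues; default 84 +/- 7.
#' @param discontinuation_hazard per-interval probability that a repeat
#'   course stops.
#' @param monitoring_interval_days spacing of monitoring due windows,
#'   anchored at each patient's first prescription; default 91.
#' @param baseline_miss_logit intercept (logit scale) of the per-window
#'   probability that a due monitoring attendance is missed.
#' @param bp_extra_miss_logit additional logit offset for the separate
#'   blood-pressure check (leflunomide patients only).
#' @param lockdown_shock_logit transient additive logit shock applied to
#'   the miss probability between `shock_start` and `shock_end`, decaying
#'   linearly (on the logit scale) to zero by `recovery_end`.
#' @param shock_start,shock_end,recovery_end disruption window; defaults
#'   23 Mar 2020, 30 Jun 2020, 30 Sep 2020.
#' @param practice_effect_sd SD of the practice random intercept (logit).
#' @param patient_frailty_sd SD of an optional patient-level random
#'   intercept (logit); default 0 (off).
#' @param test_date_jitter_sd SD (days) of jitter of the attendance date
#'   around the scheduled due date.
#' @param subgroup_effects named list `group -> named numeric vector`
#'   of logit offsets per category.
#' @param demographic_distributions named list of category probability
#'   vectors per demographic group; each must sum to 1.
#' @param missing_ethnicity_frac,missing_region_frac fractions recorded
#'   as missing for the two groups allowed to be missing.
#' @param missing_core_frac fraction of patients with a missing core
#'   field (sex / IMD / rurality / date of birth), default 0; used to
#'   exercise the data-quality exclusion rule.
#' @param death_prob probability a patient dies during the study.
#' @param seed integer seed controlling all generators.
#' @return an object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_patients = 5000L,
                       n_practices = 100L,
                       study_start = "2019-09-01",
                       study_end = "2022-07-31",
                       drug_prevalence = c(azathioprine = 0.27,
                                           leflunomide = 0.06,
                                           methotrexate = 0.67),
                       prescription_interval_days = 84,
                       prescription_interval_sd = 7,
                       discontinuation_hazard = 0.02,
                       monitoring_interval_days = 91,
                       baseline_miss_logit = qlogis(0.25),
                       bp_extra_miss_logit = 1.4,
                       lockdown_shock_logit = 0.55,
                       shock_start = "2020-03-23",
                       shock_end = "2020-06-30",
                       recovery_end = "2020-09-30",
                       practice_effect_sd = 0.8,
                       patient_frailty_sd = 0,
                       test_date_jitter_sd = 5,
                       subgroup_effects = default_subgroup_effects(),
                       demographic_distributions = default_demographics(),
                       missing_ethnicity_frac = 0.008,
                       missing_region_frac = 0.003,
                       missing_core_frac = 0,
                       death_prob = 0.01,
                       seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients), n_practices = as.integer(n_practices),
    study_start = as.Date(study_start), study_end = as.Date(study_end),
    drug_prevalence = drug_prevalence,
    prescription_interval_days = prescription_interval_days,
    prescription_interval_sd = prescription_interval_sd,
    discontinuation_hazard = discontinuation_hazard,
    monitoring_interval_days = monitoring_interval_days,
    baseline_miss_logit = baseline_miss_logit,
    bp_extra_miss_logit = bp_extra_miss_logit,
    lockdown_shock_logit = lockdown_shock_logit,
    shock_start = as.Date(shock_start), shock_end = as.Date(shock_end),
    recovery_end = as.Date(recovery_end),
    practice_effect_sd = practice_effect_sd,
    patient_frailty_sd = patient_frailty_sd,
    test_date_jitter_sd = test_date_jitter_sd,
    subgroup_effects = subgroup_effects,
    demographic_distributions = demographic_distributions,
    missing_ethnicity_frac = missing_ethnicity_frac,
    missing_region_frac = missing_region_frac,
    missing_core_frac = missing_core_frac,
    death_prob = death_prob,
    seed = as.integer(seed)
  )
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    abort(paste0("invalid configuration field `", field, "`: ", why),
          class = "dmardmon_config_error")
  }
  if (is.na(cfg$n_patients) || cfg$n_patients < 1) bad("n_patients", "must be a positive integer")
  if (is.na(cfg$n_practices) || cfg$n_practices < 1) bad("n_practices", "must be a positive integer")
  for (f in c("study_start", "study_end", "shock_start", "shock_end", "recovery_end")) {
    if (is.na(cfg[[f]])) bad(f, "not a valid date")
  }
  if (!(cfg$study_start < cfg$shock_start)) bad("shock_start", "must be after study_start")
  if (!(cfg$shock_start < cfg$shock_end)) bad("shock_end", "must be after shock_start")
  if (!(cfg$shock_end <= cfg$recovery_end)) bad("recovery_end", "must be on/after shock_end")
  if (!(cfg$recovery_end <= cfg$study_end)) bad("recovery_end", "must be on/before study_end")
  if (is.null(names(cfg$drug_prevalence)) ||
      !all(names(cfg$drug_prevalence) %in% dmard_drugs())) {
    bad("drug_prevalence", "names must be DMARD labels")
  }
  probs <- c(cfg$drug_prevalence, cfg$missing_ethnicity_frac,
             cfg$missing_region_frac, cfg$missing_core_frac, cfg$death_prob,
             cfg$discontinuation_hazard)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    bad("drug_prevalence/fractions", "all probabilities must lie in [0, 1]")
  }
  for (g in names(cfg$demographic_distributions)) {
    p <- cfg$demographic_distributions[[g]]
    if (any(p < 0) || any(p > 1)) bad(paste0("demographic_distributions$", g),
                                      "probabilities must lie in [0, 1]")
    if (abs(sum(p) - 1) > 1e-9) bad(paste0("demographic_distributions$", g),
                                    "category probabilities must sum to 1")
  }
  for (f in c("prescription_interval_days", "monitoring_interval_days")) {
    if (cfg[[f]] < 1) bad(f, "must be at least 1 day")
  }
  for (f in c("prescription_interval_sd", "practice_effect_sd",
              "patient_frailty_sd", "test_date_jitter_sd")) {
    if (cfg[[f]] < 0) bad(f, "must be non-negative")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  patients:", x$n_patients, " practices:", x$n_practices,
      " seed:", x$seed, "\n")
  cat("  study:", format(x$study_start), "..", format(x$study_end), "\n")
  cat("  shock:", format(x$shock_start), "..", format(x$shock_end),
      " recovery by", format(x$recovery_end),
      sprintf(" (logit +%.2f)", x$lockdown_shock_logit), "\n")
  cat("  baseline miss p:", sprintf("%.3f", plogis(x$baseline_miss_logit)), "\n")
  invisible(x)
}

# fields allowed in a YAML config file (flat keys; the nested lists keep
# their natural YAML mapping structure)
.config_file_keys <- c(
  "n_patients", "n_practices", "study_start", "study_end", "drug_prevalence",
  "prescription_interval_days", "prescription_interval_sd",
  "discontinuation_hazard", "monitoring_interval_days", "baseline_miss_logit",
  "bp_extra_miss_logit", "lockdown_shock_logit", "shock_start", "shock_end",
  "recovery_end", "practice_effect_sd", "patient_frailty_sd",
  "test_date_jitter_sd", "subgroup_effects", "demographic_distributions",
  "missing_ethnicity_frac", "missing_region_frac", "missing_core_frac",
  "death_prob", "seed"
)

#' Read a simulation configuration from a YAML file
#'
#' Keys mirror the arguments of [sim_config()]; absent keys take the
#' defaults, unknown keys are an error. `seed` (if given) overrides the
#' file's seed.
#'
#' @param path YAML file path.
#' @param seed optional integer overriding the file's seed.
#' @return a validated `sim_config`.
#' @export
read_sim_config <- function(path, seed = NULL) {
  if (!file.exists(path)) {
    abort(paste0("configuration file not found: ", path),
          class = "dmardmon_config_error")
  }
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .config_file_keys)
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration key(s): ", paste(unknown, collapse = ", ")),
          class = "dmardmon_config_error")
  }
  for (key in c("drug_prevalence")) {
    if (!is.null(raw[[key]])) raw[[key]] <- unlist(raw[[key]])
  }
  for (key in c("subgroup_effects", "demographic_distributions")) {
    if (!is.null(raw[[key]])) raw[[key]] <- lapply(raw[[key]], unlist)
  }
  if (!is.null(seed)) raw$seed <- as.integer(seed)
  do.call(sim_config, raw)
}
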