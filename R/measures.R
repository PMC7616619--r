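# Missed-monitoring indicators.
#
# For each index month and drug, the denominator is the set of eligible
# on-drug patients; a patient is in the numerator if any test required
# for the drug has no record in the 3-month lookback. Combined scopes
# sum patient-drug pairs (a patient on two drugs contributes twice).
# Reported counts are rounded to the nearest 5 (statistical disclosure
# control) before the percentage is formed; raw counts are retained for
# internal use and cross-checks.

#' Round a count to the nearest multiple of 5
#'
#' Disclosure-control rounding applied to every reported numerator and
#' denominator. Integer inputs never tie, so no tie-break rule is
#' needed.
#'
#' @param count non-negative integer count (vectorised).
#' @return nearest multiple of 5.
#' @export
round5 <- function(count) {
  if (any(is.na(count)) || any(count < 0)) {
    abort("round5() requires non-negative counts", class = "dmardmon_domain_error")
  }
  5 * round(count / 5)
}

#' Percentage from a numerator and denominator, reported to 1 decimal
#'
#' `100 * numerator / denominator`, rounded half away from zero to one
#' decimal place (the precision of every reported rate).
#'
#' @param numerator,denominator counts (vectorised).
#' @return percentage(s); `NA` where the denominator is 0 (an undefined
#'   rate, not an error).
#' @examples
#' aggregate_percentage(977354, 3146849) # 31.1
#' @export
aggregate_percentage <- function(numerator, denominator) {
  n <- length(numerator)
  d <- length(denominator)
  if (n != d) { # recycle to the common length
    len <- max(n, d)
    numerator <- rep_len(numerator, len)
    denominator <- rep_len(denominator, len)
  }
  out <- round_half_up(100 * numerator / denominator, 1L)
  out[denominator <= 0] <- NA_real_
  out
}

#' Percentage-point change between two rates
#'
#' @param rate_a,rate_b percentages in `[0, 100]`.
#' @return `rate_b - rate_a`, to one decimal place.
#' @examples
#' pp_change(28.4, 40.8) # +12.4
#' @export
pp_change <- function(rate_a, rate_b) {
  round_half_up(rate_b - rate_a, 1L)
}

#' Did a single patient miss monitoring for a drug at an index month?
#'
#' `TRUE` when at least one required test type has no event dated within
#' the closed 3-month lookback `[lookback_start, index_date]`.
#'
#' @param tests test tibble filtered to one patient.
#' @param drug a drug label.
#' @param index an index month.
#' @param test_set optional restriction of the required tests (for
#'   per-test indicators); must intersect the drug's requirements.
#' @return `TRUE` or `FALSE`.
#' @export
missed_for_drug <- function(tests, drug, index, test_set = NULL) {
  req <- scope_tests(drug, test_set)
  index <- as_index_month(index)
  inwin <- tests$date >= index$lookback_start & tests$date <= index$index_date
  present <- unique(tests$test_type[inwin])
  !all(req %in% present)
}

# required tests for a drug intersected with a requested test set;
# an empty intersection is a configuration error (e.g. BP is not a
# monitoring requirement for azathioprine)
scope_tests <- function(drug, test_set = NULL) {
  req <- required_tests(drug)
  if (is.null(test_set)) return(req)
  bad <- setdiff(test_set, monitoring_tests())
  if (length(bad) > 0) {
    abort(paste0("unknown test label: ", paste(bad, collapse = ", ")),
          class = "dmardmon_config_error")
  }
  out <- intersect(req, test_set)
  if (length(out) == 0) {
    abort(paste0("test set {", paste(test_set, collapse = ", "),
                 "} contains no monitoring requirement of ", drug),
          class = "dmardmon_config_error")
  }
  out
}

#' Per-patient indicator events for one index month
#'
#' The engine behind every aggregate: one row per patient-drug pair in
#' the denominator, with a logical `missed` flag.
#'
#' @param data a `dmard_ehr` dataset.
#' @param index an index month.
#' @param drugs drug labels defining the scope (default: all three).
#' @param test_set optional per-test restriction (see
#'   [missed_for_drug()]).
#' @return tibble with columns `month`, `patient_id`, `drug`, `missed`.
#' @export
indicator_events <- function(data, index, drugs = dmard_drugs(),
                             test_set = NULL) {
  index <- as_index_month(index)
  events_from_frame(month_frame(data, index), drugs, test_set, index$label)
}

# everything one month's scopes need: per-drug denominators and the
# distinct (patient, test_type) records inside the lookback
month_frame <- function(data, index) {
  index <- as_index_month(index)
  elig_ids <- data$patients$patient_id[is_eligible(data$patients, index)]
  present <- data$tests |>
    filter(date >= index$lookback_start, date <= index$index_date) |>
    distinct(patient_id, test_type)
  denoms <- purrr::map_dfr(dmard_drugs(), function(d) {
    tibble(patient_id = intersect(on_drug_ids(data$prescriptions, d, index),
                                  elig_ids),
           drug = d)
  })
  list(label = index$label, denoms = denoms, present = present)
}

events_from_frame <- function(frame, drugs, test_set, label = frame$label) {
  if (length(drugs) == 0) {
    abort("at least one drug is required", class = "dmardmon_config_error")
  }
  purrr::map_dfr(drugs, function(d) {
    req <- scope_tests(d, test_set)
    denom <- frame$denoms$patient_id[frame$denoms$drug == d]
    if (length(denom) == 0) {
      return(tibble(month = character(), patient_id = character(),
                    drug = character(), missed = logical()))
    }
    n_present <- frame$present |>
      filter(patient_id %in% denom, test_type %in% req) |>
      count(patient_id)
    full <- n_present$patient_id[n_present$n == length(req)]
    tibble(month = label, patient_id = denom, drug = d,
           missed = !(denom %in% full))
  })
}

summarise_events <- function(events, label, drugs, test_set, group = NA_character_,
                             category = NA_character_) {
  num <- sum(events$missed)
  den <- nrow(events)
  tibble(
    month = label,
    drugs = paste(sort(drugs), collapse = "+"),
    tests = if (is.null(test_set)) "all" else paste(sort(test_set), collapse = "+"),
    group = group, category = category,
    numerator = num, denominator = den,
    numerator_rounded = round5(num), denominator_rounded = round5(den),
    percentage = aggregate_percentage(round5(num), round5(den))
  )
}

#' Monthly missed-monitoring indicator for one scope
#'
#' Computes the numerator and denominator for one index month over a set
#' of drugs (patient-drug pairs; a patient on two drugs counts twice),
#' optionally restricted to a per-test scope and/or one subgroup
#' category, then applies disclosure rounding to both counts before the
#' percentage.
#'
#' @inheritParams indicator_events
#' @param group optional patient column name (e.g. `"sex"`).
#' @param category value of `group` defining the subgroup.
#' @return a one-row tibble: `month`, `drugs`, `tests`, `group`,
#'   `category`, raw and rounded counts, and `percentage` (from the
#'   rounded counts; `NA` when the rounded denominator is 0).
#' @export
monthly_indicator <- function(data, index, drugs = dmard_drugs(),
                              test_set = NULL, group = NULL, category = NULL) {
  index <- as_index_month(index)
  ev <- indicator_events(data, index, drugs, test_set)
  if (!is.null(group)) {
    if (!group %in% names(data$patients)) {
      abort(paste0("unknown subgroup column: ", group),
            class = "dmardmon_config_error")
    }
    keep <- data$patients$patient_id[
      !is.na(data$patients[[group]]) &
        as.character(data$patients[[group]]) == as.character(category)]
    ev <- filter(ev, patient_id %in% keep)
  }
  summarise_events(ev, index$label, drugs, test_set,
                   group = if (is.null(group)) NA_character_ else group,
                   category = if (is.null(category)) NA_character_ else
                     as.character(category))
}

#' Monthly indicator series
#'
#' One [monthly_indicator()] row per calendar month between `start` and
#' `end` inclusive. The 3-month rolling behaviour is inherent in each
#' month's lookback; no post-hoc smoothing is applied.
#'
#' @inheritParams monthly_indicator
#' @param start,end first and last index months (`"YYYY-MM"`).
#' @return tibble with one row per month (per category when `group` is
#'   given without `category`).
#' @export
monthly_series <- function(data, start, end, drugs = dmard_drugs(),
                           test_set = NULL, group = NULL, category = NULL) {
  months_list <- seq_index_months(start, end)
  if (!is.null(group) && is.null(category)) {
    cats <- category_levels(data$patients, group)
    return(purrr::map_dfr(cats, function(cat) {
      purrr::map_dfr(months_list, monthly_indicator, data = data,
                     drugs = drugs, test_set = test_set,
                     group = group, category = cat)
    }))
  }
  purrr::map_dfr(months_list, monthly_indicator, data = data, drugs = drugs,
                 test_set = test_set, group = group, category = category)
}

#' Cumulative totals and the repeat-miss ratio
#'
#' Sums unrounded patient-month events over all months in the range
#' (a patient missing in several months counts once per month), counts
#' distinct patients with at least one missed event, and reports the
#' events-to-unique-patients ratio.
#'
#' @inheritParams monthly_series
#' @return one-row tibble: `total_events`, `total_denominator_events`,
#'   `unique_patients`, `repeat_ratio` (`NA` when no patient ever
#'   missed).
#' @export
cumulative_totals <- function(data, start, end, drugs = dmard_drugs(),
                              test_set = NULL) {
  ev <- purrr::map_dfr(seq_index_months(start, end), indicator_events,
                       data = data, drugs = drugs, test_set = test_set)
  uniq <- n_distinct(ev$patient_id[ev$missed])
  tibble(
    total_events = sum(ev$missed),
    total_denominator_events = nrow(ev),
    unique_patients = uniq,
    repeat_ratio = if (uniq > 0) sum(ev$missed) / uniq else NA_real_
  )
}

# canonical category orderings for the standard grouping columns
category_levels <- function(patients, group) {
  known <- list(
    age_band = .age_bands,
    sex = c("female", "male"),
    ethnicity = c(.ethnicities, NA),
    region = c(.regions, NA),
    imd_quintile = as.character(1:5),
    rural_urban = as.character(1:8)
  )
  if (group %in% names(known)) {
    lv <- known[[group]]
    lv[!is.na(lv)]
  } else if (is.logical(patients[[group]])) {
    c("TRUE", "FALSE")
  } else {
    sort(unique(as.character(patients[[group]])))
  }
}

#' Subgroup columns summarised by default
#' @return character vector of patient-table column names.
#' @export
subgroup_columns <- function() {
  c("age_band", "sex", "ethnicity", "region", "imd_quintile", "rural_urban",
    "care_home", "dementia", "housebound", "learning_disability",
    "serious_mental_illness")
}

#' Cohort description at one index month
#'
#' Describes the patients included in at least one drug denominator at
#' the index month: per-category counts rounded to the nearest 5, with
#' percentages computed as a proportion of the rounded subgroup total
#' (so the published convention is matched exactly). Missing ethnicity
#' or region is reported as the category `"missing"`; zero-count
#' categories are retained.
#'
#' @param data a `dmard_ehr` dataset.
#' @param index an index month.
#' @param groups patient columns to summarise (default
#'   [subgroup_columns()]).
#' @return tibble with columns `group`, `category`, `n` (rounded),
#'   `percentage`.
#' @export
cohort_summary <- function(data, index, groups = subgroup_columns()) {
  index <- as_index_month(index)
  ids <- unique(unlist(lapply(dmard_drugs(), drug_denominator,
                              data = data, index = index)))
  cohort <- filter(data$patients, patient_id %in% ids)

  total <- tibble(group = "population", category = "total",
                  n = round5(nrow(cohort)), percentage = 100.0)
  rows <- purrr::map_dfr(groups, function(g) {
    vals <- as.character(cohort[[g]])
    vals[is.na(vals)] <- "missing"
    lv <- category_levels(data$patients, g)
    if (any(vals == "missing")) lv <- c(lv, "missing")
    cnt <- table(factor(vals, levels = lv))
    nr <- round5(as.integer(cnt))
    tibble(group = g, category = names(cnt), n = nr,
           percentage = if (sum(nr) > 0)
             aggregate_percentage(nr, sum(nr)) else rep(NA_real_, length(nr)))
  })
  bind_rows(total, rows)
}
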