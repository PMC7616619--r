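# Between-practice variation and inferential statistics: per-practice
# indicator rates summarised as deciles, a two-proportion z-test for the
# period-to-period change in an aggregate rate, and Cochran's Q for
# heterogeneity of subgroup changes.

#' Per-practice missed-monitoring rates at one index month
#'
#' Each practice's numerator and denominator are disclosure-rounded
#' exactly as in [monthly_indicator()]; practices whose rounded
#' denominator is 0 are excluded.
#'
#' @inheritParams indicator_events
#' @return tibble with columns `practice_id`, `numerator_rounded`,
#'   `denominator_rounded`, `rate` (percent).
#' @export
practice_rates <- function(data, index, drugs = dmard_drugs(),
                           test_set = NULL) {
  ev <- indicator_events(data, index, drugs, test_set) |>
    left_join(select(data$patients, patient_id, practice_id),
              by = "patient_id")
  ev |>
    group_by(practice_id) |>
    summarise(numerator_rounded = round5(sum(missed)),
              denominator_rounded = round5(n()), .groups = "drop") |>
    filter(denominator_rounded > 0) |>
    mutate(rate = aggregate_percentage(numerator_rounded, denominator_rounded)) |>
    arrange(practice_id)
}

#' Deciles of a collection of practice rates
#'
#' The nine deciles at probabilities 0.1 to 0.9, by linear interpolation
#' between order statistics (`stats::quantile()` type 7).
#'
#' @param rates numeric vector of percentages; at least 2 values.
#' @return one-row tibble `d1` .. `d9`, `median_rate` (= `d5`),
#'   `interdecile_range` (= `d9 - d1`), `n_practices`.
#' @export
deciles <- function(rates) {
  rates <- rates[!is.na(rates)]
  if (length(rates) < 2) {
    abort("at least 2 rates are needed to compute deciles",
          class = "dmardmon_insufficient_data")
  }
  q <- unname(quantile(rates, probs = seq(0.1, 0.9, by = 0.1), type = 7))
  out <- as_tibble(as.list(setNames(q, paste0("d", 1:9))))
  out$median_rate <- out$d5
  out$interdecile_range <- out$d9 - out$d1
  out$n_practices <- length(rates)
  out
}

#' Monthly practice-decile series
#'
#' @inheritParams monthly_series
#' @return tibble with one row per month: `month`, `d1` .. `d9`,
#'   `median_rate`, `interdecile_range`, `n_practices`.
#' @export
practice_decile_series <- function(data, start, end, drugs = dmard_drugs(),
                                   test_set = NULL) {
  purrr::map_dfr(seq_index_months(start, end), function(ix) {
    pr <- practice_rates(data, ix, drugs, test_set)
    if (nrow(pr) < 2) {
      return(tibble(month = ix$label))
    }
    bind_cols(tibble(month = ix$label), deciles(pr$rate))
  })
}

#' Two-proportion z-test for a change in an aggregate rate
#'
#' Tests whether the missed-monitoring proportion changed between two
#' periods, using the normal approximation with pooled variance for the
#' statistic and a Wald (unpooled) 95% interval for the
#' percentage-point difference. This is the test applied to aggregate
#' (disclosure-rounded) counts; a practice-level two-sample alternative
#' is [change_test_practice()].
#'
#' @param n1,x1 denominator and numerator in the first period.
#' @param n2,x2 denominator and numerator in the second period.
#' @return an object of class `dmard_change_test` with elements
#'   `statistic`, `p_value`, `estimate` (percentage points, period 2
#'   minus period 1), `conf_low`, `conf_high`, and the inputs.
#' @export
change_test <- function(n1, x1, n2, x2) {
  if (any(c(n1, n2) <= 0) || any(is.na(c(n1, x1, n2, x2)))) {
    abort("both periods need a positive denominator",
          class = "dmardmon_insufficient_data")
  }
  if (x1 > n1 || x2 > n2 || x1 < 0 || x2 < 0) {
    abort("numerators must lie in [0, denominator]",
          class = "dmardmon_domain_error")
  }
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se_pooled <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se_pooled == 0) 0 else (p2 - p1) / se_pooled
  se_wald <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  est <- 100 * (p2 - p1)
  structure(
    list(statistic = z, p_value = 2 * pnorm(-abs(z)),
         estimate = est,
         conf_low = est - 100 * qnorm(0.975) * se_wald,
         conf_high = est + 100 * qnorm(0.975) * se_wald,
         p1 = p1, p2 = p2, n1 = n1, n2 = n2,
         method = "two-proportion z-test (pooled variance)"),
    class = "dmard_change_test"
  )
}

#' Practice-level two-sample change test
#'
#' Welch two-sample t-test comparing per-practice rates between two
#' periods; an alternative view of the same change where the unit of
#' analysis is the practice rather than the aggregate count.
#'
#' @param rates1,rates2 numeric vectors of practice rates (percent).
#' @return an object of class `dmard_change_test`.
#' @export
change_test_practice <- function(rates1, rates2) {
  if (length(rates1) < 2 || length(rates2) < 2) {
    abort("at least 2 practice rates per period are needed",
          class = "dmardmon_insufficient_data")
  }
  tt <- stats::t.test(rates2, rates1)
  structure(
    list(statistic = unname(tt$statistic), p_value = tt$p.value,
         estimate = unname(tt$estimate[1] - tt$estimate[2]),
         conf_low = tt$conf.int[1], conf_high = tt$conf.int[2],
         p1 = mean(rates1) / 100, p2 = mean(rates2) / 100,
         n1 = length(rates1), n2 = length(rates2),
         method = "Welch two-sample t-test on practice rates"),
    class = "dmard_change_test"
  )
}

#' Per-category rate changes for one subgroup family
#'
#' For every category of a patient subgroup, computes the
#' disclosure-rounded rates at a baseline and a comparison month, the
#' percentage-point change, and its sampling variance
#' `p1 (1 - p1) / n1 + p2 (1 - p2) / n2` (proportion scale), with
#' proportions clamped to `[0.5/n, 1 - 0.5/n]` so no weight degenerates.
#'
#' @param data a `dmard_ehr` dataset.
#' @param group patient column name (e.g. `"region"`).
#' @param baseline,comparison the two index months.
#' @param drugs drug scope (default all three).
#' @param min_denominator categories whose rounded denominator falls
#'   below this in either period are dropped (default 1, i.e. only
#'   empty categories are dropped).
#' @return tibble: `group`, `category`, `p1`, `p2`, `n1`, `n2`, `delta`
#'   (percentage points), `variance` (proportion scale).
#' @export
subgroup_deltas <- function(data, group, baseline, comparison,
                            drugs = dmard_drugs(), min_denominator = 1) {
  per_period <- function(ix) {
    monthly_series(data, ix, ix, drugs = drugs, group = group) |>
      select(category, numerator_rounded, denominator_rounded)
  }
  b <- per_period(baseline)
  c2 <- per_period(comparison)
  out <- inner_join(b, c2, by = "category", suffix = c("_1", "_2")) |>
    filter(denominator_rounded_1 >= min_denominator,
           denominator_rounded_2 >= min_denominator,
           denominator_rounded_1 > 0, denominator_rounded_2 > 0) |>
    mutate(
      group = group,
      n1 = denominator_rounded_1, n2 = denominator_rounded_2,
      p1 = pmin(pmax(numerator_rounded_1 / n1, 0.5 / n1), 1 - 0.5 / n1),
      p2 = pmin(pmax(numerator_rounded_2 / n2, 0.5 / n2), 1 - 0.5 / n2),
      delta = 100 * (p2 - p1),
      variance = p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2
    ) |>
    select(group, category, p1, p2, n1, n2, delta, variance)
  out
}

#' Cochran's Q heterogeneity test over subgroup changes
#'
#' Tests whether the percentage-point changes differ across the
#' categories of one subgroup family. With inverse-variance weights
#' `w_i = 1 / variance_i`, `Q = sum w_i (d_i - d_bar)^2` where `d_bar`
#' is the weighted mean change; under homogeneity Q is chi-squared with
#' `k - 1` degrees of freedom. `delta` is taken in percentage points
#' and `variance` on the proportion scale, as produced by
#' [subgroup_deltas()]; the scales are reconciled internally (Q is
#' invariant to any common rescaling of the weights).
#'
#' @param deltas tibble with columns `delta` and `variance` (one row per
#'   category), e.g. from [subgroup_deltas()].
#' @return an object of class `dmard_cochran_q` with elements `Q`, `df`,
#'   `p_value`, `k` and the weighted mean change `mean_delta`
#'   (percentage points).
#' @export
cochran_q <- function(deltas) {
  k <- nrow(deltas)
  if (is.null(k) || k < 2) {
    abort("Cochran's Q needs at least 2 categories",
          class = "dmardmon_insufficient_data")
  }
  if (any(is.na(deltas$variance)) || any(deltas$variance <= 0)) {
    abort("all category variances must be positive",
          class = "dmardmon_data_error")
  }
  d <- deltas$delta / 100 # back to the proportion scale of the variances
  w <- 1 / deltas$variance
  dbar <- sum(w * d) / sum(w)
  Q <- sum(w * (d - dbar)^2)
  structure(
    list(Q = Q, df = k - 1L,
         p_value = pchisq(Q, df = k - 1L, lower.tail = FALSE),
         k = k, mean_delta = 100 * dbar),
    class = "dmard_cochran_q"
  )
}

#' Heterogeneity of change across several subgroup families
#'
#' Runs [subgroup_deltas()] and [cochran_q()] for each listed family.
#'
#' @inheritParams subgroup_deltas
#' @param groups patient column names (default [subgroup_columns()]).
#' @return tibble: `group`, `k`, `Q`, `df`, `p_value`, `mean_delta`.
#' @export
heterogeneity_by_group <- function(data, baseline, comparison,
                                   groups = subgroup_columns(),
                                   drugs = dmard_drugs()) {
  purrr::map_dfr(groups, function(g) {
    sd_ <- subgroup_deltas(data, g, baseline, comparison, drugs = drugs)
    if (nrow(sd_) < 2) {
      return(tibble(group = g, k = nrow(sd_), Q = NA_real_, df = NA_integer_,
                    p_value = NA_real_, mean_delta = NA_real_))
    }
    q <- cochran_q(sd_)
    tibble(group = g, k = q$k, Q = q$Q, df = q$df, p_value = q$p_value,
           mean_delta = q$mean_delta)
  })
}
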