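ix <- index_month(2020, 5)

test_that("round5 rounds to the nearest multiple of five", {
  expect_equal(round5(12), 10)
  expect_equal(round5(13), 15)
  expect_equal(round5(0), 0)
  expect_equal(round5(c(1, 2, 3, 7, 8, 997354)), c(0, 0, 5, 5, 10, 997355))
  expect_error(round5(-1), class = "dmardmon_domain_error")
})

test_that("percentages use half-up rounding to one decimal", {
  expect_equal(aggregate_percentage(977354, 3146849), 31.1)
  expect_equal(aggregate_percentage(125850, 193665), 65.0)
  expect_equal(aggregate_percentage(0, 100), 0.0)
  expect_equal(aggregate_percentage(1, 1000), 0.1)
  expect_equal(aggregate_percentage(25, 1000), 2.5) # exact .x5 stays
  expect_equal(aggregate_percentage(5, 16), 31.3)   # 31.25 rounds up
  expect_true(is.na(aggregate_percentage(5, 0)))
})

test_that("pp_change is an oriented one-decimal difference", {
  expect_equal(pp_change(28.4, 40.8), 12.4)
  expect_equal(pp_change(40.8, 28.1), -12.7)
  expect_equal(pp_change(33.3, 33.3), 0.0)
})

test_that("missed_for_drug checks every required test in the lookback", {
  # leflunomide with bloods but no BP is missed
  bloods <- tibble::tibble(patient_id = "p1",
                           test_type = c("FBC", "LFT", "UE"),
                           date = as.Date("2020-04-15"))
  expect_true(missed_for_drug(bloods, "leflunomide", ix))
  expect_false(missed_for_drug(bloods, "methotrexate", ix))

  # tests on the index date itself count (inclusive boundary)
  on_index <- make_panel("p1", "leflunomide", ix$index_date)
  expect_false(missed_for_drug(on_index, "leflunomide", ix))
  on_lb_start <- make_panel("p1", "leflunomide", ix$lookback_start)
  expect_false(missed_for_drug(on_lb_start, "leflunomide", ix))
  day_before <- make_panel("p1", "leflunomide", ix$lookback_start - 1)
  expect_true(missed_for_drug(day_before, "leflunomide", ix))

  expect_true(missed_for_drug(empty_tests(), "methotrexate", ix))

  # per-test scope restriction
  expect_false(missed_for_drug(bloods, "leflunomide", ix, test_set = "FBC"))
  expect_error(missed_for_drug(bloods, "azathioprine", ix, test_set = "BP"),
               class = "dmardmon_config_error")
})

test_that("monthly_indicator rounds both counts before the percentage", {
  # 13 patient-drug pairs, 7 missed -> rounded 5/15 -> 33.3%
  pats <- make_patients(13)
  rx <- purrr::map_dfr(pats$patient_id, make_issues,
                       drug = "azathioprine", last = ix$index_date - 20, k = 4)
  tested <- pats$patient_id[8:13]
  tst <- purrr::map_dfr(tested, make_panel, drug = "azathioprine",
                        date = ix$index_date - 10)
  data <- ehr_data(pats, rx, tst)
  res <- monthly_indicator(data, ix, drugs = "azathioprine")
  expect_equal(res$numerator, 7)
  expect_equal(res$denominator, 13)
  expect_equal(res$numerator_rounded, 5)
  expect_equal(res$denominator_rounded, 15)
  expect_equal(res$percentage, 33.3)
  # matches the brute-force oracle
  o <- o_indicator(pats, rx, tst, 2020, 5, drugs = "azathioprine")
  expect_equal(res$numerator, o$numerator)
  expect_equal(res$denominator, o$denominator)

  # all monitored -> 0.0
  tst_all <- purrr::map_dfr(pats$patient_id, make_panel,
                            drug = "azathioprine", date = ix$index_date - 10)
  res0 <- monthly_indicator(ehr_data(pats, rx, tst_all), ix,
                            drugs = "azathioprine")
  expect_equal(res0$percentage, 0.0)

  # BP is not a requirement of azathioprine
  expect_error(monthly_indicator(data, ix, drugs = "azathioprine",
                                 test_set = "BP"),
               class = "dmardmon_config_error")
  expect_error(monthly_indicator(data, ix, drugs = character(0)),
               class = "dmardmon_config_error")
})

test_that("combined scopes sum patient-drug pairs and per-test numerators nest", {
  set.seed(5)
  d <- simulate_ehr(micro_config(5, n_patients = 150))
  for (m in c("2020-02", "2020-05")) {
    overall <- monthly_indicator(d, m)
    per_drug <- purrr::map_dfr(dmard_drugs(), function(dr) {
      monthly_indicator(d, m, drugs = dr)
    })
    expect_equal(overall$denominator, sum(per_drug$denominator))
    expect_equal(overall$numerator, sum(per_drug$numerator))
    # each single-test numerator is at most the all-tests numerator
    for (t in c("FBC", "LFT", "UE")) {
      per_test <- monthly_indicator(d, m, test_set = t)
      expect_lte(per_test$numerator, overall$numerator)
      expect_equal(per_test$denominator, overall$denominator)
    }
  }
})

test_that("monthly_series is one indicator per month and is translation-equivariant", {
  pats <- make_patients(8)
  rx <- purrr::map_dfr(pats$patient_id, make_issues,
                       drug = "methotrexate", last = as.Date("2020-05-10"), k = 6)
  tst <- purrr::map_dfr(pats$patient_id[1:4], make_panel,
                        drug = "methotrexate", date = as.Date("2020-04-20"))
  data <- ehr_data(pats, rx, tst)

  one <- monthly_series(data, "2020-05", "2020-05", drugs = "methotrexate")
  expect_equal(nrow(one), 1)
  expect_equal(one, monthly_indicator(data, "2020-05", drugs = "methotrexate"))

  s <- monthly_series(data, "2020-01", "2020-06", drugs = "methotrexate")
  expect_equal(s$month, sprintf("2020-0%d", 1:6))

  # shifting all events forward one month shifts the series one month
  shift <- function(d) lubridate::`%m+%`(d, months(1))
  data2 <- ehr_data(pats,
                    dplyr::mutate(rx, issue_date = shift(issue_date)),
                    dplyr::mutate(tst, date = shift(date)))
  s2 <- monthly_series(data2, "2020-02", "2020-07", drugs = "methotrexate")
  expect_equal(s2$numerator, s$numerator)
  expect_equal(s2$denominator, s$denominator)
})

test_that("cumulative totals count patient-months and unique patients", {
  # one patient missing in three consecutive months
  pats <- make_patients(1)
  rx <- make_issues("p000001", "methotrexate", as.Date("2020-06-10"), k = 8)
  data <- ehr_data(pats, rx, empty_tests())
  ct <- cumulative_totals(data, "2020-03", "2020-05", drugs = "methotrexate")
  expect_equal(ct$total_events, 3)
  expect_equal(ct$unique_patients, 1)
  expect_equal(ct$repeat_ratio, 3.0)

  # fully monitored -> no events, undefined ratio
  tst <- purrr::map_dfr(as.character(seq(as.Date("2019-12-01"),
                                         as.Date("2020-06-01"), by = "61 days")),
                        function(dt) make_panel("p000001", "methotrexate", dt))
  ct0 <- cumulative_totals(ehr_data(pats, rx, tst), "2020-03", "2020-05",
                           drugs = "methotrexate")
  expect_equal(ct0$total_events, 0)
  expect_true(is.na(ct0$repeat_ratio))

  # known per-month misses equal the explicit enumeration
  set.seed(9)
  d <- simulate_ehr(micro_config(9, n_patients = 60))
  months <- c("2020-01", "2020-02", "2020-03")
  per_month <- purrr::map(months, function(m) {
    ev <- indicator_events(d, m)
    ev[ev$missed, c("patient_id", "drug")]
  })
  ct2 <- cumulative_totals(d, months[1], months[3])
  expect_equal(ct2$total_events, sum(purrr::map_int(per_month, nrow)))
  expect_equal(ct2$unique_patients,
               dplyr::n_distinct(dplyr::bind_rows(per_month)$patient_id))
})

test_that("rounding perturbs each reported rate by a bounded amount", {
  set.seed(21)
  d <- simulate_ehr(micro_config(21, n_patients = 180))
  s <- monthly_series(d, "2020-01", "2020-08")
  s <- s[s$denominator > 0, ]
  raw <- 100 * s$numerator / s$denominator
  bound <- 100 * (2.5 / s$denominator + 2.5 * s$numerator / s$denominator^2)
  expect_true(all(abs(s$percentage - raw) <= bound + 0.05)) # 0.05 = display rounding
})

test_that("cohort_summary rounds counts and uses the rounded subgroup total", {
  # counts {female 57620, male 36990} -> female 60.9%
  expect_equal(aggregate_percentage(57620, 57620 + 36990), 60.9)

  set.seed(13)
  d <- simulate_ehr(micro_config(13, n_patients = 200))
  cs <- cohort_summary(d, "2020-05")
  sexes <- cs[cs$group == "sex", ]
  expect_setequal(sexes$category, c("female", "male"))
  expect_true(all(sexes$n %% 5 == 0))
  expect_equal(sexes$percentage,
               aggregate_percentage(sexes$n, sum(sexes$n)))
  # single-category group: 100%
  allf <- d
  allf$patients$sex <- "female"
  cs2 <- cohort_summary(allf, "2020-05", groups = "sex")
  expect_equal(cs2$percentage[cs2$category == "female"], 100.0)
  expect_equal(cs2$percentage[cs2$category == "male"], 0.0) # retained at 0
})
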