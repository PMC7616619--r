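test_that("practice rates equal the per-practice brute-force indicator", {
  set.seed(17)
  d <- simulate_ehr(micro_config(17, n_patients = 200,
                                 n_practices = 20))
  pr <- practice_rates(d, "2020-04")
  expect_true(all(pr$denominator_rounded %% 5 == 0))
  for (gp in pr$practice_id) {
    sub_ids <- d$patients$patient_id[d$patients$practice_id == gp]
    o <- o_indicator(d$patients[d$patients$patient_id %in% sub_ids, ],
                     d$prescriptions[d$prescriptions$patient_id %in% sub_ids, ],
                     d$tests[d$tests$patient_id %in% sub_ids, ],
                     2020, 4)
    row <- pr[pr$practice_id == gp, ]
    expect_equal(row$numerator_rounded, round5(o$numerator))
    expect_equal(row$denominator_rounded, round5(o$denominator))
    expect_equal(row$rate, aggregate_percentage(round5(o$numerator),
                                                round5(o$denominator)))
  }
  # practices with a zero rounded denominator are excluded
  expect_true(all(pr$denominator_rounded > 0))
})

test_that("deciles follow linear order-statistic interpolation", {
  # 11 equally spaced values land on the data points
  d1 <- deciles(seq(0, 100, by = 10))
  expect_equal(unlist(d1[paste0("d", 1:9)], use.names = FALSE),
               seq(10, 90, by = 10))
  expect_equal(d1$median_rate, 50)
  expect_equal(d1$interdecile_range, 80)

  # constant input: every decile equals the constant
  dc <- deciles(rep(42.0, 25))
  expect_true(all(unlist(dc[paste0("d", 1:9)]) == 42))

  # 37 random rates match the independent oracle, in any input order
  set.seed(23)
  x <- runif(37, 0, 100)
  da <- deciles(x)
  db <- deciles(sample(x))
  expect_equal(unlist(da[paste0("d", 1:9)], use.names = FALSE), o_deciles(x))
  expect_equal(da, db)

  expect_error(deciles(5), class = "dmardmon_insufficient_data")
  # monotone by construction
  s <- simulate_ehr(micro_config(25, n_patients = 200, n_practices = 15))
  ds <- practice_decile_series(s, "2020-02", "2020-05")
  for (i in seq_len(nrow(ds))) {
    q <- unlist(ds[i, paste0("d", 1:9)])
    expect_true(all(diff(q) >= 0))
    expect_true(all(q >= 0 & q <= 100))
  }
})

test_that("the change test matches the closed-form pooled z", {
  t0 <- change_test(1000, 284, 1000, 284)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)

  t1 <- change_test(1000, 284, 1000, 408)
  o <- o_ztest(1000, 284, 1000, 408)
  expect_equal(t1$statistic, o$z)
  expect_equal(t1$p_value, o$p)
  expect_equal(t1$estimate, 12.4)
  expect_gt(t1$statistic, 0) # orientation: rise gives positive statistic
  expect_true(t1$conf_low < t1$estimate && t1$estimate < t1$conf_high)

  # independent cross-check: z^2 equals the uncorrected chi-square test
  pt <- prop.test(c(284, 408), c(1000, 1000), correct = FALSE)
  expect_equal(t1$statistic^2, unname(pt$statistic))
  expect_equal(t1$p_value, pt$p.value)

  fall <- change_test(1000, 408, 1000, 284)
  expect_lt(fall$statistic, 0)
  expect_lt(fall$estimate, 0)

  expect_error(change_test(0, 0, 100, 10), class = "dmardmon_insufficient_data")
  expect_error(change_test(100, 110, 100, 10), class = "dmardmon_domain_error")

  td <- tidy(t1)
  expect_equal(td$estimate, t1$estimate)
  expect_equal(td$p.value, t1$p_value)
  expect_equal(glance(t1)$n1, 1000)
})

test_that("the practice-level change test matches t.test", {
  set.seed(3)
  r1 <- runif(30, 10, 40)
  r2 <- runif(30, 20, 60)
  ct <- change_test_practice(r1, r2)
  tt <- t.test(r2, r1)
  expect_equal(ct$statistic, unname(tt$statistic))
  expect_equal(ct$p_value, tt$p.value)
  expect_equal(ct$estimate, mean(r2) - mean(r1))
})

test_that("Cochran's Q matches the direct formula and its invariances", {
  # identical deltas: Q = 0, p = 1
  same <- tibble::tibble(delta = rep(7.5, 4), variance = c(1, 2, 3, 4) * 1e-3)
  q0 <- cochran_q(same)
  expect_equal(q0$Q, 0)
  expect_equal(q0$p_value, 1)
  expect_equal(q0$df, 3)

  # k = 2, equal variances, deltas +d/-d (proportion scale d = 0.05):
  # weighted mean 0, Q = 2 d^2 / v
  two <- tibble::tibble(delta = c(5, -5), variance = c(0.001, 0.001))
  q2 <- cochran_q(two)
  expect_equal(q2$Q, 2 * 0.05^2 / 0.001)
  expect_equal(q2$p_value, pchisq(q2$Q, 1, lower.tail = FALSE))

  # uniform rescaling of the weights leaves Q unchanged
  set.seed(31)
  rnd <- tibble::tibble(delta = rnorm(6, 10, 3),
                        variance = runif(6, 1e-4, 1e-3))
  qa <- cochran_q(rnd)
  qb <- cochran_q(dplyr::mutate(rnd, variance = variance * 37.5))
  expect_equal(qa$Q, qb$Q * 37.5)
  # ... i.e. scaling all variances by c scales Q by 1/c; Q is invariant
  # when the *weights* are rescaled with deltas fixed, which the formula
  # guarantees because the weighted mean is scale-free:
  dbar_a <- sum((1 / rnd$variance) * rnd$delta) / sum(1 / rnd$variance)
  dbar_b <- sum((1 / (37.5 * rnd$variance)) * rnd$delta) /
    sum(1 / (37.5 * rnd$variance))
  expect_equal(dbar_a, dbar_b)

  expect_error(cochran_q(same[1, ]), class = "dmardmon_insufficient_data")
  expect_error(cochran_q(tibble::tibble(delta = c(1, 2), variance = c(0, 1))),
               class = "dmardmon_data_error")

  tq <- tidy(q2)
  expect_equal(tq$statistic, q2$Q)
  expect_equal(tq$df, 1L)
})

test_that("under a common-change null Q follows chi-square(k-1)", {
  set.seed(37)
  k <- 9
  n1 <- 10000
  n2 <- 10000
  p1 <- 0.28
  p2 <- 0.41
  qs <- replicate(1000, {
    x1 <- rbinom(k, n1, p1)
    x2 <- rbinom(k, n2, p2)
    ph1 <- pmin(pmax(x1 / n1, 0.5 / n1), 1 - 0.5 / n1)
    ph2 <- pmin(pmax(x2 / n2, 0.5 / n2), 1 - 0.5 / n2)
    d <- tibble::tibble(delta = 100 * (ph2 - ph1),
                        variance = ph1 * (1 - ph1) / n1 + ph2 * (1 - ph2) / n2)
    cochran_q(d)$Q
  })
  ks <- suppressWarnings(ks.test(qs, "pchisq", df = k - 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("subgroup deltas feed a heterogeneity table per family", {
  set.seed(41)
  d <- simulate_ehr(micro_config(41, n_patients = 600, n_practices = 12))
  sd_ <- subgroup_deltas(d, "sex", "2020-02", "2020-05")
  expect_setequal(sd_$category, c("female", "male"))
  expect_true(all(sd_$variance > 0))
  expect_true(all(sd_$p1 > 0 & sd_$p1 < 1))
  # delta is p2 - p1 in percentage points
  expect_equal(sd_$delta, 100 * (sd_$p2 - sd_$p1))

  het <- heterogeneity_by_group(d, "2020-02", "2020-05",
                                groups = c("sex", "age_band"))
  expect_equal(het$group, c("sex", "age_band"))
  expect_true(all(het$df == het$k - 1, na.rm = TRUE))
  expect_true(all(het$p_value >= 0 & het$p_value <= 1, na.rm = TRUE))
})
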