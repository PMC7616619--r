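# Brute-force reference implementations of the cohort and measure rules,
# written independently of the package internals (plain loops, hand-coded
# calendar arithmetic). Used as the oracle the engine must agree with.

# last day of a calendar month
o_last_day <- function(year, month) {
  first <- as.Date(sprintf("%04d-%02d-01", year, month))
  seq(first, by = "month", length.out = 2)[2] - 1
}

# first day of the month `k` months before (year, month)
o_first_day_back <- function(year, month, k) {
  m <- month - k
  y <- year
  while (m < 1) { m <- m + 12; y <- y - 1 }
  as.Date(sprintf("%04d-%02d-01", y, m))
}

# calendar-month subtraction with end-of-month clamping
o_months_back <- function(date, k) {
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  d <- as.integer(format(date, "%d"))
  m <- m - k
  while (m < 1) { m <- m + 12; y <- y - 1 }
  last <- as.integer(format(o_last_day(y, m), "%d"))
  as.Date(sprintf("%04d-%02d-%02d", y, m, min(d, last)))
}

o_required <- function(drug) {
  switch(drug,
         azathioprine = c("FBC", "LFT", "UE"),
         leflunomide = c("FBC", "LFT", "UE", "BP"),
         methotrexate = c("FBC", "LFT", "UE"),
         stop("unknown drug"))
}

o_eligible <- function(p, index_date) {
  if (!is.na(p$death_date) && p$death_date <= index_date) return(FALSE)
  if (is.na(p$registration_start) || p$registration_start > index_date) return(FALSE)
  if (is.na(p$date_of_birth)) return(FALSE)
  age <- floor(as.numeric(index_date - p$date_of_birth) / 365.25)
  if (age < 18 || age > 120) return(FALSE)
  !is.na(p$sex) && !is.na(p$imd_quintile) && !is.na(p$rural_urban)
}

o_on_drug <- function(issue_dates, index_date) {
  b3 <- o_months_back(index_date, 3)
  b6 <- o_months_back(index_date, 6)
  any(issue_dates > b3 & issue_dates <= index_date) &&
    any(issue_dates > b6 & issue_dates <= b3)
}

# raw numerator and denominator (patient-drug pairs) for one month
o_indicator <- function(patients, prescriptions, tests, year, month,
                        drugs = c("azathioprine", "leflunomide", "methotrexate"),
                        test_set = NULL) {
  index_date <- o_last_day(year, month)
  lookback <- o_first_day_back(year, month, 2)
  num <- 0L
  den <- 0L
  for (i in seq_len(nrow(patients))) {
    p <- patients[i, ]
    if (!o_eligible(p, index_date)) next
    ptests <- tests[tests$patient_id == p$patient_id &
                      tests$date >= lookback & tests$date <= index_date, ]
    for (d in drugs) {
      iss <- prescriptions$issue_date[prescriptions$patient_id == p$patient_id &
                                        prescriptions$drug == d]
      if (!o_on_drug(iss, index_date)) next
      req <- o_required(d)
      if (!is.null(test_set)) req <- intersect(req, test_set)
      den <- den + 1L
      if (!all(req %in% ptests$test_type)) num <- num + 1L
    }
  }
  list(numerator = num, denominator = den)
}

# deciles by direct order-statistic interpolation
o_deciles <- function(x) {
  x <- sort(x)
  n <- length(x)
  sapply(seq(0.1, 0.9, by = 0.1), function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  })
}

# pooled two-proportion z by direct formula
o_ztest <- function(n1, x1, n2, x2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  z <- (p2 - p1) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
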