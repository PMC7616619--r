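# broom-style tidiers and print methods for the two test objects.

#' Tidy a change-test result
#'
#' @param x a `dmard_change_test`.
#' @param ... unused.
#' @return one-row tibble: `estimate` (percentage points), `statistic`,
#'   `p.value`, `conf.low`, `conf.high`, `method`.
#' @export
tidy.dmard_change_test <- function(x, ...) {
  tibble(estimate = x$estimate, statistic = x$statistic, p.value = x$p_value,
         conf.low = x$conf_low, conf.high = x$conf_high, method = x$method)
}

#' @rdname tidy.dmard_change_test
#' @export
glance.dmard_change_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value,
         n1 = x$n1, n2 = x$n2)
}

#' @export
print.dmard_change_test <- function(x, ...) {
  cat("<", x$method, ">\n", sep = "")
  cat(sprintf("  rates: %.1f%% -> %.1f%%  change: %+.1f pp [%.1f, %.1f]\n",
              100 * x$p1, 100 * x$p2, x$estimate, x$conf_low, x$conf_high))
  cat(sprintf("  statistic = %.3f, p = %.3g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Tidy a Cochran's Q heterogeneity result
#'
#' @param x a `dmard_cochran_q`.
#' @param ... unused.
#' @return one-row tibble: `statistic` (Q), `df`, `p.value`, `k`,
#'   `mean_delta`.
#' @export
tidy.dmard_cochran_q <- function(x, ...) {
  tibble(statistic = x$Q, df = x$df, p.value = x$p_value, k = x$k,
         mean_delta = x$mean_delta)
}

#' @rdname tidy.dmard_cochran_q
#' @export
glance.dmard_cochran_q <- function(x, ...) tidy.dmard_cochran_q(x)

#' @export
print.dmard_cochran_q <- function(x, ...) {
  cat("<Cochran's Q heterogeneity test>\n")
  cat(sprintf("  Q = %.3f on %d df (k = %d), p = %.3g\n",
              x$Q, x$df, x$k, x$p_value))
  cat(sprintf("  weighted mean change: %+.1f pp\n", x$mean_delta))
  invisible(x)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
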