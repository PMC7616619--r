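# ggplot2 figures: monthly indicator time series with period reference
# lines, and the practice-level decile chart.

month_to_date <- function(month) as.Date(paste0(month, "-01"))

reference_lines <- function(reference_months) {
  if (length(reference_months) == 0) return(NULL)
  ggplot2::geom_vline(xintercept = month_to_date(reference_months),
                      linetype = "dashed", colour = "grey40")
}

#' Plot a monthly indicator series
#'
#' Line chart of the missed-monitoring percentage over time, one line
#' per scope (drug set / test set / subgroup category), with dashed
#' vertical reference lines at the named periods (defaults: baseline
#' February 2020 and the post-lockdown May 2020 window).
#'
#' @param series tibble from [monthly_series()] (rows from several
#'   scopes may be bound together).
#' @param reference_months character vector of `"YYYY-MM"` months to
#'   mark.
#' @return a ggplot object.
#' @export
plot_indicator_series <- function(series,
                                  reference_months = c("2020-02", "2020-05")) {
  series <- series |>
    mutate(date = month_to_date(month),
           scope = dplyr::case_when(
             !is.na(category) ~ paste0(group, ": ", category),
             tests != "all" ~ paste0(drugs, " / ", tests),
             TRUE ~ drugs
           ))
  p <- ggplot2::ggplot(series,
                       ggplot2::aes(x = date, y = percentage, colour = scope)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    reference_lines(reference_months) +
    ggplot2::scale_y_continuous(limits = c(0, NA)) +
    ggplot2::labs(x = NULL, y = "patients with missed monitoring (%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (n_distinct(series$scope) == 1) p <- p + ggplot2::guides(colour = "none")
  p
}

#' Plot a practice-level decile chart
#'
#' Deciles of per-practice missed-monitoring rates over time: the
#' median as a solid line, the other deciles dashed.
#'
#' @param decile_series tibble from [practice_decile_series()].
#' @param reference_months `"YYYY-MM"` months to mark.
#' @return a ggplot object.
#' @export
plot_practice_deciles <- function(decile_series,
                                  reference_months = c("2020-02", "2020-05")) {
  long <- decile_series |>
    select(month, dplyr::starts_with("d", ignore.case = FALSE)) |>
    tidyr::pivot_longer(-month, names_to = "decile", values_to = "value") |>
    filter(grepl("^d[1-9]$", decile)) |>
    mutate(date = month_to_date(month),
           is_median = decile == "d5")
  ggplot2::ggplot(long, ggplot2::aes(x = date, y = value, group = decile,
                                     linetype = is_median)) +
    ggplot2::geom_line(colour = "steelblue") +
    reference_lines(reference_months) +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid", `FALSE` = "dashed"),
                                   guide = "none") +
    ggplot2::scale_y_continuous(limits = c(0, NA)) +
    ggplot2::labs(x = NULL, y = "practice missed-monitoring rate (%)",
                  title = "Practice-level deciles") +
    ggplot2::theme_minimal()
}
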