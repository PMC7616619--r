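# End-to-end pipeline stages: simulate -> measures -> report. Each
# stage writes CSV outputs plus a manifest listing every file with an
# MD5 digest, so identical seed + configuration gives identical
# digests.

log_msg <- function(verbose, ...) {
  if (isTRUE(verbose)) message(...)
}

run_manifest <- function(config, out_dir, files, stage) {
  files <- files[file.exists(files)]
  list(
    stage = stage,
    package_version = as.character(packageVersion("dmardmon")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = if (!is.null(config)) config$seed else NULL,
    config = if (!is.null(config)) config_snapshot(config) else NULL,
    files = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
}

config_snapshot <- function(config) {
  snap <- unclass(config)
  for (f in names(snap)) {
    if (inherits(snap[[f]], "Date")) snap[[f]] <- format(snap[[f]])
  }
  snap
}

write_manifest <- function(manifest, out_dir) {
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Simulate a dataset and write it to disk
#'
#' Runs [simulate_ehr()] and writes `patients.csv`,
#' `prescriptions.csv`, `tests.csv` and a `manifest.json` (configuration
#' snapshot, seed, package version, file digests) into `out_dir`.
#'
#' @param config a [sim_config()] or the path of a YAML configuration
#'   file.
#' @param out_dir output directory (created if needed).
#' @param seed optional seed overriding the configuration's.
#' @param verbose log progress to stderr.
#' @return (invisibly) the manifest list.
#' @export
run_simulate <- function(config = sim_config(), out_dir, seed = NULL,
                         verbose = FALSE) {
  if (is.character(config)) config <- read_sim_config(config, seed = seed)
  else if (!is.null(seed)) { config$seed <- as.integer(seed) }
  config <- validate_sim_config(config)
  log_msg(verbose, "simulating ", config$n_patients, " patients (seed ",
          config$seed, ")")
  data <- simulate_ehr(config)
  paths <- write_ehr_csv(data, out_dir)
  manifest <- run_manifest(config, out_dir, paths, stage = "simulate")
  write_manifest(manifest, out_dir)
  invisible(manifest)
}

#' Compute all monthly measures and write them to disk
#'
#' Reads the three event CSVs from `data_dir` and writes, into
#' `out_dir`: the overall monthly series, per-drug and per-test series,
#' per-subgroup series, practice-level deciles, cumulative totals
#' (overall, per drug, per test), and a cohort summary for the final
#' month.
#'
#' @param data_dir directory holding `patients.csv`,
#'   `prescriptions.csv`, `tests.csv`.
#' @param out_dir output directory (created if needed).
#' @param start,end first and last index months (`"YYYY-MM"`); defaults
#'   November 2019 to July 2022.
#' @param groups subgroup columns to break the series down by.
#' @param verbose log progress to stderr.
#' @return (invisibly) a named list of the output tibbles.
#' @export
run_measures <- function(data_dir, out_dir, start = "2019-11",
                         end = "2022-07", groups = subgroup_columns(),
                         verbose = FALSE) {
  data <- read_ehr_data(data_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  months <- seq_index_months(start, end)
  per_test_drugs <- lapply(setNames(nm = monitoring_tests()), drugs_requiring)

  group_cols <- intersect(groups, names(data$patients))
  pat_groups <- select(data$patients, patient_id, all_of(group_cols))

  acc <- list(overall = list(), by_drug = list(), by_test = list(),
              by_group = list(), deciles = list(), ev_overall = list(),
              ev_test = list())
  for (i in seq_along(months)) {
    ix <- months[[i]]
    log_msg(verbose, "measuring ", ix$label)
    fr <- month_frame(data, ix)
    ev <- events_from_frame(fr, dmard_drugs(), NULL)

    acc$overall[[i]] <- summarise_events(ev, ix$label, dmard_drugs(), NULL)
    acc$by_drug[[i]] <- purrr::map_dfr(dmard_drugs(), function(d) {
      summarise_events(filter(ev, drug == d), ix$label, d, NULL)
    })
    bt <- purrr::map(monitoring_tests(), function(t) {
      evt <- events_from_frame(fr, per_test_drugs[[t]], t)
      list(row = summarise_events(evt, ix$label, per_test_drugs[[t]], t),
           ev = mutate(evt, test = t))
    })
    acc$by_test[[i]] <- purrr::map_dfr(bt, "row")
    acc$ev_test[[i]] <- purrr::map_dfr(bt, "ev")
    evj <- left_join(ev, pat_groups, by = "patient_id")
    acc$by_group[[i]] <- purrr::map_dfr(group_cols, function(g) {
      purrr::map_dfr(category_levels(data$patients, g), function(cat) {
        sub <- evj[!is.na(evj[[g]]) & as.character(evj[[g]]) == cat, ]
        summarise_events(sub, ix$label, dmard_drugs(), NULL,
                         group = g, category = cat)
      })
    })
    pr <- ev |>
      left_join(select(data$patients, patient_id, practice_id),
                by = "patient_id") |>
      group_by(practice_id) |>
      summarise(num = round5(sum(missed)), den = round5(n()),
                .groups = "drop") |>
      filter(den > 0) |>
      mutate(rate = aggregate_percentage(num, den))
    acc$deciles[[i]] <- if (nrow(pr) >= 2) {
      bind_cols(tibble(month = ix$label), deciles(pr$rate))
    } else tibble(month = ix$label)
    acc$ev_overall[[i]] <- ev
  }

  ev_all <- bind_rows(acc$ev_overall)
  ev_test_all <- bind_rows(acc$ev_test)
  totals_of <- function(ev_sub, scope_drugs, scope_tests) {
    uniq <- n_distinct(ev_sub$patient_id[ev_sub$missed])
    tibble(drugs = paste(sort(scope_drugs), collapse = "+"),
           tests = scope_tests,
           total_events = sum(ev_sub$missed),
           total_denominator_events = nrow(ev_sub),
           unique_patients = uniq,
           repeat_ratio = if (uniq > 0) sum(ev_sub$missed) / uniq else NA_real_)
  }
  totals <- bind_rows(
    totals_of(ev_all, dmard_drugs(), "all"),
    purrr::map_dfr(dmard_drugs(), function(d) {
      totals_of(filter(ev_all, drug == d), d, "all")
    }),
    purrr::map_dfr(monitoring_tests(), function(t) {
      totals_of(filter(ev_test_all, test == t), per_test_drugs[[t]], t)
    })
  )

  out <- list(
    monthly_overall = bind_rows(acc$overall),
    monthly_by_drug = bind_rows(acc$by_drug),
    monthly_by_test = bind_rows(acc$by_test),
    monthly_by_group = bind_rows(acc$by_group),
    practice_deciles = bind_rows(acc$deciles),
    cumulative_totals = totals,
    cohort_summary = cohort_summary(data, months[[length(months)]],
                                    groups = group_cols)
  )
  paths <- character()
  for (nm in names(out)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(out[[nm]], p, na = "")
    paths <- c(paths, p)
  }
  write_manifest(run_manifest(NULL, out_dir, paths, stage = "measures"),
                 out_dir)
  invisible(out)
}

#' Build report figures and comparison tables from measures outputs
#'
#' Reads the CSVs written by [run_measures()] and writes time-series
#' plots (overall, per drug, per test, per subgroup family), the
#' practice decile chart, a baseline/lockdown/recovery comparison table
#' with two-proportion change tests per category, and a per-family
#' Cochran's Q heterogeneity table.
#'
#' @param measures_dir directory written by [run_measures()].
#' @param out_dir output directory (created if needed).
#' @param periods named `"YYYY-MM"` months: `baseline`, `lockdown`,
#'   `recovery`.
#' @param verbose log progress to stderr.
#' @return (invisibly) a list with the comparison and heterogeneity
#'   tables.
#' @export
run_report <- function(measures_dir, out_dir,
                       periods = c(baseline = "2020-02",
                                   lockdown = "2020-05",
                                   recovery = "2022-07"),
                       verbose = FALSE) {
  need <- file.path(measures_dir,
                    c("monthly_overall.csv", "monthly_by_drug.csv",
                      "monthly_by_test.csv", "monthly_by_group.csv",
                      "practice_deciles.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0) {
    abort(paste0("missing measures file(s): ", paste(missing, collapse = ", ")),
          class = "dmardmon_data_error")
  }
  rd <- function(f) readr::read_csv(file.path(measures_dir, f),
                                    show_col_types = FALSE, progress = FALSE)
  overall <- rd("monthly_overall.csv")
  by_drug <- rd("monthly_by_drug.csv")
  by_test <- rd("monthly_by_test.csv")
  by_group <- rd("monthly_by_group.csv")
  dec <- rd("practice_deciles.csv")

  absent <- setdiff(periods, overall$month)
  if (length(absent) > 0) {
    abort(paste0("measures outputs do not cover period month(s): ",
                 paste(absent, collapse = ", ")),
          class = "dmardmon_argument_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ref <- unname(periods[c("baseline", "lockdown")])
  save_plot <- function(p, name) {
    ggplot2::ggsave(file.path(out_dir, name), p, width = 8, height = 4.5,
                    dpi = 120)
  }
  log_msg(verbose, "writing plots to ", out_dir)
  save_plot(plot_indicator_series(overall, ref), "series_overall.png")
  save_plot(plot_indicator_series(by_drug, ref), "series_by_drug.png")
  save_plot(plot_indicator_series(by_test, ref), "series_by_test.png")
  for (g in unique(by_group$group)) {
    save_plot(plot_indicator_series(filter(by_group, group == g), ref),
              paste0("series_by_", g, ".png"))
  }
  if ("d1" %in% names(dec)) {
    save_plot(plot_practice_deciles(dec, ref), "practice_deciles.png")
  }

  # comparison table: per-category rates at the three periods plus the
  # baseline -> lockdown change test on the rounded counts
  at <- function(df, m) filter(df, month == m)
  comparison <- by_group |>
    filter(month %in% periods) |>
    mutate(period = names(periods)[match(month, periods)]) |>
    select(group, category, period, numerator_rounded, denominator_rounded,
           percentage) |>
    tidyr::pivot_wider(names_from = period,
                       values_from = c(numerator_rounded, denominator_rounded,
                                       percentage))
  ct <- purrr::pmap_dfr(comparison, function(...) {
    row <- list(...)
    if (is.na(row$denominator_rounded_baseline) ||
        is.na(row$denominator_rounded_lockdown) ||
        row$denominator_rounded_baseline == 0 ||
        row$denominator_rounded_lockdown == 0) {
      return(tibble(change_pp = NA_real_, statistic = NA_real_,
                    p_value = NA_real_))
    }
    t <- change_test(row$denominator_rounded_baseline,
                     row$numerator_rounded_baseline,
                     row$denominator_rounded_lockdown,
                     row$numerator_rounded_lockdown)
    tibble(change_pp = pp_change(row$percentage_baseline,
                                 row$percentage_lockdown),
           statistic = t$statistic, p_value = t$p_value)
  })
  comparison <- bind_cols(comparison, ct)

  het <- comparison |>
    filter(!is.na(statistic)) |>
    group_by(group) |>
    group_modify(function(df, key) {
      if (nrow(df) < 2) {
        return(tibble(k = nrow(df), Q = NA_real_, df = NA_integer_,
                      p_value = NA_real_, mean_delta = NA_real_))
      }
      d <- df |>
        mutate(n1 = denominator_rounded_baseline,
               n2 = denominator_rounded_lockdown,
               p1 = pmin(pmax(numerator_rounded_baseline / n1, 0.5 / n1),
                         1 - 0.5 / n1),
               p2 = pmin(pmax(numerator_rounded_lockdown / n2, 0.5 / n2),
                         1 - 0.5 / n2),
               delta = 100 * (p2 - p1),
               variance = p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
      q <- cochran_q(d)
      tibble(k = q$k, Q = q$Q, df = q$df, p_value = q$p_value,
             mean_delta = q$mean_delta)
    }) |>
    ungroup()

  ov <- purrr::map(periods, function(m) at(overall, m))
  overall_test <- change_test(ov$baseline$denominator_rounded,
                              ov$baseline$numerator_rounded,
                              ov$lockdown$denominator_rounded,
                              ov$lockdown$numerator_rounded)
  summary_tbl <- tibble(
    scope = "overall",
    baseline_rate = ov$baseline$percentage,
    lockdown_rate = ov$lockdown$percentage,
    recovery_rate = ov$recovery$percentage,
    change_pp = pp_change(ov$baseline$percentage, ov$lockdown$percentage),
    recovery_change_pp = pp_change(ov$lockdown$percentage,
                                   ov$recovery$percentage),
    statistic = overall_test$statistic,
    p_value = overall_test$p_value
  )

  readr::write_csv(comparison, file.path(out_dir, "comparison_table.csv"), na = "")
  readr::write_csv(het, file.path(out_dir, "heterogeneity.csv"), na = "")
  readr::write_csv(summary_tbl, file.path(out_dir, "overall_change.csv"), na = "")
  paths <- list.files(out_dir, full.names = TRUE)
  write_manifest(run_manifest(NULL, out_dir,
                              setdiff(paths, file.path(out_dir, "manifest.json")),
                              stage = "report"),
                 out_dir)
  invisible(list(comparison = comparison, heterogeneity = het,
                 overall = summary_tbl))
}
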