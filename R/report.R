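#' Monthly RAR-rate trend, stratified by photo exposure
#'
#' Bins sessions into calendar months (by sign time) and computes the RAR rate
#' per 100 000 sessions overall and within the photo-exposed and unexposed
#' strata. Bins with an empty denominator are emitted with a missing rate,
#' never zero; within every bin the two strata sum to the overall counts.
#'
#' @param rows Analysis tibble (needs `sign_time`, `is_rar`, `photo`).
#' @param bin Bin width understood by [lubridate::floor_date()] (default
#'   `"month"`).
#' @param per Rate denominator scale (default 100 000).
#' @return A tibble: `stratum` (`Overall`, `Photo`, `NoPhoto`), `bin_start`,
#'   `events`, `sessions`, `rate`.
#' @export
trend_series <- function(rows, bin = "month", per = 100000) {
  rows$bin_start <- lubridate::floor_date(rows$sign_time, unit = bin)
  bins <- seq(min(rows$bin_start), max(rows$bin_start), by = bin)
  one <- function(sub, label) {
    out <- sub |>
      dplyr::group_by(.data$bin_start) |>
      dplyr::summarise(events = sum(.data$is_rar), sessions = dplyr::n(),
                       .groups = "drop")
    out <- tidyr::complete(out, bin_start = bins,
                           fill = list(events = 0L, sessions = 0L))
    out$rate <- ifelse(out$sessions > 0, out$events / out$sessions * per,
                       NA_real_)
    out$stratum <- label
    out
  }
  dplyr::bind_rows(
    one(rows, "Overall"),
    one(rows[rows$photo, , drop = FALSE], "Photo"),
    one(rows[!rows$photo, , drop = FALSE], "NoPhoto")
  ) |>
    dplyr::relocate("stratum")
}

#' Univariable odds-ratio table
#'
#' One row per non-reference level of every analysis covariate: pairwise
#' level-vs-reference 2x2 odds ratios for the factor covariates, one-vs-rest
#' odds ratios for race (each named race against all remaining sessions), and
#' a single-predictor logistic odds ratio per year for age. Zero-cell tables
#' fall back to the Haldane-Anscombe correction and are flagged.
#'
#' @param rows Analysis tibble.
#' @return Tibble: `variable`, `level`, `reference`, `or`, `ci_low`,
#'   `ci_high`, `p_value`, `method`.
#' @export
univariable_or_table <- function(rows) {
  out <- list()
  or_row <- function(variable, level, reference, t) {
    r <- tryCatch(contingency_or(t), error = function(e) {
      contingency_or(t, haldane = TRUE)
    })
    tibble::tibble(variable = variable, level = level, reference = reference,
                   or = r$odds_ratio, ci_low = r$ci_low, ci_high = r$ci_high,
                   p_value = r$p_value, method = r$method)
  }
  pair <- function(variable, level, reference) {
    a <- sum(rows$is_rar[rows[[variable]] == level])
    b <- sum(rows[[variable]] == level) - a
    cc <- sum(rows$is_rar[rows[[variable]] == reference])
    d <- sum(rows[[variable]] == reference) - cc
    or_row(variable, level, reference,
           contingency_table(a, b, cc, d, exposure = level))
  }
  ph <- table(factor(rows$photo, c(FALSE, TRUE)), factor(rows$is_rar, c(FALSE, TRUE)))
  out$photo <- or_row("photo", "Yes", "No", contingency_table(
    ph["TRUE", "TRUE"], ph["TRUE", "FALSE"], ph["FALSE", "TRUE"],
    ph["FALSE", "FALSE"], exposure = "photo"))
  age_fit <- fit_logistic(rows, covariates = "age_years", exclusions = FALSE,
                          on_separation = "flag")
  ac <- age_fit$coefficients
  out$age <- tibble::tibble(variable = "age_years", level = "per year",
                            reference = "", or = ac$aor, ci_low = ac$ci_low,
                            ci_high = ac$ci_high, p_value = ac$p_value,
                            method = "logistic")
  out$sex <- pair("sex", "Male", "Female")
  race_levels <- intersect(c("White", "Black", "Asian", "Other"),
                           unique(rows$race))
  race_tabs <- one_vs_rest_tables(rows, "race")
  out$race <- dplyr::bind_rows(purrr::map(
    race_levels, ~ or_row("race", .x, "rest", race_tabs[[.x]])))
  if (all(c("Hispanic", "Non-Hispanic") %in% rows$ethnicity)) {
    out$ethnicity <- pair("ethnicity", "Hispanic", "Non-Hispanic")
  }
  out$group <- dplyr::bind_rows(purrr::map(
    intersect(c("Cardiac", "ICU", "GeneralCare"), unique(rows$care_group)),
    ~ pair("care_group", .x, "Other")))
  out$shift <- pair("shift", "Day", "Night")
  out$provider <- dplyr::bind_rows(purrr::map(
    intersect(c("Fellow", "Resident", "PA/NP", "Other"),
              unique(rows$provider_type)),
    ~ pair("provider_type", .x, "Attending")))
  out$insurance <- dplyr::bind_rows(purrr::map(
    intersect(c("Public", "SelfPay"), unique(rows$insurance)),
    ~ pair("insurance", .x, "Private")))
  dplyr::bind_rows(out)
}

#' Descriptive session-characteristics table
#'
#' Counts and column percentages of every covariate by RAR status, with
#' chi-square P-values for categorical variables (per-level one-vs-rest P for
#' race and insurance, global otherwise) and a Welch t-test for age.
#'
#' @param rows Analysis tibble.
#' @return Tibble: `variable`, `level`, `n_no_rar`, `pct_no_rar`, `n_rar`,
#'   `pct_rar`, `p_value`.
#' @export
descriptive_table <- function(rows) {
  n0 <- sum(!rows$is_rar)
  n1 <- sum(rows$is_rar)
  cat_block <- function(variable, per_level = FALSE) {
    counts <- rows |>
      dplyr::count(level = as.character(.data[[variable]]), .data$is_rar) |>
      tidyr::pivot_wider(names_from = "is_rar", values_from = "n",
                         values_fill = 0L)
    ev <- if ("TRUE" %in% names(counts)) counts[["TRUE"]] else rep(0L, nrow(counts))
    ne <- if ("FALSE" %in% names(counts)) counts[["FALSE"]] else rep(0L, nrow(counts))
    p <- if (per_level) {
      purrr::map_dbl(seq_along(ev), function(i) {
        m <- matrix(c(ev[i], ne[i], sum(ev) - ev[i], sum(ne) - ne[i]), 2,
                    byrow = TRUE)
        tryCatch(chi_square_test(m)$p_value, error = function(e) NA_real_)
      })
    } else {
      gp <- tryCatch(
        chi_square_test(cbind(events = ev, nonevents = ne))$p_value,
        error = function(e) NA_real_)
      c(gp, rep(NA_real_, length(ev) - 1L))
    }
    tibble::tibble(variable = variable, level = counts$level,
                   n_no_rar = ne, pct_no_rar = 100 * ne / n0,
                   n_rar = ev, pct_rar = 100 * ev / n1, p_value = p)
  }
  age_p <- tryCatch(
    stats::t.test(age_years ~ is_rar, data = rows)$p.value,
    error = function(e) NA_real_)
  age_row <- tibble::tibble(
    variable = "age_years", level = "mean (SD)",
    n_no_rar = round(mean(rows$age_years[!rows$is_rar]), 2),
    pct_no_rar = round(stats::sd(rows$age_years[!rows$is_rar]), 2),
    n_rar = round(mean(rows$age_years[rows$is_rar]), 2),
    pct_rar = round(stats::sd(rows$age_years[rows$is_rar]), 2),
    p_value = age_p)
  dplyr::bind_rows(
    cat_block("photo"), age_row, cat_block("sex"),
    cat_block("race", per_level = TRUE), cat_block("ethnicity"),
    cat_block("care_group"), cat_block("shift"), cat_block("provider_type"),
    cat_block("insurance", per_level = TRUE))
}

#' Run the full surveillance pipeline
#'
#' Generate (optional) -> detect -> sessionize -> analyze -> report. Writes
#' every stage artifact plus a manifest with the seed, row counts at every
#' stage and all exclusion tallies. Idempotent: the same configuration and
#' seed produce byte-identical tables.
#'
#' @param config A [generator_config()] object, or a directory containing
#'   `orders.csv`, `patients.csv`, `providers.csv` (pre-extracted data).
#' @param out_dir Results directory (created if needed).
#' @param include_mixed Also fit the mixed-effects sensitivity model
#'   (default `TRUE`).
#' @param make_plot Write `trend.png` alongside `trend.csv` (default `FALSE`;
#'   the CSV is the tested artifact).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, include_mixed = TRUE,
                         make_plot = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  manifest <- list(package_version = as.character(utils::packageVersion("rarwatch")))

  if (inherits(config, "rar_config")) {
    manifest$seed <- config$seed
    cohort <- stage("generate", generate_cohort(config))
    log <- stage("generate", generate_order_log(config, cohort$patients,
                                                cohort$providers))
    patients <- cohort$patients
    providers <- cohort$providers
    orders <- log$orders
    write_timed_csv(patients, file.path(out_dir, "patients.csv"))
    write_timed_csv(providers, file.path(out_dir, "providers.csv"))
    write_timed_csv(orders, file.path(out_dir, "orders.csv"))
    write_timed_csv(log$truth, file.path(out_dir, "truth.csv"))
    write_config(config, file.path(out_dir, "config.json"))
    pilot <- config$pilot_start
    full <- config$full_start
  } else {
    in_dir <- config
    orders <- stage("load", read_orders(file.path(in_dir, "orders.csv")))
    patients <- stage("load", read_patients(file.path(in_dir, "patients.csv")))
    providers <- stage("load", readr::read_csv(
      file.path(in_dir, "providers.csv"), col_types = "cc", na = ""))
    pilot <- "2020-09-16"
    full <- "2021-03-11"
  }
  manifest$n_patients <- nrow(patients)
  manifest$n_providers <- nrow(providers)
  manifest$n_orders <- nrow(orders)
  manifest$n_retracted_orders <- sum(!is.na(orders$retract_time))

  events <- stage("detect", detect_rar_events(orders))
  write_rar_events(events, file.path(out_dir, "rar_events.csv"))
  manifest$n_rar_events <- nrow(events)

  sessions <- stage("sessionize", build_sessions(orders, rar_order_ids(events)))
  rows <- stage("sessionize",
                build_analysis_table(sessions, patients, providers,
                                     pilot_start = pilot, full_start = full))
  write_timed_csv(
    dplyr::mutate(sessions,
                  order_ids = purrr::map_chr(.data$order_ids, paste,
                                             collapse = ";")),
    file.path(out_dir, "sessions.csv"))
  write_timed_csv(rows, file.path(out_dir, "analysis.csv"))
  manifest$n_sessions <- nrow(sessions)
  manifest$n_rar_sessions <- sum(sessions$is_rar)
  manifest$n_analysis_rows <- nrow(rows)

  res <- stage("analyze", analyze_rows(rows, include_mixed = include_mixed))
  readr::write_csv(res$table1, file.path(out_dir, "table1.csv"), na = "")
  readr::write_csv(res$or_table, file.path(out_dir, "or_table.csv"), na = "")
  jsonlite::write_json(res$model_report,
                       file.path(out_dir, "model_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  manifest$model_excluded <- as.list(res$excluded)

  trend <- stage("report", trend_series(rows))
  trend_out <- dplyr::mutate(trend, bin_start = format(.data$bin_start,
                                                       "%Y-%m-%d"))
  readr::write_csv(trend_out, file.path(out_dir, "trend.csv"), na = "")
  if (make_plot) {
    try(plot_trend(trend, file.path(out_dir, "trend.png")), silent = TRUE)
  }
  manifest$rates_by_period <- purrr::map(
    split(rows$is_rar, rows$period),
    ~ list(events = sum(.x), sessions = length(.x),
           rate_per_100k = if (length(.x) > 0) sum(.x) / length(.x) * 1e5 else NULL))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

analyze_rows <- function(rows, include_mixed = TRUE, alpha_in = 0.1) {
  table1 <- descriptive_table(rows)
  or_tab <- univariable_or_table(rows)
  screen <- univariable_screen(rows, alpha_in = alpha_in)
  selected <- intersect(attr(screen, "selected"), default_covariates())
  if (length(selected) == 0L) selected <- "photo"
  fit <- fit_logistic(rows, covariates = selected, on_separation = "flag")
  or_tab <- dplyr::left_join(
    or_tab,
    dplyr::select(fit$coefficients, "variable", "level",
                  aor = "aor", aor_ci_low = "ci_low",
                  aor_ci_high = "ci_high", aor_p = "p_value"),
    by = c("variable", "level"))
  report <- list(
    screen = screen,
    multivariable = fit_to_list(fit),
    period_tests = period_tests(rows)
  )
  if (include_mixed) {
    mixed <- tryCatch(
      fit_logistic_mixed(rows, covariates = selected),
      error = function(e) NULL)
    report$mixed <- if (is.null(mixed)) {
      list(converged = FALSE, error = "mixed fit failed")
    } else {
      fit_to_list(mixed)
    }
  }
  list(table1 = table1, or_table = or_tab, model_report = report,
       excluded = fit$excluded)
}

fit_to_list <- function(fit) {
  list(model = fit$model, n_used = fit$n_used,
       converged = fit$converged, excluded = as.list(fit$excluded),
       reference = as.list(fit$reference),
       coefficients = fit$coefficients,
       varcomp = fit$varcomp)
}

period_tests <- function(rows) {
  by_p <- split(rows$is_rar, rows$period)
  rate <- function(x) if (length(x) > 0) sum(x) / length(x) * 1e5 else NA_real_
  cmp <- function(a, b) {
    if (length(a) == 0 || length(b) == 0) return(NA_real_)
    equal_proportions_test(sum(a), length(a), sum(b), length(b))$p_value
  }
  list(
    rate_pre = rate(by_p$Pre), rate_pilot = rate(by_p$Pilot),
    rate_full = rate(by_p$Full),
    p_pre_vs_pilot = cmp(by_p$Pre, by_p$Pilot),
    p_pre_vs_full = cmp(by_p$Pre, by_p$Full)
  )
}

read_patients <- function(path) {
  p <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      birth_date = readr::col_character(),
      photo_time = readr::col_character(),
      ccc_count = readr::col_integer(),
      .default = readr::col_character()
    ),
    na = ""
  )
  p$birth_date <- parse_time_col(p$birth_date, "birth_date")
  p$photo_time <- parse_time_col(p$photo_time, "photo_time")
  p
}

#' Plot the monthly RAR-rate trend
#'
#' @param trend Tibble from [trend_series()].
#' @param path Optional PNG path; when given the plot is saved and the path
#'   returned invisibly.
#' @return A ggplot object (or `path`, invisibly).
#' @export
plot_trend <- function(trend, path = NULL) {
  gg <- ggplot2::ggplot(
    trend,
    ggplot2::aes(x = .data$bin_start, y = .data$rate,
                 colour = .data$stratum)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 0.8, na.rm = TRUE) +
    ggplot2::scale_colour_manual(
      values = c(Overall = "grey40", Photo = "#2166ac", NoPhoto = "#b2182b")) +
    ggplot2::labs(x = NULL, y = "RAR events per 100 000 order sessions",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, gg, width = 8, height = 4.5, dpi = 150)
    return(invisible(path))
  }
  gg
}
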