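#' Build a 2x2 exposure-by-outcome contingency table
#'
#' @param exposed_events,exposed_nonevents,unexposed_events,unexposed_nonevents
#'   Non-negative cell counts.
#' @param exposure,outcome Axis labels.
#' @return An object of class `rar_contingency`.
#' @examples
#' # photo-exposed vs not, RAR sessions vs not
#' contingency_table(90, 573262, 854, 2840564, exposure = "photo")
#' @export
contingency_table <- function(exposed_events, exposed_nonevents,
                              unexposed_events, unexposed_nonevents,
                              exposure = "exposed", outcome = "event") {
  cells <- c(exposed_events, exposed_nonevents,
             unexposed_events, unexposed_nonevents)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("contingency cells must be non-negative counts", call. = FALSE)
  }
  if (sum(cells) == 0) {
    stop("contingency table is empty", call. = FALSE)
  }
  structure(
    list(exposed_events = exposed_events,
         exposed_nonevents = exposed_nonevents,
         unexposed_events = unexposed_events,
         unexposed_nonevents = unexposed_nonevents,
         exposure = exposure, outcome = outcome),
    class = "rar_contingency"
  )
}

#' @exportS3Method base::print
print.rar_contingency <- function(x, ...) {
  m <- matrix(c(x$exposed_events, x$exposed_nonevents,
                x$unexposed_events, x$unexposed_nonevents),
              nrow = 2, byrow = TRUE,
              dimnames = list(c(x$exposure, paste0("not ", x$exposure)),
                              c(x$outcome, paste0("no ", x$outcome))))
  print(m)
  invisible(x)
}

#' Cross-product odds ratio with Wald confidence interval
#'
#' `OR = (a d) / (b c)` with `a` = exposed events, `b` = exposed non-events,
#' `c` = unexposed events, `d` = unexposed non-events; the 95% CI is
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` and the p-value comes
#' from the Wald z statistic. Identical (to machine precision) to the odds
#' ratio of a saturated one-predictor logistic fit.
#'
#' @param t A [contingency_table()].
#' @param conf_level Confidence level (default 0.95).
#' @param haldane If `TRUE`, apply the Haldane-Anscombe +0.5 correction to
#'   every cell (required when any cell is zero; never applied silently).
#' @return An object of class `rar_or_test`: `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `method`.
#' @examples
#' contingency_or(contingency_table(90, 573262, 854, 2840564)) # OR 0.522
#' @export
contingency_or <- function(t, conf_level = 0.95, haldane = FALSE) {
  stopifnot(inherits(t, "rar_contingency"))
  a <- t$exposed_events; b <- t$exposed_nonevents
  cc <- t$unexposed_events; d <- t$unexposed_nonevents
  if (min(a, b, cc, d) == 0) {
    if (!haldane) {
      stop("zero cell in contingency table; re-run with `haldane = TRUE` ",
           "for the Haldane-Anscombe +0.5 correction", call. = FALSE)
    }
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  log_or <- log(a) + log(d) - log(b) - log(cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(odds_ratio = exp(log_or),
         ci_low = exp(log_or - z * se),
         ci_high = exp(log_or + z * se),
         p_value = 2 * stats::pnorm(-abs(log_or / se)),
         method = if (haldane && min(t$exposed_events, t$exposed_nonevents,
                                     t$unexposed_events, t$unexposed_nonevents) == 0)
           "wald-haldane" else "wald",
         exposure = t$exposure),
    class = "rar_or_test"
  )
}

#' @exportS3Method base::print
print.rar_or_test <- function(x, ...) {
  cat(sprintf("OR %.3f (95%% CI %.3f-%.3f), p = %.3g  [%s]\n",
              x$odds_ratio, x$ci_low, x$ci_high, x$p_value, x$method))
  invisible(x)
}

#' One-vs-rest 2x2 tables for a categorical variable
#'
#' Each level of the variable is contrasted against all remaining sessions
#' pooled (the encoding under which published per-level race odds ratios are
#' reproducible, as opposed to pairwise-vs-reference contrasts). Accepts
#' either session-level rows (with a logical `is_rar` outcome) or a summary
#' tibble of per-level counts with columns `level`, `events`, `nonevents`.
#'
#' @param rows Analysis tibble, or a per-level counts tibble.
#' @param variable Column name of the categorical variable (ignored for the
#'   counts form).
#' @return Named list of [contingency_table()]s, one per level.
#' @export
one_vs_rest_tables <- function(rows, variable = NULL) {
  if (all(c("level", "events", "nonevents") %in% names(rows))) {
    counts <- tibble::tibble(level = as.character(rows$level),
                             events = rows$events, nonevents = rows$nonevents)
  } else {
    stopifnot(!is.null(variable), variable %in% names(rows),
              "is_rar" %in% names(rows))
    counts <- rows |>
      dplyr::count(level = as.character(.data[[variable]]),
                   .data$is_rar) |>
      tidyr::pivot_wider(names_from = "is_rar", values_from = "n",
                         values_fill = 0L)
    counts$events <- if ("TRUE" %in% names(counts)) counts[["TRUE"]] else 0L
    counts$nonevents <- if ("FALSE" %in% names(counts)) counts[["FALSE"]] else 0L
  }
  if (nrow(counts) < 2L) {
    stop("one-vs-rest requires a variable with at least 2 levels",
         call. = FALSE)
  }
  tot_e <- sum(counts$events)
  tot_n <- sum(counts$nonevents)
  out <- purrr::map(seq_len(nrow(counts)), function(i) {
    contingency_table(
      exposed_events = counts$events[i],
      exposed_nonevents = counts$nonevents[i],
      unexposed_events = tot_e - counts$events[i],
      unexposed_nonevents = tot_n - counts$nonevents[i],
      exposure = counts$level[i]
    )
  })
  stats::setNames(out, counts$level)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson's chi-square without continuity correction (the declared dialect),
#' on a 2x2 [contingency_table()] or a k-level counts matrix/tibble
#' (columns = events, nonevents).
#'
#' @param t A `rar_contingency`, a numeric matrix with 2 columns, or a tibble
#'   with columns `events` and `nonevents`.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(t) {
  m <- if (inherits(t, "rar_contingency")) {
    matrix(c(t$exposed_events, t$exposed_nonevents,
             t$unexposed_events, t$unexposed_nonevents), nrow = 2, byrow = TRUE)
  } else if (is.matrix(t)) {
    t
  } else {
    as.matrix(tibble::tibble(events = t$events, nonevents = t$nonevents))
  }
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero margin in contingency table", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value))
}

#' Welch two-sample t-test from summary statistics
#'
#' Two-sided t-test of two group means given only the published summaries
#' (mean, SD, n per arm), with the Welch-Satterthwaite degrees of freedom.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @examples
#' welch_t_test(7.19, 6.70, 3413826, 5.75, 6.50, 944) # age by RAR status
#' @export
welch_t_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 <= 1 || n2 <= 1) stop("each arm needs n > 1", call. = FALSE)
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive",
                                 call. = FALSE)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  stat <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble::tibble(statistic = stat, df = df,
                 p_value = 2 * stats::pt(-abs(stat), df))
}

#' Two-sided test of equal proportions
#'
#' Two-sample proportion test (chi-square form, no continuity correction),
#' used to compare RAR rates between implementation periods.
#'
#' @param x1,n1 Events and sessions in the first period.
#' @param x2,n2 Events and sessions in the second period.
#' @return A one-row tibble: `p1`, `p2`, `statistic`, `p_value`.
#' @export
equal_proportions_test <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("denominators must be positive", call. = FALSE)
  if (x1 > n1 || x2 > n2) stop("events cannot exceed denominator",
                               call. = FALSE)
  ht <- suppressWarnings(
    stats::prop.test(c(x1, x2), c(n1, n2), correct = FALSE))
  tibble::tibble(p1 = x1 / n1, p2 = x2 / n2,
                 statistic = unname(ht$statistic),
                 p_value = unname(ht$p.value))
}
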