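#' Published session counts by RAR status (reference worked example)
#'
#' Order-session characteristic counts, cross-tabulated by RAR status, as
#' published for a large pediatric inpatient cohort observed 2020-2022
#' (3 414 770 order sessions, 944 RAR sessions, 85 767 patients). These
#' printed counts are the worked-example inputs for the contingency machinery:
#' feeding them through [contingency_or()] and [one_vs_rest_tables()]
#' reproduces the published univariable odds ratios (photo 0.522,
#' Hispanic 0.745, cardiac 2.42, Black 1.18, ...).
#'
#' @return A tibble with columns `variable`, `level`, `n_rar`, `n_no_rar`.
#' @examples
#' counts <- reference_session_counts()
#' ph <- subset(counts, variable == "photo")
#' contingency_or(contingency_table(
#'   ph$n_rar[ph$level == "Yes"], ph$n_no_rar[ph$level == "Yes"],
#'   ph$n_rar[ph$level == "No"], ph$n_no_rar[ph$level == "No"]))
#' @export
reference_session_counts <- function() {
  path <- system.file("extdata", "session_counts_reference.csv",
                      package = "rarwatch", mustWork = TRUE)
  readr::read_csv(path, col_types = "ccii")
}

#' @rdname reference_session_counts
#' @details `reference_age_summary()` returns the published age summaries
#'   (mean, SD, n) of the two outcome groups, the inputs to
#'   [welch_t_test()].
#' @export
reference_age_summary <- function() {
  tibble::tibble(
    group = c("no_rar", "rar"),
    mean = c(7.19, 5.75),
    sd = c(6.70, 6.50),
    n = c(3413826L, 944L)
  )
}

#' Pairwise and one-vs-rest tables from published counts
#'
#' Convenience wrapper turning [reference_session_counts()] rows into the 2x2
#' [contingency_table()] comparing `level` against `reference` for a
#' variable, mirroring the published univariable contrasts.
#'
#' @param counts Counts tibble (`variable`, `level`, `n_rar`, `n_no_rar`).
#' @param variable Variable name.
#' @param level Exposure level.
#' @param reference Reference level.
#' @return A `rar_contingency`.
#' @export
counts_pair_table <- function(counts, variable, level, reference) {
  sub <- counts[counts$variable == variable, ]
  pick <- function(lv, col) sub[[col]][sub$level == lv]
  contingency_table(pick(level, "n_rar"), pick(level, "n_no_rar"),
                    pick(reference, "n_rar"), pick(reference, "n_no_rar"),
                    exposure = level)
}
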