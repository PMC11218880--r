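# Model-frame preparation shared by every logistic fit.
#
# Reference levels follow the published convention: photo No, sex Female,
# ethnicity Non-Hispanic (Hispanic entered one-vs-rest with unknowns pooled
# into the reference), care group Other, shift Night, provider Attending,
# insurance Private. Race is entered as one-vs-rest indicators (each named
# level against all remaining sessions); sessions with unknown race carry all
# four indicators at zero.
covariate_terms <- function() {
  list(
    photo = list(terms = "photo", labels = c(photoYes = "Yes")),
    age_years = list(terms = "age_years", labels = c(age_years = "per year")),
    sex = list(terms = "sex", labels = c(sexMale = "Male",
                                         sexUnknown = "Unknown")),
    race = list(terms = c("race_white", "race_black", "race_asian",
                          "race_other"),
                labels = c(race_whiteTRUE = "White", race_blackTRUE = "Black",
                           race_asianTRUE = "Asian", race_otherTRUE = "Other")),
    ethnicity = list(terms = "eth_hispanic",
                     labels = c(eth_hispanicTRUE = "Hispanic")),
    care_group = list(terms = "care_group",
                      labels = c(care_groupCardiac = "Cardiac",
                                 care_groupICU = "ICU",
                                 care_groupGeneralCare = "GeneralCare")),
    shift = list(terms = "shift", labels = c(shiftDay = "Day")),
    provider_type = list(terms = "provider_type",
                         labels = c(provider_typeFellow = "Fellow",
                                    provider_typeResident = "Resident",
                                    `provider_typePA/NP` = "PA/NP",
                                    provider_typeOther = "Other")),
    insurance = list(terms = "insurance",
                     labels = c(insurancePublic = "Public",
                                insuranceSelfPay = "SelfPay")),
    ccc_count = list(terms = "ccc_count",
                     labels = c(ccc_count = "per condition"))
  )
}

default_covariates <- function() {
  c("photo", "age_years", "sex", "race", "ethnicity", "care_group", "shift",
    "provider_type", "insurance")
}

reference_levels <- function() {
  c(photo = "No", sex = "Female", race = "rest (one-vs-rest)",
    ethnicity = "Non-Hispanic", care_group = "Other", shift = "Night",
    provider_type = "Attending", insurance = "Private")
}

prepare_model_frame <- function(rows, covariates, outcome = "is_rar",
                                exclusions = TRUE) {
  excluded <- c(sex_unknown = 0L, insurance_selfpay = 0L)
  if (exclusions) {
    if ("sex" %in% covariates && "sex" %in% names(rows)) {
      drop <- rows$sex == "Unknown"
      excluded["sex_unknown"] <- sum(drop)
      rows <- rows[!drop, , drop = FALSE]
    }
    if ("insurance" %in% covariates && "insurance" %in% names(rows)) {
      drop <- rows$insurance == "SelfPay"
      excluded["insurance_selfpay"] <- sum(drop)
      rows <- rows[!drop, , drop = FALSE]
    }
  }
  d <- tibble::tibble(.rows = nrow(rows))
  d$.outcome <- as.integer(rows[[outcome]])
  for (cv in covariates) {
    switch(cv,
      photo = { d$photo <- factor(ifelse(rows$photo, "Yes", "No"),
                                  levels = c("No", "Yes")) },
      age_years = { d$age_years <- rows$age_years },
      sex = { d$sex <- factor(rows$sex,
                              levels = intersect(c("Female", "Male", "Unknown"),
                                                 unique(rows$sex))) },
      race = {
        d$race_white <- rows$race == "White"
        d$race_black <- rows$race == "Black"
        d$race_asian <- rows$race == "Asian"
        d$race_other <- rows$race == "Other"
      },
      ethnicity = { d$eth_hispanic <- rows$ethnicity == "Hispanic" },
      care_group = { d$care_group <- factor(
        rows$care_group, levels = intersect(
          c("Other", "Cardiac", "ICU", "GeneralCare"),
          unique(rows$care_group))) },
      shift = { d$shift <- factor(as.character(rows$shift),
                                  levels = c("Night", "Day")) },
      provider_type = { d$provider_type <- factor(
        rows$provider_type, levels = intersect(
          c("Attending", "Fellow", "Resident", "PA/NP", "Other"),
          unique(rows$provider_type))) },
      insurance = { d$insurance <- factor(
        rows$insurance, levels = intersect(
          c("Private", "Public", "SelfPay"), unique(rows$insurance))) },
      ccc_count = { d$ccc_count <- rows$ccc_count },
      stop("unknown covariate: ", cv, call. = FALSE)
    )
  }
  for (id in c("patient_id", "provider_id")) {
    if (id %in% names(rows)) d[[id]] <- rows[[id]]
  }
  terms <- unlist(purrr::map(covariate_terms()[covariates], "terms"))
  # a term observed at a single level carries no contrast; drop it rather
  # than letting model.matrix fail on sparse synthetic data
  varies <- vapply(terms, function(tm) {
    x <- d[[tm]]
    if (is.factor(x)) nlevels(droplevels(x)) >= 2L else length(unique(x)) >= 2L
  }, logical(1))
  list(data = d, excluded = excluded, terms = terms[varies],
       dropped_terms = terms[!varies])
}

coef_table <- function(cf, covariates, conf_level = 0.95) {
  cv_terms <- covariate_terms()[covariates]
  labels <- unlist(unname(purrr::map(cv_terms, "labels")))
  vars <- rep(names(cv_terms), purrr::map_int(cv_terms, ~ length(.x$labels)))
  names(vars) <- names(labels)
  terms <- setdiff(rownames(cf), "(Intercept)")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- cf[terms, 1]
  se <- cf[terms, 2]
  tibble::tibble(
    term = terms,
    variable = unname(vars[terms]),
    level = unname(labels[terms]),
    estimate = unname(est),
    se = unname(se),
    aor = exp(unname(est)),
    ci_low = exp(unname(est) - z * se),
    ci_high = exp(unname(est) + z * se),
    p_value = 2 * stats::pnorm(-abs(unname(est) / se))
  )
}

#' Univariable screen of candidate covariates
#'
#' Fits a single-covariate logistic regression per candidate and keeps those
#' whose global likelihood-ratio P-value falls below `alpha_in` — the entry
#' rule used to choose the multivariable model (under which the
#' complex-chronic-condition count drops out when it carries no signal).
#'
#' @param rows Analysis tibble.
#' @param covariates Candidate covariate names (see [fit_logistic()]).
#' @param alpha_in Entry threshold on the global P (default 0.1).
#' @param outcome Outcome column (default `is_rar`).
#' @return A tibble `covariate`, `df`, `p_value`, `selected`, with the
#'   selected names in `attr(, "selected")`.
#' @export
univariable_screen <- function(rows, covariates = c(default_covariates(),
                                                    "ccc_count"),
                               alpha_in = 0.1, outcome = "is_rar") {
  res <- purrr::map(covariates, function(cv) {
    prep <- prepare_model_frame(rows, cv, outcome = outcome,
                                exclusions = FALSE)
    if (length(prep$terms) == 0L) {
      return(tibble::tibble(covariate = cv, df = 0L, p_value = NA_real_))
    }
    f <- stats::as.formula(paste(".outcome ~", paste(prep$terms, collapse = "+")))
    fit <- stats::glm(f, family = stats::binomial(), data = prep$data)
    dev <- fit$null.deviance - fit$deviance
    df <- fit$df.null - fit$df.residual
    tibble::tibble(covariate = cv, df = df,
                   p_value = stats::pchisq(dev, df, lower.tail = FALSE))
  })
  out <- dplyr::bind_rows(res)
  out$selected <- !is.na(out$p_value) & out$p_value < alpha_in
  attr(out, "selected") <- out$covariate[out$selected]
  out
}

#' Multivariable logistic regression for RAR risk
#'
#' Maximum-likelihood logistic fit of the session-level outcome on the chosen
#' covariates, with Wald confidence intervals. Small-cell exclusions (sessions
#' with unknown sex, and self-pay insurance sessions) are dropped before
#' fitting and their counts recorded. Race enters as one-vs-rest indicators;
#' all other categoricals use the published reference levels (see
#' [fit_logistic_mixed()] for the clustered sensitivity version).
#'
#' @param rows Analysis tibble from [build_analysis_table()].
#' @param covariates Covariates to include; default is every published model
#'   term (photo, age, sex, race, ethnicity, care group, shift, provider type,
#'   insurance).
#' @param exclusions Apply the small-cell row exclusions (default `TRUE`).
#' @param outcome Outcome column (default `is_rar`).
#' @param on_separation `"error"` (default) aborts on non-convergence or
#'   separation; `"flag"` returns the fit with `converged = FALSE` so
#'   pipelines can report it.
#' @return An object of class `rar_fit`: `coefficients` (term, variable,
#'   level, estimate, se, aOR, CI, p), `reference`, `n_used`, `excluded`,
#'   `converged`, `model`.
#' @export
fit_logistic <- function(rows, covariates = default_covariates(),
                         exclusions = TRUE, outcome = "is_rar",
                         on_separation = c("error", "flag")) {
  on_separation <- match.arg(on_separation)
  prep <- prepare_model_frame(rows, covariates, outcome = outcome,
                              exclusions = exclusions)
  if (length(unique(prep$data$.outcome)) < 2L) {
    stop("degenerate outcome: `", outcome,
         "` is constant after exclusions (complete separation)",
         call. = FALSE)
  }
  if (length(prep$terms) == 0L) {
    stop("no non-constant predictors to fit", call. = FALSE)
  }
  f <- stats::as.formula(paste(".outcome ~", paste(prep$terms, collapse = "+")))
  boundary <- FALSE
  fit <- withCallingHandlers(
    stats::glm(f, family = stats::binomial(), data = prep$data,
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        boundary <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  cf <- summary(fit)$coefficients
  separated <- !fit$converged || boundary
  if (separated && on_separation == "error") {
    stop("logistic fit did not converge (possible separation); ",
         "no coefficients reported", call. = FALSE)
  }
  structure(
    list(coefficients = coef_table(cf, covariates),
         reference = reference_levels()[intersect(names(reference_levels()),
                                                  covariates)],
         n_used = stats::nobs(fit),
         excluded = prep$excluded,
         converged = !separated,
         model = "fixed",
         varcomp = NULL),
    class = "rar_fit"
  )
}

#' Mixed-effects logistic regression (clustered sensitivity analysis)
#'
#' The same fixed-effect structure as [fit_logistic()] plus random intercepts
#' for the requested cluster ids (patient and provider by default), fitted
#' with [lme4::glmer()]. Reported alongside the fixed-only model to check that
#' clustering leaves the covariate effects essentially unchanged.
#'
#' @inheritParams fit_logistic
#' @param clusters Cluster id columns to give random intercepts.
#' @param nagq Integration points passed to [lme4::glmer()] (0 is the fast
#'   Laplace-free approximation; adequate for a sensitivity comparison).
#' @return A `rar_fit` with `model = "mixed"` and `varcomp`, the
#'   random-intercept variance estimates.
#' @export
fit_logistic_mixed <- function(rows, covariates = default_covariates(),
                               clusters = c("patient_id", "provider_id"),
                               exclusions = TRUE, outcome = "is_rar",
                               nagq = 0L) {
  missing_cl <- setdiff(clusters, names(rows))
  if (length(missing_cl) > 0L) {
    stop("data-integrity error: cluster id column(s) not found: ",
         paste(missing_cl, collapse = ", "), call. = FALSE)
  }
  prep <- prepare_model_frame(rows, covariates, outcome = outcome,
                              exclusions = exclusions)
  f <- stats::as.formula(paste(
    ".outcome ~", paste(prep$terms, collapse = "+"), "+",
    paste(sprintf("(1 | %s)", clusters), collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    lme4::glmer(f, family = stats::binomial(), data = prep$data, nAGQ = nagq,
                control = lme4::glmerControl(calc.derivs = FALSE)),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
        converged <<- FALSE
      }
      invokeRestart("muffleWarning")
    }
  )
  vc <- lme4::VarCorr(fit)
  varcomp <- tibble::tibble(
    cluster = names(vc),
    variance = purrr::map_dbl(vc, ~ as.numeric(.x[1, 1]))
  )
  cf <- summary(fit)$coefficients
  structure(
    list(coefficients = coef_table(cf, covariates),
         reference = reference_levels()[intersect(names(reference_levels()),
                                                  covariates)],
         n_used = stats::nobs(fit),
         excluded = prep$excluded,
         converged = converged,
         model = "mixed",
         varcomp = varcomp),
    class = "rar_fit"
  )
}

#' Model of patient-photo presence
#'
#' Logistic regression with the photo flag as the *outcome* and every other
#' analysis covariate as predictor — used to surface demographic or context
#' strata with systematically lower photo uptake.
#'
#' @inheritParams fit_logistic
#' @return A `rar_fit` (outcome = photo exposure).
#' @export
photo_predictor_model <- function(rows,
                                  covariates = setdiff(default_covariates(),
                                                       "photo"),
                                  exclusions = TRUE,
                                  on_separation = c("error", "flag")) {
  fit_logistic(rows, covariates = covariates, exclusions = exclusions,
               outcome = "photo", on_separation = on_separation)
}

#' @exportS3Method base::print
print.rar_fit <- function(x, ...) {
  cat(sprintf("<rar_fit: %s logistic, n = %s, converged = %s>\n",
              x$model, format(x$n_used, big.mark = ","), x$converged))
  if (sum(x$excluded) > 0) {
    cat("  excluded rows:",
        paste(names(x$excluded), x$excluded, sep = "=", collapse = ", "), "\n")
  }
  df <- x$coefficients
  cat(sprintf("  %-14s %-12s aOR %6s  95%% CI [%s, %s]\n",
              "variable", "level", "", "low", "high"))
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-14s %-12s %9.3f  [%6.3f, %6.3f]  p=%.3g\n",
                df$variable[i], df$level[i], df$aor[i], df$ci_low[i],
                df$ci_high[i], df$p_value[i]))
  }
  if (!is.null(x$varcomp)) {
    cat("  random-intercept variances:",
        paste(x$varcomp$cluster, round(x$varcomp$variance, 4),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
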