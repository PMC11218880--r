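#' Synthetic order-log generator configuration
#'
#' Builds and validates the configuration object consumed by
#' [generate_cohort()] and [generate_order_log()]. Defaults emulate a large
#' pediatric inpatient hospital system observed from 2020-01-01 to 2022-07-01
#' with a staged patient-photograph rollout (pilot 2020-09-16, full go-live
#' 2021-03-11) and a wrong-patient signing risk of roughly 30-40 per 100 000
#' order sessions, of which a fraction `p_catch` are noticed and corrected
#' within the two 10-minute windows that define a retract-and-reorder (RAR)
#' near-miss signature.
#'
#' The per-session probability of a wrong-patient signing follows a logistic
#' model `logit(p) = beta %*% x` over the session covariates (photo exposure at
#' sign time, patient age, care group, provider type, shift, ethnicity, race,
#' insurance). When `beta["intercept"]` is `NA` (the default) it is calibrated
#' at generation time so that the *marginal* wrong-patient probability among
#' photo-unexposed sessions equals `base_wpoe_rate`; see
#' [calibrate_intercept()].
#'
#' @param n_patients,n_providers Cohort sizes.
#' @param study_start,study_end Study window (parsed as UTC timestamps).
#' @param sessions_per_patient_mean Poisson mean of order sessions per patient.
#' @param orders_per_session_mean Mean orders per session (`1 + Poisson(mean - 1)`).
#' @param base_wpoe_rate Marginal probability that a photo-unexposed order
#'   session is signed on the wrong patient.
#' @param p_catch Probability a wrong-patient signing is caught and corrected
#'   within both 10-minute windows, producing the full RAR signature.
#' @param beta Named numeric vector of log-odds coefficients; unspecified names
#'   keep their defaults. Recognised names: `intercept`, `photo`,
#'   `age_per_year`, `group_cardiac`, `group_icu`, `group_general`,
#'   `provider_fellow`, `provider_resident`, `provider_panp`, `provider_other`,
#'   `shift_day`, `ethnicity_hispanic`, `race_black`, `insurance_public`,
#'   `sex_male`, `ccc_per_condition`.
#' @param pilot_start,full_start Photo-rollout dates (pilot unit, then
#'   system-wide go-live).
#' @param p_photo_pilot,p_photo_full Probability a patient acquires a photo
#'   during the pilot window / after full go-live. Defaults place roughly 17%
#'   of sessions after the patient's photo-acquisition time.
#' @param p_benign_retract Probability an ordinary order is retracted with no
#'   reorder.
#' @param p_benign_rar_same_patient Probability of a retract-then-reorder decoy
#'   on the *same* patient (never a RAR event).
#' @param n_forced_rar Number of sessions forced to be caught wrong-patient
#'   signings regardless of `base_wpoe_rate` (testing hook; default 0).
#' @param n_codes Size of the opaque orderable catalog.
#' @param p_day Probability a session is signed during the day shift
#'   (07:00-19:00).
#' @param marginals Optional list overriding demographic / context category
#'   probabilities (`sex`, `race`, `ethnicity`, `insurance`, `provider_type`,
#'   `care_group`), each a named probability vector summing to 1.
#' @param age_mean_years,age_sd_years Mean and SD of patient age (gamma
#'   distributed) at the study midpoint.
#' @param ccc_mean Poisson mean of the complex-chronic-condition count
#'   covariate (pass-through; never used by the risk model default).
#' @param seed Integer seed; identical `(config, seed)` gives byte-identical
#'   output.
#'
#' @return An object of class `rar_config` (a validated named list).
#' @examples
#' cfg <- generator_config(n_patients = 500, n_providers = 20, seed = 1)
#' cfg$base_wpoe_rate
#' @export
generator_config <- function(n_patients = 85767,
                             n_providers = 250,
                             study_start = "2020-01-01",
                             study_end = "2022-07-01",
                             sessions_per_patient_mean = 39.8,
                             orders_per_session_mean = 3,
                             base_wpoe_rate = 31.9e-5 / 0.8,
                             p_catch = 0.8,
                             beta = NULL,
                             pilot_start = "2020-09-16",
                             full_start = "2021-03-11",
                             p_photo_pilot = 0.02,
                             p_photo_full = 0.60,
                             p_benign_retract = 0.005,
                             p_benign_rar_same_patient = 0.001,
                             n_forced_rar = 0L,
                             n_codes = 500L,
                             p_day = 0.733,
                             marginals = NULL,
                             age_mean_years = 7.19,
                             age_sd_years = 6.70,
                             ccc_mean = 0.8,
                             seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    n_providers = as.integer(n_providers),
    study_start = as_utc(study_start, "study_start"),
    study_end = as_utc(study_end, "study_end"),
    sessions_per_patient_mean = sessions_per_patient_mean,
    orders_per_session_mean = orders_per_session_mean,
    base_wpoe_rate = base_wpoe_rate,
    p_catch = p_catch,
    beta = merge_beta(beta),
    pilot_start = as_utc(pilot_start, "pilot_start"),
    full_start = as_utc(full_start, "full_start"),
    p_photo_pilot = p_photo_pilot,
    p_photo_full = p_photo_full,
    p_benign_retract = p_benign_retract,
    p_benign_rar_same_patient = p_benign_rar_same_patient,
    n_forced_rar = as.integer(n_forced_rar),
    n_codes = as.integer(n_codes),
    p_day = p_day,
    marginals = utils::modifyList(default_marginals(), marginals %||% list()),
    age_mean_years = age_mean_years,
    age_sd_years = age_sd_years,
    ccc_mean = ccc_mean,
    seed = as.integer(seed)
  )
  class(cfg) <- "rar_config"
  validate_config(cfg)
}

merge_beta <- function(beta) {
  out <- default_beta()
  beta <- as.list(beta %||% list())
  for (nm in names(beta)) {
    if (!nm %in% names(out)) {
      stop("configuration error: unknown beta coefficient `", nm, "`",
           call. = FALSE)
    }
    out[[nm]] <- if (is.null(beta[[nm]])) NA_real_ else beta[[nm]]
  }
  out
}

# Risk-model truth used by the generator. Effect sizes mirror the adjusted
# odds ratios reported for pediatric inpatient RAR surveillance: photo 0.6,
# cardiac 2.12, ICU 2.05, general care 1.13, resident 1.37, day shift 0.881,
# Hispanic 0.80, age 0.985 per year.
default_beta <- function() {
  list(
    intercept = NA_real_, # NA -> calibrated from base_wpoe_rate
    photo = log(0.60),
    age_per_year = log(0.985),
    group_cardiac = log(2.12),
    group_icu = log(2.05),
    group_general = log(1.13),
    provider_fellow = log(1.06),
    provider_resident = log(1.37),
    provider_panp = 0,
    provider_other = log(1.10),
    shift_day = log(0.881),
    ethnicity_hispanic = log(0.802),
    race_black = log(1.2),
    insurance_public = log(1.09),
    sex_male = 0,
    ccc_per_condition = 0
  )
}

# Category marginals target the session-characteristic margins of a large
# pediatric inpatient cohort (male 52.6%, Black 45.6%, Hispanic 14.9%,
# public insurance 61.5%, ICU 27.6% of sessions, day shift 73.3%, ...).
default_marginals <- function() {
  list(
    sex = c(Female = 0.473985, Male = 0.5260, Unknown = 0.000015),
    race = c(White = 0.470, Black = 0.456, Asian = 0.038, Other = 0.006,
             Unknown = 0.030),
    ethnicity = c(Hispanic = 0.149, `Non-Hispanic` = 0.848, Unknown = 0.003),
    insurance = c(Public = 0.615, Private = 0.369, SelfPay = 0.016),
    provider_type = c(Attending = 0.429, Fellow = 0.075, Resident = 0.189,
                      `PA/NP` = 0.258, Other = 0.049),
    care_group = c(Cardiac = 0.106, GeneralCare = 0.290, ICU = 0.276,
                   Other = 0.328)
  )
}

as_utc <- function(x, field) {
  out <- if (inherits(x, "POSIXct")) {
    lubridate::with_tz(x, "UTC")
  } else {
    lubridate::as_datetime(x, tz = "UTC")
  }
  if (is.na(out)) {
    stop("configuration error: `", field, "` is not a parseable timestamp",
         call. = FALSE)
  }
  out
}

validate_config <- function(cfg) {
  chk_prob <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1) {
      stop("configuration error: `", field, "` must be a probability in [0, 1]",
           call. = FALSE)
    }
  }
  for (f in c("base_wpoe_rate", "p_catch", "p_photo_pilot", "p_photo_full",
              "p_benign_retract", "p_benign_rar_same_patient", "p_day")) {
    chk_prob(f)
  }
  chk_pos <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || is.na(v) || v <= 0) {
      stop("configuration error: `", field, "` must be positive", call. = FALSE)
    }
  }
  for (f in c("n_providers", "sessions_per_patient_mean", "n_codes",
              "age_mean_years", "age_sd_years")) {
    chk_pos(f)
  }
  if (cfg$n_patients < 0) {
    stop("configuration error: `n_patients` must be non-negative", call. = FALSE)
  }
  if (cfg$orders_per_session_mean < 1) {
    stop("configuration error: `orders_per_session_mean` must be >= 1",
         call. = FALSE)
  }
  if (!(cfg$study_start < cfg$pilot_start &&
        cfg$pilot_start < cfg$full_start &&
        cfg$full_start < cfg$study_end)) {
    stop("configuration error: need study_start < pilot_start < full_start ",
         "< study_end", call. = FALSE)
  }
  for (nm in names(cfg$marginals)) {
    p <- cfg$marginals[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      stop("configuration error: marginals$", nm,
           " must be non-negative and sum to 1", call. = FALSE)
    }
  }
  cfg
}

#' @exportS3Method base::print
print.rar_config <- function(x, ...) {
  cat("<rar_config>\n")
  cat("  patients:", x$n_patients, " providers:", x$n_providers, "\n")
  cat("  study:", format(x$study_start, "%Y-%m-%d"), "to",
      format(x$study_end, "%Y-%m-%d"),
      sprintf("(pilot %s, full go-live %s)\n",
              format(x$pilot_start, "%Y-%m-%d"),
              format(x$full_start, "%Y-%m-%d")))
  cat(sprintf("  sessions/patient: %.1f  wrong-patient rate: %.1f per 100k (p_catch %.2f)\n",
              x$sessions_per_patient_mean, x$base_wpoe_rate * 1e5, x$p_catch))
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Calibrate the wrong-patient intercept from the marginal rate
#'
#' Solves for the intercept of the wrong-patient logistic model so that the
#' expected wrong-patient probability among photo-unexposed sessions equals
#' `config$base_wpoe_rate`. Under the rare-event approximation
#' `E[p] ~ exp(intercept) * E[exp(beta.x)]`, the intercept is
#' `log(base_wpoe_rate) - log(M)` where `M` is the mean covariate risk
#' multiplier, computed analytically from the configured category marginals and
#' the gamma moment-generating function for age.
#'
#' @param config A [generator_config()] object.
#' @return The calibrated intercept (log-odds scale).
#' @export
calibrate_intercept <- function(config) {
  b <- config$beta
  m <- config$marginals
  gshape <- (config$age_mean_years / config$age_sd_years)^2
  gscale <- config$age_sd_years^2 / config$age_mean_years
  t <- b$age_per_year
  if (t * gscale >= 1) {
    stop("configuration error: `age_per_year` coefficient too large to calibrate",
         call. = FALSE)
  }
  m_age <- (1 - t * gscale)^(-gshape) # E[exp(t * age)], age ~ Gamma
  lvl <- function(p, ors) sum(p * ors)
  m_group <- lvl(m$care_group[c("Cardiac", "GeneralCare", "ICU", "Other")],
                 exp(c(b$group_cardiac, b$group_general, b$group_icu, 0)))
  m_prov <- lvl(m$provider_type[c("Attending", "Fellow", "Resident", "PA/NP", "Other")],
                exp(c(0, b$provider_fellow, b$provider_resident,
                      b$provider_panp, b$provider_other)))
  m_shift <- config$p_day * exp(b$shift_day) + (1 - config$p_day)
  m_eth <- lvl(m$ethnicity[c("Hispanic", "Non-Hispanic", "Unknown")],
               exp(c(b$ethnicity_hispanic, 0, 0)))
  m_race <- m$race[["Black"]] * exp(b$race_black) + (1 - m$race[["Black"]])
  m_ins <- m$insurance[["Public"]] * exp(b$insurance_public) +
    (1 - m$insurance[["Public"]])
  m_sex <- m$sex[["Male"]] * exp(b$sex_male) + (1 - m$sex[["Male"]])
  m_ccc <- exp(config$ccc_mean * (exp(b$ccc_per_condition) - 1)) # Poisson mgf
  mult <- m_age * m_group * m_prov * m_shift * m_eth * m_race * m_ins *
    m_sex * m_ccc
  log(config$base_wpoe_rate) - log(mult)
}

#' Read and write generator configurations as JSON
#'
#' @param config A [generator_config()] object.
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()` returns a
#'   validated `rar_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$study_start <- format_iso(x$study_start)
  x$study_end <- format_iso(x$study_end)
  x$pilot_start <- format_iso(x$pilot_start)
  x$full_start <- format_iso(x$full_start)
  x$marginals <- lapply(x$marginals, as.list)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$marginals <- lapply(x$marginals, unlist)
  x$beta <- as.list(x$beta)
  do.call(generator_config, x)
}

format_iso <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

`%||%` <- function(a, b) if (is.null(a)) b else a
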