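# Small, census-dense configurations: few providers relative to the session
# volume so a wrong-patient signing always finds a counterpart patient in the
# provider's same-day census.
small_config <- function(..., base_wpoe_rate = 2e-3, seed = 1) {
  rarwatch::generator_config(
    n_patients = 2000, n_providers = 2, sessions_per_patient_mean = 12,
    base_wpoe_rate = base_wpoe_rate, seed = seed, ...
  )
}

small_run <- function(cfg) {
  co <- rarwatch::generate_cohort(cfg)
  log <- rarwatch::generate_order_log(cfg, co$patients, co$providers)
  c(co, log)
}

# Synthetic analysis rows with independently drawn covariates; outcome drawn
# from a user-supplied probability function of the covariate tibble.
make_rows <- function(n, p_fun = function(d) rep(0.05, n), seed = 1) {
  set.seed(seed)
  d <- tibble::tibble(
    session_id = sprintf("S%06d", seq_len(n)),
    patient_id = sample(sprintf("P%04d", 1:max(2, n %/% 20)), n, replace = TRUE),
    provider_id = sample(sprintf("D%03d", 1:10), n, replace = TRUE),
    sign_time = lubridate::as_datetime("2021-06-01", tz = "UTC") +
      stats::runif(n, 0, 86400 * 30),
    photo = stats::runif(n) < 0.3,
    age_years = stats::rgamma(n, 1.15, scale = 6.2),
    sex = sample(c("Female", "Male"), n, replace = TRUE),
    race = sample(c("White", "Black", "Asian", "Other", "Unknown"), n,
                  replace = TRUE, prob = c(.47, .456, .038, .006, .03)),
    ethnicity = sample(c("Hispanic", "Non-Hispanic"), n, replace = TRUE,
                       prob = c(.15, .85)),
    insurance = sample(c("Public", "Private"), n, replace = TRUE),
    ccc_count = stats::rpois(n, 0.8),
    provider_type = sample(c("Attending", "Fellow", "Resident", "PA/NP",
                             "Other"), n, replace = TRUE),
    care_group = sample(c("Cardiac", "GeneralCare", "ICU", "Other"), n,
                        replace = TRUE),
    shift = factor(sample(c("Day", "Night"), n, replace = TRUE),
                   levels = c("Night", "Day")),
    period = factor(sample(c("Pre", "Pilot", "Full"), n, replace = TRUE),
                    levels = c("Pre", "Pilot", "Full"))
  )
  d$is_rar <- stats::runif(n) < p_fun(d)
  d
}
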