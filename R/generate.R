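#' Generate a synthetic patient cohort and provider census
#'
#' Draws patients (demographics, birth dates, complex-chronic-condition counts,
#' photo-acquisition times under the staged rollout) and providers from the
#' configured marginals. Photographs are never assigned to patients younger
#' than 6 months at the acquisition opportunity, and never outside the study
#' window.
#'
#' @param config A [generator_config()] object.
#' @return A list with tibbles `patients` and `providers`.
#' @examples
#' cohort <- generate_cohort(generator_config(n_patients = 100, seed = 1))
#' nrow(cohort$patients)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "rar_config"))
  set.seed(config$seed)
  m <- config$marginals
  n <- config$n_patients

  providers <- tibble::tibble(
    provider_id = sprintf("D%05d", seq_len(config$n_providers)),
    provider_type = sample_levels(m$provider_type, config$n_providers)
  )

  if (n == 0L) {
    patients <- tibble::tibble(
      patient_id = character(),
      birth_date = lubridate::as_datetime(character(0), tz = "UTC"),
      sex = character(), race = character(), ethnicity = character(),
      insurance = character(), ccc_count = integer(),
      photo_time = lubridate::as_datetime(character(0), tz = "UTC")
    )
    return(list(patients = patients, providers = providers))
  }

  gshape <- (config$age_mean_years / config$age_sd_years)^2
  gscale <- config$age_sd_years^2 / config$age_mean_years
  mid <- config$study_start + (config$study_end - config$study_start) / 2
  age_mid <- stats::rgamma(n, shape = gshape, scale = gscale)
  birth_date <- mid - lubridate::ddays(age_mid * 365.25)

  # Staged photo rollout: a small pilot unit, then system-wide capture.
  u_pilot <- stats::runif(n)
  u_full <- stats::runif(n)
  t_pilot <- runif_time(n, config$pilot_start, config$full_start)
  t_full <- runif_time(n, config$full_start, config$study_end)
  photo_time <- dplyr::if_else(
    u_pilot < config$p_photo_pilot, t_pilot,
    dplyr::if_else(u_full < config$p_photo_full, t_full,
                   lubridate::as_datetime(NA_real_, tz = "UTC"))
  )
  # No photos for infants <6 months old at the acquisition opportunity.
  age_at_photo <- as.numeric(photo_time - birth_date, units = "days") / 365.25
  photo_time[!is.na(age_at_photo) & age_at_photo < 0.5] <-
    lubridate::as_datetime(NA_real_, tz = "UTC")

  patients <- tibble::tibble(
    patient_id = sprintf("P%07d", seq_len(n)),
    birth_date = birth_date,
    sex = sample_levels(m$sex, n),
    race = sample_levels(m$race, n),
    ethnicity = sample_levels(m$ethnicity, n),
    insurance = sample_levels(m$insurance, n),
    ccc_count = stats::rpois(n, config$ccc_mean),
    photo_time = photo_time
  )
  list(patients = patients, providers = providers)
}

sample_levels <- function(probs, n) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

runif_time <- function(n, from, to) {
  lubridate::as_datetime(
    stats::runif(n, as.numeric(from), as.numeric(to)), tz = "UTC"
  )
}

#' Generate a synthetic CPOE order log with injected wrong-patient signings
#'
#' Simulates order sessions for the cohort: each session draws a care group,
#' shift, and sign time; the probability that the session is a wrong-patient
#' signing comes from the logistic risk model `logit(p) = beta %*% x`, where
#' `x` includes the session patient's photo exposure at sign time. A caught
#' wrong-patient signing (probability `p_catch`) emits the full
#' retract-and-reorder signature: every order in the session is retracted at a
#' shared Uniform(0, 600] s latency and re-placed with identical order codes on
#' the intended patient — drawn uniformly from the provider's same-day census —
#' at a further Uniform(0, 600] s latency. Uncaught signings leave no trace.
#' Benign retractions and same-patient retract-reorder decoys are injected at
#' the configured rates.
#'
#' @param config A [generator_config()] object.
#' @param patients,providers Tibbles from [generate_cohort()].
#' @return A list with `orders` (one row per placed order, `retract_time` `NA`
#'   unless retracted) and `truth`, the ground-truth ledger with one row per
#'   injected (retraction, reorder) signature. The ledger is written for
#'   validation only and must never feed the detector.
#' @export
generate_order_log <- function(config, patients, providers) {
  stopifnot(inherits(config, "rar_config"))
  set.seed(config$seed + 1L)
  empty <- empty_order_log()
  if (nrow(patients) == 0L) {
    return(empty)
  }
  if (nrow(providers) == 0L) {
    stop("generation error: provider census is empty", call. = FALSE)
  }
  m <- config$marginals
  b <- config$beta
  intercept <- if (is.na(b$intercept)) calibrate_intercept(config) else b$intercept

  n_sess_per_patient <- stats::rpois(nrow(patients), config$sessions_per_patient_mean)
  n <- sum(n_sess_per_patient)
  if (n == 0L) {
    return(empty)
  }
  pat_idx <- rep(seq_len(nrow(patients)), n_sess_per_patient)
  prov_idx <- sample.int(nrow(providers), n, replace = TRUE)

  # Sign times: uniform day in [max(study_start, birth), study_end), with the
  # time of day biased toward the 07:00-19:00 shift by p_day.
  lo <- pmax(as.numeric(config$study_start),
             as.numeric(patients$birth_date)[pat_idx])
  hi <- as.numeric(config$study_end) - 86400
  day0 <- floor(stats::runif(n, lo, pmax(lo + 1, hi)) / 86400) * 86400
  is_day <- stats::runif(n) < config$p_day
  tod <- ifelse(is_day,
                7 * 3600 + stats::runif(n) * 12 * 3600,
                (19 * 3600 + stats::runif(n) * 12 * 3600) %% 86400)
  sign_time <- lubridate::as_datetime(day0 + tod, tz = "UTC")

  care_group <- sample_levels(m$care_group, n)

  photo_time <- patients$photo_time[pat_idx]
  photo <- !is.na(photo_time) & photo_time < sign_time
  age <- pmax(0, as.numeric(sign_time - patients$birth_date[pat_idx],
                            units = "days") / 365.25)
  ptype <- providers$provider_type[prov_idx]

  eta <- intercept +
    b$photo * photo +
    b$age_per_year * age +
    b$group_cardiac * (care_group == "Cardiac") +
    b$group_icu * (care_group == "ICU") +
    b$group_general * (care_group == "GeneralCare") +
    b$provider_fellow * (ptype == "Fellow") +
    b$provider_resident * (ptype == "Resident") +
    b$provider_panp * (ptype == "PA/NP") +
    b$provider_other * (ptype == "Other") +
    b$shift_day * is_day +
    b$ethnicity_hispanic * (patients$ethnicity[pat_idx] == "Hispanic") +
    b$race_black * (patients$race[pat_idx] == "Black") +
    b$insurance_public * (patients$insurance[pat_idx] == "Public") +
    b$sex_male * (patients$sex[pat_idx] == "Male") +
    b$ccc_per_condition * patients$ccc_count[pat_idx]

  wrong <- stats::runif(n) < stats::plogis(eta)
  caught <- wrong & stats::runif(n) < config$p_catch
  if (config$n_forced_rar > 0L) {
    forced <- sample.int(n, min(config$n_forced_rar, n))
    wrong[forced] <- TRUE
    caught[forced] <- TRUE
  }

  k <- 1L + stats::rpois(n, config$orders_per_session_mean - 1)
  ord_sess <- rep(seq_len(n), k)
  n_ord <- length(ord_sess)
  codes <- sprintf("C%04d", sample.int(config$n_codes, n_ord, replace = TRUE))
  # Injected signatures must pair unambiguously: caught sessions carry
  # distinct order codes.
  for (s in which(caught & k > 1L)) {
    rows <- which(ord_sess == s)
    codes[rows] <- sprintf(
      "C%04d", sample.int(config$n_codes, length(rows), replace = FALSE))
  }

  orders <- tibble::tibble(
    patient_id = patients$patient_id[pat_idx][ord_sess],
    provider_id = providers$provider_id[prov_idx][ord_sess],
    order_code = codes,
    placed_time = sign_time[ord_sess],
    retract_time = lubridate::as_datetime(rep(NA_real_, n_ord), tz = "UTC"),
    care_group = care_group[ord_sess],
    sign_time = sign_time[ord_sess]
  )
  sess_caught <- caught[ord_sess]

  # Benign retractions (no reorder) and same-patient retract-reorder decoys.
  u_ord <- stats::runif(n_ord)
  benign <- !sess_caught & u_ord < config$p_benign_retract
  p2 <- config$p_benign_retract + config$p_benign_rar_same_patient
  decoy <- !sess_caught & u_ord >= config$p_benign_retract & u_ord < p2
  retr_lat <- runif_pos(n_ord) # per-order retraction latency, (0, 600] s
  orders$retract_time[benign | decoy] <-
    orders$placed_time[benign | decoy] + retr_lat[benign | decoy]

  decoy_rows <- which(decoy)
  decoy_orders <- NULL
  if (length(decoy_rows) > 0L) {
    re_lat <- runif_pos(length(decoy_rows))
    decoy_orders <- orders[decoy_rows, ]
    decoy_orders$placed_time <- orders$retract_time[decoy_rows] + re_lat
    decoy_orders$sign_time <- decoy_orders$placed_time
    decoy_orders$retract_time <- lubridate::as_datetime(NA_real_, tz = "UTC")
  }

  # Caught wrong-patient signings: retract the whole session, reorder on the
  # intended patient drawn from the provider's same-day census.
  caught_sess <- which(caught)
  reorders <- NULL
  truth <- empty_truth()
  if (length(caught_sess) > 0L) {
    day_key <- paste(providers$provider_id[prov_idx],
                     as.Date(sign_time, tz = "UTC"))
    census <- split(patients$patient_id[pat_idx], day_key)
    lat1 <- runif_pos(length(caught_sess))
    lat2 <- runif_pos(length(caught_sess))
    correct_pat <- character(length(caught_sess))
    for (i in seq_along(caught_sess)) {
      s <- caught_sess[i]
      cand <- setdiff(unique(census[[day_key[s]]]), patients$patient_id[pat_idx[s]])
      if (length(cand) == 0L) {
        stop("generation error: provider ", providers$provider_id[prov_idx[s]],
             " has an empty same-day census on ",
             as.Date(sign_time[s], tz = "UTC"),
             "; no counterpart patient for a wrong-patient signing",
             call. = FALSE)
      }
      correct_pat[i] <- cand[sample.int(length(cand), 1L)]
    }
    sess_pos <- match(ord_sess, caught_sess) # NA for uninvolved orders
    involved <- which(!is.na(sess_pos))
    pos <- sess_pos[involved]
    orders$retract_time[involved] <- orders$placed_time[involved] + lat1[pos]
    reorders <- orders[involved, ]
    reorders$patient_id <- correct_pat[pos]
    reorders$placed_time <- orders$retract_time[involved] + lat2[pos]
    reorders$sign_time <- reorders$placed_time
    reorders$retract_time <- lubridate::as_datetime(NA_real_, tz = "UTC")
    truth_pos <- pos
  }

  all_orders <- dplyr::bind_rows(orders, decoy_orders, reorders)
  all_orders$order_id <- sprintf("O%09d", seq_len(nrow(all_orders)))
  all_orders <- dplyr::relocate(all_orders, "order_id")

  if (length(caught_sess) > 0L) {
    n_base <- nrow(orders) + length(decoy_rows)
    reorder_ids <- all_orders$order_id[n_base + seq_len(nrow(reorders))]
    truth <- tibble::tibble(
      retracted_order_id = all_orders$order_id[involved],
      reorder_order_id = reorder_ids,
      provider_id = orders$provider_id[involved],
      wrong_patient_id = orders$patient_id[involved],
      correct_patient_id = correct_pat[truth_pos],
      place_to_retract_s = lat1[truth_pos],
      retract_to_reorder_s = lat2[truth_pos]
    )
  }
  list(orders = all_orders, truth = truth)
}

runif_pos <- function(n, upper = 600) {
  upper - stats::runif(n) * upper * (1 - 1e-9) # (0, upper]
}

empty_order_log <- function() {
  list(
    orders = tibble::tibble(
      order_id = character(), patient_id = character(),
      provider_id = character(), order_code = character(),
      placed_time = lubridate::as_datetime(character(0), tz = "UTC"),
      retract_time = lubridate::as_datetime(character(0), tz = "UTC"),
      care_group = character(),
      sign_time = lubridate::as_datetime(character(0), tz = "UTC")
    ),
    truth = empty_truth()
  )
}

empty_truth <- function() {
  tibble::tibble(
    retracted_order_id = character(), reorder_order_id = character(),
    provider_id = character(), wrong_patient_id = character(),
    correct_patient_id = character(), place_to_retract_s = numeric(),
    retract_to_reorder_s = numeric()
  )
}

#' Write a synthetic order log to a directory of CSV files
#'
#' Writes `orders.csv`, `patients.csv`, `providers.csv` and `truth.csv` with
#' ISO-8601 UTC timestamps and empty fields for missing values, plus the
#' configuration as `config.json`.
#'
#' @param config A [generator_config()] object.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
simulate_to_dir <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config)
  log <- generate_order_log(config, cohort$patients, cohort$providers)
  write_timed_csv(cohort$patients, file.path(dir, "patients.csv"))
  write_timed_csv(cohort$providers, file.path(dir, "providers.csv"))
  write_timed_csv(log$orders, file.path(dir, "orders.csv"))
  write_timed_csv(log$truth, file.path(dir, "truth.csv"))
  write_config(config, file.path(dir, "config.json"))
  invisible(dir)
}

write_timed_csv <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(
    dplyr::where(lubridate::is.POSIXct), format_iso))
  readr::write_csv(df, path, na = "")
  invisible(path)
}
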