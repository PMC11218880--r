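#' Group orders into provider signing sessions
#'
#' An order session — the unit of analysis — is the set of orders one provider
#' signs for one patient at one sign time. If one order of a session is placed
#' on the wrong patient, all of them are, so the session (not the order) is
#' the denominator unit and a session is a RAR session as soon as any of its
#' orders is a detected RAR retraction.
#'
#' @param orders Order tibble carrying `sign_time` (see [read_orders()]).
#' @param rar_ids Character vector of retracted (wrong-patient) order ids,
#'   from [rar_order_ids()].
#' @param tolerance_s Sign-time jitter tolerance in seconds (default 0:
#'   exact-equality grouping). When positive, sign times are binned to
#'   multiples of `tolerance_s` before grouping, for feeds whose signing
#'   action stamps slightly different times on each order.
#' @return A tibble of sessions: `session_id`, `patient_id`, `provider_id`,
#'   `sign_time`, `order_ids` (list column), `n_orders`, `is_rar`,
#'   `care_group`.
#' @export
build_sessions <- function(orders, rar_ids = character(0), tolerance_s = 0) {
  if (!"sign_time" %in% names(orders)) {
    stop("data-integrity error: orders missing column(s) sign_time",
         call. = FALSE)
  }
  orders$sign_time <- parse_time_col(orders$sign_time, "sign_time")
  if (anyNA(orders$sign_time)) {
    stop("data-integrity error: order with missing sign_time at row ",
         which(is.na(orders$sign_time))[1L], call. = FALSE)
  }
  key_time <- as.numeric(orders$sign_time)
  if (tolerance_s > 0) {
    key_time <- floor(key_time / tolerance_s) * tolerance_s
  }
  key <- paste(orders$patient_id, orders$provider_id, key_time, sep = "\r")
  first <- !duplicated(key)
  g <- match(key, key[first])
  k <- sum(first)
  flagged <- orders$order_id %in% rar_ids
  sessions <- tibble::tibble(
    patient_id = orders$patient_id[first],
    provider_id = orders$provider_id[first],
    sign_time = orders$sign_time[first],
    order_ids = unname(split(orders$order_id, factor(g, levels = seq_len(k)))),
    n_orders = tabulate(g, nbins = k),
    is_rar = rowsum(as.integer(flagged), g)[, 1L] > 0L,
    care_group = if ("care_group" %in% names(orders)) {
      orders$care_group[first]
    } else {
      NA_character_
    }
  )
  sessions <- sessions[order(sessions$sign_time, sessions$provider_id,
                             sessions$patient_id), ]
  sessions$session_id <- sprintf("S%08d", seq_len(k))
  dplyr::relocate(sessions, "session_id")
}

#' Assign the photo-rollout period of a sign time
#'
#' `Pre` before the pilot start, `Pilot` from the pilot start up to (not
#' including) the full go-live, `Full` from the go-live on.
#'
#' @param sign_time POSIXct vector (or parseable strings).
#' @param pilot_start,full_start Period boundaries; defaults are the rollout
#'   dates of the emulated implementation (2020-09-16 and 2021-03-11).
#' @return Factor with levels `Pre`, `Pilot`, `Full`.
#' @examples
#' assign_period(c("2020-09-15 23:59", "2020-12-01", "2021-03-11 00:00"))
#' @export
assign_period <- function(sign_time,
                          pilot_start = "2020-09-16",
                          full_start = "2021-03-11") {
  sign_time <- parse_time_col(sign_time, "sign_time")
  pilot_start <- as_utc(pilot_start, "pilot_start")
  full_start <- as_utc(full_start, "full_start")
  out <- dplyr::case_when(
    sign_time < pilot_start ~ "Pre",
    sign_time < full_start ~ "Pilot",
    TRUE ~ "Full"
  )
  factor(out, levels = c("Pre", "Pilot", "Full"))
}

#' Assign the day/night shift of a sign time
#'
#' Day is the 12-hour window from 07:00 (inclusive) to 19:00 (exclusive),
#' local clock time of the timestamp; everything else is Night.
#'
#' @param sign_time POSIXct vector (or parseable strings).
#' @return Factor with levels `Night`, `Day` (`Night` first: the model
#'   reference level).
#' @export
assign_shift <- function(sign_time) {
  sign_time <- parse_time_col(sign_time, "sign_time")
  hr <- lubridate::hour(sign_time)
  factor(ifelse(hr >= 7 & hr < 19, "Day", "Night"),
         levels = c("Night", "Day"))
}

#' Build the session-level analysis table
#'
#' One row per order session with the outcome flag, the photo exposure, and
#' all analysis covariates. Photo exposure is strict: the patient's photo must
#' have been acquired *before* the session sign time (a photo acquired at
#' exactly the sign time does not count). Age is fractional years
#' (days / 365.25) at sign time.
#'
#' @param sessions Tibble from [build_sessions()].
#' @param patients,providers Cohort tibbles (generator dialect).
#' @param pilot_start,full_start Passed to [assign_period()].
#' @return A tibble with one analysis row per session: `session_id`,
#'   `is_rar`, `photo`, `age_years`, `sex`, `race`, `ethnicity`, `insurance`,
#'   `ccc_count`, `provider_type`, `care_group`, `shift`, `period`, plus
#'   `patient_id`, `provider_id` and `sign_time` for clustering and trend
#'   binning.
#' @export
build_analysis_table <- function(sessions, patients, providers,
                                 pilot_start = "2020-09-16",
                                 full_start = "2021-03-11") {
  bad_p <- setdiff(sessions$patient_id, patients$patient_id)
  bad_d <- setdiff(sessions$provider_id, providers$provider_id)
  if (length(bad_p) > 0L || length(bad_d) > 0L) {
    stop("data-integrity error: unresolvable ids: ",
         paste(utils::head(c(bad_p, bad_d), 5L), collapse = ", "),
         call. = FALSE)
  }
  pi <- match(sessions$patient_id, patients$patient_id)
  di <- match(sessions$provider_id, providers$provider_id)
  tibble::tibble(
    session_id = sessions$session_id,
    patient_id = sessions$patient_id,
    provider_id = sessions$provider_id,
    sign_time = sessions$sign_time,
    is_rar = sessions$is_rar,
    photo = !is.na(patients$photo_time[pi]) &
      patients$photo_time[pi] < sessions$sign_time,
    age_years = pmax(0, as.numeric(
      sessions$sign_time - patients$birth_date[pi], units = "days") / 365.25),
    sex = patients$sex[pi],
    race = patients$race[pi],
    ethnicity = patients$ethnicity[pi],
    insurance = patients$insurance[pi],
    ccc_count = patients$ccc_count[pi],
    provider_type = providers$provider_type[di],
    care_group = sessions$care_group,
    shift = assign_shift(sessions$sign_time),
    period = assign_period(sessions$sign_time, pilot_start, full_start)
  )
}

#' RAR rate per `per` order sessions
#'
#' @param rows Analysis tibble (needs `is_rar`).
#' @param per Denominator scale (default 100 000 sessions).
#' @param subset Optional logical vector (or expression evaluated in `rows`)
#'   selecting the sessions to include.
#' @return A one-row tibble: `events`, `sessions`, `rate` (events per `per`
#'   sessions).
#' @examples
#' rows <- tibble::tibble(is_rar = c(TRUE, rep(FALSE, 99999)))
#' rar_rate(rows) # 1 per 100 000
#' @export
rar_rate <- function(rows, per = 100000, subset = NULL) {
  stopifnot(per > 0)
  keep <- rlang::eval_tidy(rlang::enquo(subset), data = rows)
  if (!is.null(keep)) {
    rows <- rows[keep, , drop = FALSE]
  }
  n <- nrow(rows)
  if (n == 0L) {
    stop("undefined rate: empty session subset", call. = FALSE)
  }
  k <- sum(rows$is_rar)
  tibble::tibble(events = k, sessions = n, rate = k / n * per)
}
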