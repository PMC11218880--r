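t0 <- lubridate::as_datetime("2021-06-01 10:00:00", tz = "UTC")

demo_orders <- function() {
  tibble::tibble(
    order_id = c("o1", "o2", "o3", "o4", "o5"),
    patient_id = c("P1", "P1", "P1", "P1", "P2"),
    provider_id = "D1",
    order_code = paste0("C", 1:5),
    placed_time = c(rep(t0, 4), t0 + 3600),
    retract_time = lubridate::as_datetime(NA_real_, tz = "UTC"),
    care_group = "ICU",
    sign_time = c(rep(t0, 4), t0 + 3600)
  )
}

test_that("orders sharing patient, provider and sign time form one session", {
  s <- build_sessions(demo_orders(), rar_ids = "o2")
  expect_identical(nrow(s), 2L)
  s1 <- s[s$patient_id == "P1", ]
  expect_identical(s1$n_orders, 4L)
  expect_true(s1$is_rar)
  expect_false(s[s$patient_id == "P2", ]$is_rar)
})

test_that("orders differing only in sign time split into sessions", {
  o <- demo_orders()[1:2, ]
  o$sign_time[2] <- t0 + 1
  o$placed_time[2] <- t0 + 1
  expect_identical(nrow(build_sessions(o)), 2L)
  # a jitter tolerance merges them back
  expect_identical(nrow(build_sessions(o, tolerance_s = 60)), 1L)
})

test_that("sessions partition the orders of a synthetic log", {
  run <- small_run(small_config(seed = 21))
  ev <- detect_rar_events(run$orders)
  s <- build_sessions(run$orders, rar_order_ids(ev))
  expect_identical(sum(s$n_orders), nrow(run$orders))
  expect_setequal(unlist(s$order_ids), run$orders$order_id)
  # flag consistency: RAR sessions <= RAR events <= retracted orders
  expect_lte(sum(s$is_rar), nrow(ev))
  expect_lte(nrow(ev), sum(!is.na(run$orders$retract_time)))
})

test_that("missing sign time is an integrity error", {
  o <- demo_orders()
  o$sign_time[3] <- NA
  expect_error(build_sessions(o), "missing sign_time")
})

test_that("period assignment splits at the pilot and go-live instants", {
  expect_identical(as.character(assign_period("2020-09-15 23:59:59")), "Pre")
  expect_identical(as.character(assign_period("2020-09-16 00:00:00")), "Pilot")
  expect_identical(as.character(assign_period("2020-12-01")), "Pilot")
  expect_identical(as.character(assign_period("2021-03-11 00:00:00")), "Full")
  expect_identical(as.character(assign_period("2021-03-10 23:59:59")), "Pilot")
})

test_that("day shift is [07:00, 19:00) local time", {
  expect_identical(as.character(assign_shift("2021-01-01 07:00:00")), "Day")
  expect_identical(as.character(assign_shift("2021-01-01 18:59:59")), "Day")
  expect_identical(as.character(assign_shift("2021-01-01 19:00:00")), "Night")
  expect_identical(as.character(assign_shift("2021-01-01 06:59:59")), "Night")
  set.seed(1)
  u <- lubridate::as_datetime("2021-01-01", tz = "UTC") +
    stats::runif(20000, 0, 86400)
  expect_equal(mean(assign_shift(u) == "Day"), 0.5, tolerance = 0.02)
})

test_that("photo exposure is strictly before the sign time", {
  pts <- tibble::tibble(
    patient_id = c("P1", "P2"),
    birth_date = t0 - lubridate::dyears(5),
    sex = "Female", race = "White", ethnicity = "Non-Hispanic",
    insurance = "Public", ccc_count = 0L,
    photo_time = c(t0, lubridate::as_datetime(NA_real_, tz = "UTC"))
  )
  prov <- tibble::tibble(provider_id = "D1", provider_type = "Attending")
  o <- demo_orders()
  o$patient_id[5] <- "P1" # same patient signs again an hour later
  o2 <- demo_orders()[5, ]
  o2$order_id <- "o6"
  s <- build_sessions(dplyr::bind_rows(o, o2))
  rows <- build_analysis_table(s, pts, prov)
  # P1's photo lands exactly at the first session's sign time -> unexposed
  expect_false(rows$photo[rows$patient_id == "P1" & rows$sign_time == t0])
  # ... but counts for the later session of the same patient
  expect_true(rows$photo[rows$patient_id == "P1" & rows$sign_time > t0])
  # a patient with no photo on file is never exposed
  expect_false(any(rows$photo[rows$patient_id == "P2"]))
})

test_that("photo exposure is non-decreasing over a patient's sessions", {
  run <- small_run(small_config(seed = 22))
  rows <- build_analysis_table(
    build_sessions(run$orders), run$patients, run$providers)
  rows <- dplyr::arrange(rows, patient_id, sign_time)
  jumps <- rows |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(ok = all(diff(photo) >= 0), .groups = "drop")
  expect_true(all(jumps$ok))
})

test_that("photo-exposed session fraction matches the rollout target", {
  cfg <- generator_config(n_patients = 4000, n_providers = 5,
                          sessions_per_patient_mean = 12,
                          base_wpoe_rate = 0, seed = 23)
  run <- small_run(cfg)
  rows <- build_analysis_table(
    build_sessions(run$orders), run$patients, run$providers)
  expect_lt(abs(mean(rows$photo) - 0.168), 0.02)
})

test_that("unresolvable foreign keys are integrity errors", {
  prov <- tibble::tibble(provider_id = "D1", provider_type = "Attending")
  pts <- tibble::tibble(patient_id = "P9", birth_date = t0,
                        sex = "F", race = "White",
                        ethnicity = "Non-Hispanic", insurance = "Public",
                        ccc_count = 0L,
                        photo_time = lubridate::as_datetime(NA_real_))
  expect_error(build_analysis_table(build_sessions(demo_orders()), pts, prov),
               "unresolvable ids.*P1")
})

test_that("rar_rate reproduces hand-computed rates and rejects empty subsets", {
  rows <- tibble::tibble(is_rar = c(rep(TRUE, 944), rep(FALSE, 3414770 - 944)),
                         grp = "a")
  r <- rar_rate(rows)
  expect_equal(r$rate, 944 / 3414770 * 1e5) # 27.64 per 100 000
  expect_identical(r$events, 944L)
  expect_equal(rar_rate(tibble::tibble(is_rar = rep(FALSE, 10)))$rate, 0)
  expect_equal(rar_rate(tibble::tibble(is_rar = c(TRUE, rep(FALSE, 99999))))$rate,
               1)
  expect_error(rar_rate(rows, subset = rows$grp == "b"), "empty")
})
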