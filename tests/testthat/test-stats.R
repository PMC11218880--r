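random_table <- function(seed) {
  set.seed(seed)
  contingency_table(sample(1:500, 1), sample(1:5000, 1),
                    sample(1:500, 1), sample(1:5000, 1))
}

test_that("cross-product OR equals the saturated logistic fit exactly", {
  for (s in 1:25) {
    t <- random_table(s)
    r <- contingency_or(t)
    counts <- c(t$exposed_events, t$exposed_nonevents,
                t$unexposed_events, t$unexposed_nonevents)
    d <- data.frame(exposed = c(1, 1, 0, 0), event = c(1, 0, 1, 0))
    fit <- stats::glm(event ~ exposed, family = stats::binomial(),
                      data = d, weights = counts,
                      control = stats::glm.control(epsilon = 1e-14))
    est <- stats::coef(fit)[["exposed"]]
    se <- summary(fit)$coefficients["exposed", 2]
    expect_equal(r$odds_ratio, exp(est), tolerance = 1e-10)
    expect_equal(log(r$ci_high / r$ci_low) / 2 / stats::qnorm(0.975), se,
                 tolerance = 1e-6)
  }
})

test_that("odds ratios are reciprocal under label inversion and consistent", {
  for (s in 26:45) {
    t <- random_table(s)
    r <- contingency_or(t)
    flipped <- contingency_table(t$unexposed_events, t$unexposed_nonevents,
                                 t$exposed_events, t$exposed_nonevents)
    rf <- contingency_or(flipped)
    expect_equal(r$odds_ratio * rf$odds_ratio, 1, tolerance = 1e-12)
    expect_true(r$ci_low <= r$odds_ratio && r$odds_ratio <= r$ci_high)
    # Wald CI excludes 1 <=> Wald p < .05
    expect_identical(r$ci_low > 1 || r$ci_high < 1, r$p_value < 0.05)
  }
})

test_that("symmetric tables give OR 1 with a symmetric interval", {
  r <- contingency_or(contingency_table(10, 10, 10, 10))
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$ci_low * r$ci_high, 1, tolerance = 1e-12)
  expect_equal(r$p_value, 1)
})

test_that("zero cells error unless the Haldane correction is requested", {
  t <- contingency_table(0, 100, 5, 100)
  expect_error(contingency_or(t), "haldane")
  r <- contingency_or(t, haldane = TRUE)
  expect_identical(r$method, "wald-haldane")
  expect_equal(r$odds_ratio, (0.5 * 100.5) / (100.5 * 5.5))
})

test_that("one-vs-rest tables of a two-level variable are transposes", {
  rows <- make_rows(500, seed = 2)
  tabs <- one_vs_rest_tables(rows, "sex")
  expect_named(tabs, c("Female", "Male"), ignore.order = TRUE)
  expect_identical(tabs$Female$exposed_events, tabs$Male$unexposed_events)
  or1 <- contingency_or(tabs$Female, haldane = TRUE)$odds_ratio
  or2 <- contingency_or(tabs$Male, haldane = TRUE)$odds_ratio
  expect_equal(or1 * or2, 1, tolerance = 1e-12)
  expect_error(one_vs_rest_tables(rows[rows$sex == "Male", ], "sex"),
               "2 levels")
})

test_that("one-vs-rest ORs hover around 1 when labels carry no signal", {
  rows <- make_rows(20000, p_fun = function(d) rep(0.05, nrow(d)), seed = 3)
  tabs <- one_vs_rest_tables(rows, "care_group")
  ors <- vapply(tabs, function(t) contingency_or(t)$odds_ratio, numeric(1))
  expect_true(all(ors > 0.75 & ors < 1.33))
})

test_that("chi-square and Welch tests reproduce published table statistics", {
  # ethnicity 2x2: P prints as .004
  p_eth <- chi_square_test(contingency_table(109, 508928, 833, 2896028))$p_value
  expect_equal(round(p_eth, 3), 0.004)
  # provider 5x2: P prints as .007
  prov <- cbind(events = c(353, 78, 210, 260, 43),
                nonevents = c(1464390, 255723, 646791, 879300, 167622))
  expect_equal(round(chi_square_test(prov)$p_value, 3), 0.007)
  # photo 2x2: P prints as <.001
  expect_lt(chi_square_test(contingency_table(90, 573262, 854, 2840564))$p_value,
            0.001)
  # age summaries: P prints as <.001
  expect_lt(welch_t_test(7.19, 6.70, 3413826, 5.75, 6.50, 944)$p_value, 0.001)
})

test_that("degenerate chi-square inputs are rejected", {
  expect_error(chi_square_test(contingency_table(0, 0, 5, 10)), "zero margin")
  p <- chi_square_test(contingency_table(50, 950, 500, 9500))$p_value
  expect_equal(p, 1, tolerance = 1e-9) # identical proportions
})

test_that("Welch test from summaries behaves at its closed-form limits", {
  expect_equal(welch_t_test(5, 2, 100, 5, 2, 100)$p_value, 1)
  # 3-standard-error mean shift at large n -> p ~ 2*pnorm(-3) = 0.0027
  n <- 1e6
  shift <- 3 * sqrt(2 / n)
  expect_equal(welch_t_test(0, 1, n, shift, 1, n)$p_value, 2 * stats::pnorm(-3),
               tolerance = 1e-3)
  expect_error(welch_t_test(5, 0, 100, 5, 2, 100), "positive")
  expect_error(welch_t_test(5, 1, 1, 5, 2, 100), "n > 1")
})

test_that("equal-proportions test is exact under equality and scales", {
  expect_equal(equal_proportions_test(30, 100000, 30, 100000)$p_value, 1)
  expect_equal(equal_proportions_test(30, 100000, 60, 200000)$p_value, 1)
  expect_error(equal_proportions_test(30, 10, 5, 100), "exceed")
})

test_that("period-rate contrast has power at published effect sizes", {
  # pre 31.9 vs full 24.3 per 100k at ~1.2M sessions each
  reject <- 0L
  for (s in 1:10) {
    set.seed(s)
    x1 <- stats::rbinom(1, 1200000, 31.9e-5)
    x2 <- stats::rbinom(1, 1200000, 24.3e-5)
    p <- equal_proportions_test(x1, 1200000, x2, 1200000)$p_value
    reject <- reject + (p < 0.05)
  }
  expect_gte(reject, 6)
})

test_that("univariable screen keeps signal and drops noise at the 0.1 rule", {
  rows <- make_rows(4000, p_fun = function(d) ifelse(d$photo, 0.4, 0.05),
                    seed = 5)
  scr <- univariable_screen(rows, covariates = c("photo", "ccc_count"))
  expect_true(scr$selected[scr$covariate == "photo"])
  # a covariate independent of the outcome enters ~10% of the time
  hits <- 0L
  for (s in 1:60) {
    rows <- make_rows(400, p_fun = function(d) rep(0.3, nrow(d)), seed = 500 + s)
    scr <- univariable_screen(rows, covariates = "ccc_count")
    hits <- hits + scr$selected[1]
  }
  expect_lte(hits, 18) # E[hits] = 6 under the null
})

test_that("a single binary predictor reproduces the cross-product OR exactly", {
  rows <- make_rows(5000, p_fun = function(d) ifelse(d$photo, 0.02, 0.06),
                    seed = 6)
  fit <- fit_logistic(rows, covariates = "photo")
  tab <- one_vs_rest_tables(
    tibble::tibble(level = c("Yes", "No"),
                   events = c(sum(rows$is_rar & rows$photo),
                              sum(rows$is_rar & !rows$photo)),
                   nonevents = c(sum(!rows$is_rar & rows$photo),
                                 sum(!rows$is_rar & !rows$photo))))
  or <- contingency_or(tab$Yes)
  expect_equal(fit$coefficients$aor, or$odds_ratio, tolerance = 1e-8)
  expect_equal(fit$coefficients$ci_low, or$ci_low, tolerance = 1e-6)
})

test_that("null-model Wald intervals cover 1 at the nominal rate", {
  covered <- 0L
  for (s in 1:20) {
    rows <- make_rows(5000, p_fun = function(d) rep(0.05, nrow(d)),
                      seed = 700 + s)
    fit <- fit_logistic(rows)
    ph <- fit$coefficients[fit$coefficients$variable == "photo", ]
    covered <- covered + (ph$ci_low <= 1 && 1 <= ph$ci_high)
  }
  expect_gte(covered, 16) # nominal 95%
})

test_that("small-cell exclusions are applied and tallied", {
  rows <- make_rows(2000, seed = 8)
  rows$sex[1:7] <- "Unknown"
  rows$insurance[8:19] <- "SelfPay"
  fit <- fit_logistic(rows)
  expect_identical(unname(fit$excluded["sex_unknown"]), 7L)
  expect_identical(unname(fit$excluded["insurance_selfpay"]), 12L)
  expect_identical(fit$n_used, nrow(rows) - 19L)
})

test_that("degenerate outcomes raise separation errors", {
  rows <- make_rows(500, seed = 9)
  rows$photo <- TRUE
  expect_error(photo_predictor_model(rows), "separation|degenerate")
  rows2 <- make_rows(500, seed = 10)
  rows2$is_rar <- FALSE
  expect_error(fit_logistic(rows2), "degenerate")
})

test_that("photo-predictor model recovers a stratum with lower uptake", {
  rows <- make_rows(30000, seed = 11)
  set.seed(11)
  p_photo <- ifelse(rows$ethnicity == "Hispanic", 0.15, 0.30)
  rows$photo <- stats::runif(nrow(rows)) < p_photo
  fit <- photo_predictor_model(rows)
  hs <- fit$coefficients[fit$coefficients$level == "Hispanic", ]
  expect_lt(hs$ci_high, 1)
  truth <- (0.15 / 0.85) / (0.30 / 0.70)
  expect_true(hs$ci_low <= truth && truth <= hs$ci_high)
})

test_that("mixed model with singleton clusters matches the fixed fit", {
  rows <- make_rows(3000, p_fun = function(d) ifelse(d$photo, 0.03, 0.08),
                    seed = 12)
  rows$patient_id <- sprintf("P%05d", seq_len(nrow(rows)))
  rows$provider_id <- sprintf("D%05d", seq_len(nrow(rows)))
  fixed <- fit_logistic(rows, covariates = c("photo", "age_years"))
  mixed <- fit_logistic_mixed(rows, covariates = c("photo", "age_years"))
  expect_identical(mixed$model, "mixed")
  for (i in seq_len(nrow(fixed$coefficients))) {
    expect_lt(abs(mixed$coefficients$estimate[i] -
                    fixed$coefficients$estimate[i]),
              2 * fixed$coefficients$se[i])
  }
})

test_that("mixed model detects real cluster heterogeneity", {
  set.seed(13)
  n <- 8000
  rows <- make_rows(n, seed = 13)
  rows$patient_id <- sample(sprintf("P%03d", 1:150), n, replace = TRUE)
  u <- stats::rnorm(150, sd = 1.5)
  eta <- -2.5 + u[as.integer(factor(rows$patient_id))]
  rows$is_rar <- stats::runif(n) < stats::plogis(eta)
  mixed <- fit_logistic_mixed(rows, covariates = "age_years",
                              clusters = "patient_id")
  expect_gt(mixed$varcomp$variance[mixed$varcomp$cluster == "patient_id"], 0)
})

test_that("missing cluster ids are integrity errors", {
  rows <- make_rows(200, seed = 14)
  rows$provider_id <- NULL
  expect_error(fit_logistic_mixed(rows), "provider_id")
})
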