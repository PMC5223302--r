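design_21 <- randomize_arms(assign_triplets(make_clusters(21, seed = 1)), seed = 2)

test_that("parameter validation enforces probabilities, sites and support", {
  expect_error(sim_params(report_prob = 1.2), "\\[0, 1\\]")
  expect_error(sim_params(site_probs = list(rti = c(0.5, 0.4, 0.2),
                                            gti = c(0.33, 0.56, 0.11))),
               "sum to 1")
  expect_error(sim_params(sigma_person = 2), "support")
  expect_error(sim_params(beta_exp_same = c(rti = 3, gti = 3)), "support")
  m <- seasonal_months()
  m[1, ] <- 0.1
  expect_error(sim_params(beta_month = m), "reference month")
  expect_s3_class(default_calibration(), "sim_params")
})

test_that("zero baseline risk produces no symptom weeks", {
  p <- default_calibration(beta0 = c(rti = -Inf, gti = -Inf),
                           n_weeks = 10, reporters_per_cluster = 5)
  pw <- simulate_trial(design_21, p, seed = 4)
  expect_equal(sum(pw$rti_symptoms, na.rm = TRUE), 0)
  expect_equal(sum(pw$gti_symptoms, na.rm = TRUE), 0)
})

test_that("with no heterogeneity the weekly prevalence matches exp(beta0)", {
  p <- sim_params(
    beta0 = c(rti = log(0.12), gti = log(0.02)),
    beta_arm = list(rti = c(soap_water = 0, alcohol_rub = 0),
                    gti = c(soap_water = 0, alcohol_rub = 0)),
    beta_exp_same = c(rti = 0, gti = 0), beta_exp_lag = c(rti = 0, gti = 0),
    beta_interact = list(rti = c(soap_water = 0, alcohol_rub = 0),
                         gti = c(soap_water = 0, alcohol_rub = 0)),
    beta_month = seasonal_months(c(rti = 0, gti = 0)),
    sigma_person = 0, sigma_cluster = 0,
    exposure_rate = list(rti = c(control = 0, soap_water = 0, alcohol_rub = 0),
                         gti = c(control = 0, soap_water = 0, alcohol_rub = 0)),
    n_weeks = 70, reporters_per_cluster = 35, report_prob = 1,
    dropout_hazard = 0, include_days = FALSE)
  pw <- simulate_trial(design_21, p, seed = 5)
  n <- nrow(pw)
  expect_gt(n, 50000)
  se <- sqrt(0.12 * 0.88 / n)
  expect_lt(abs(mean(pw$rti_symptoms) - 0.12), 3 * se)
})

test_that("marginal prevalence follows the lognormal mean identity", {
  # untruncated configuration: tiny baseline risk, sizeable person SD
  p <- sim_params(
    beta0 = c(rti = log(0.01), gti = log(0.005)),
    beta_arm = list(rti = c(soap_water = 0, alcohol_rub = 0),
                    gti = c(soap_water = 0, alcohol_rub = 0)),
    beta_exp_same = c(rti = 0, gti = 0), beta_exp_lag = c(rti = 0, gti = 0),
    beta_interact = list(rti = c(soap_water = 0, alcohol_rub = 0),
                         gti = c(soap_water = 0, alcohol_rub = 0)),
    beta_month = seasonal_months(c(rti = 0, gti = 0)),
    sigma_person = 0.5, sigma_cluster = 0,
    exposure_rate = list(rti = c(control = 0, soap_water = 0, alcohol_rub = 0),
                         gti = c(control = 0, soap_water = 0, alcohol_rub = 0)),
    n_weeks = 70, reporters_per_cluster = 35, report_prob = 1,
    dropout_hazard = 0, include_days = FALSE)
  pw <- simulate_trial(design_21, p, seed = 6)
  target <- 0.01 * exp(0.5^2 / 2)
  # person-level clustering dominates the Monte-Carlo error
  person_means <- tapply(pw$rti_symptoms, pw$person_id, mean)
  se <- stats::sd(person_means) / sqrt(length(person_means))
  expect_lt(abs(mean(pw$rti_symptoms) - target), 3 * se)
})

test_that("conditional prevalence ratio given exposure converges to exp(beta)", {
  p <- sim_params(
    beta0 = c(rti = log(0.03), gti = log(0.005)),
    beta_arm = list(rti = c(soap_water = 0, alcohol_rub = 0),
                    gti = c(soap_water = 0, alcohol_rub = 0)),
    beta_exp_same = c(rti = log(5), gti = 0), beta_exp_lag = c(rti = 0, gti = 0),
    beta_interact = list(rti = c(soap_water = 0, alcohol_rub = 0),
                         gti = c(soap_water = 0, alcohol_rub = 0)),
    beta_month = seasonal_months(c(rti = 0, gti = 0)),
    sigma_person = 0, sigma_cluster = 0,
    n_weeks = 70, reporters_per_cluster = 69, report_prob = 1,
    dropout_hazard = 0, include_days = FALSE)
  pw <- simulate_trial(design_21, p, seed = 7)
  expect_gt(nrow(pw), 1e5)
  rows <- build_analysis_rows(pw, "rti")
  k1 <- sum(rows$y[rows$exp_same]); n1 <- sum(rows$exp_same)
  k0 <- sum(rows$y[!rows$exp_same]); n0 <- sum(!rows$exp_same)
  log_ratio <- log((k1 / n1) / (k0 / n0))
  se <- sqrt((1 - k1 / n1) / k1 + (1 - k0 / n0) / k0)
  expect_lt(abs(log_ratio - log(5)), 3 * se)
})

test_that("identical seed and parameters reproduce the dataset exactly", {
  p <- default_calibration(n_weeks = 12, reporters_per_cluster = 6)
  pw1 <- simulate_trial(design_21, p, seed = 11)
  pw2 <- simulate_trial(design_21, p, seed = 11)
  expect_identical(pw1, pw2)
  pw3 <- simulate_trial(design_21, p, seed = 12)
  expect_false(identical(pw1, pw3))
})

test_that("a realized risk at or above one aborts naming the pattern", {
  p <- default_calibration(n_weeks = 10, reporters_per_cluster = 10)
  p$sigma_person <- 3  # bypass construction check to hit the runtime guard
  expect_error(simulate_trial(design_21, p, seed = 13),
               "risk >= 1.*arm=")
})

test_that("unreported weeks carry no symptom or exposure values", {
  p <- default_calibration(n_weeks = 20, reporters_per_cluster = 10,
                           report_prob = 0.7)
  pw <- simulate_trial(design_21, p, seed = 14)
  un <- !pw$reported
  expect_true(any(un))
  expect_true(all(is.na(pw$rti_symptoms[un])))
  expect_true(all(is.na(pw$gti_exposure[un])))
  expect_true(all(is.na(pw$rti_site[un])))
  # site is none exactly when no exposure was reported
  rep_rows <- pw[pw$reported, ]
  expect_identical(rep_rows$rti_site == "none", !rep_rows$rti_exposure)
  # day vectors agree with the weekly flag
  flags <- rowSums(rep_rows[paste0("rti_d", 1:7)] == 1L) > 0
  expect_identical(unname(flags), unname(rep_rows$rti_symptoms))
})

test_that("person-week CSV round-trips bit-identically", {
  p <- default_calibration(n_weeks = 8, reporters_per_cluster = 4)
  pw <- simulate_trial(design_21, p, seed = 15)
  path <- withr::local_tempfile(fileext = ".csv")
  write_person_weeks(pw, path)
  back <- read_person_weeks(path)
  expect_equal(as.data.frame(back), as.data.frame(pw))
})
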