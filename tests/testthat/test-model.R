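# hand-built analysis rows covering all arms, months and exposure cells
grid_rows <- function(n_per_cell = 4, months = 1:12, seed = 1) {
  set.seed(seed)
  rows <- expand.grid(arm = trial_arms(), month = months,
                      exp_same = c(FALSE, TRUE), rep = seq_len(n_per_cell),
                      stringsAsFactors = FALSE)
  rows$person_id <- sprintf("P%03d", seq_len(nrow(rows)) %% 60 + 1)
  rows$cluster_id <- paste0("C", match(rows$arm, trial_arms()))
  rows$week_index <- seq_len(nrow(rows))
  rows$y <- rbinom(nrow(rows), 1, 0.1)
  rows$exp_lag <- sample(c(TRUE, FALSE, NA), nrow(rows), replace = TRUE)
  rows$site <- "none"
  rows$outcome <- "RTI"
  rows
}

test_that("the design matrix has the reference-coded column structure", {
  rows <- grid_rows()
  d <- build_design(rows, "same_week", interaction = TRUE)
  expect_equal(ncol(d$X), 1 + 2 + 1 + 2 + 11)
  expect_true(all(c("arm_soap_water", "arm_alcohol_rub", "exposed",
                    "exposed_x_arm_soap_water", "month_12") %in% colnames(d$X)))
  # column sums equal brute-force level counts
  expect_equal(unname(colSums(d$X)[c("arm_soap_water", "exposed", "month_7")]),
               c(sum(rows$arm == "soap_water"), sum(rows$exp_same),
                 sum(rows$month == 7)))
  expect_equal(sum(d$X[, "exposed_x_arm_alcohol_rub"]),
               sum(rows$exp_same & rows$arm == "alcohol_rub"))
  # following-week timing drops rows with missing lag
  d2 <- build_design(rows, "following_week", interaction = FALSE)
  expect_equal(length(d2$y), sum(!is.na(rows$exp_lag)))
})

test_that("degenerate designs are refused or reduced", {
  rows <- grid_rows(months = 1)
  expect_warning(d <- build_design(rows, "same_week"), "single calendar month")
  expect_false(any(grepl("^month_", colnames(d$X))))
  rows <- grid_rows()
  expect_error(build_design(rows[rows$arm != "control", ], "same_week"),
               "unseen")
  rows$exp_same <- FALSE
  expect_error(build_design(rows, "same_week"), "constant")
})

test_that("log_posterior matches a naive term-by-term oracle", {
  rows <- grid_rows(n_per_cell = 1, months = 1:3, seed = 2)[1:18, ]
  rows$person_id <- rep(sprintf("P%d", 1:6), 3)
  d <- build_design(rows, "same_week", interaction = TRUE)
  priors <- prior_spec()
  p <- ncol(d$X)
  np <- length(d$person_ids); nc <- length(d$cluster_ids)
  set.seed(3)
  for (rep in 1:5) {
    theta <- list(beta = c(log(0.1), rnorm(p - 1, 0, 0.2)),
                  u = rnorm(np, 0, 0.3), v = rnorm(nc, 0, 0.2),
                  sigma_person = runif(1, 0.1, 1),
                  sigma_cluster = runif(1, 0.1, 1))
    want <- naive_log_posterior(theta, d, priors)
    if (!is.finite(want)) next
    expect_equal(log_posterior(theta, d, priors), want, tolerance = 1e-10)
  }
  # likelihood differences isolate the Bernoulli terms
  theta <- list(beta = c(log(0.5), rep(0, p - 1)), u = rep(0, np),
                v = rep(0, nc), sigma_person = 0.5, sigma_cluster = 0.5)
  theta2 <- theta; theta2$beta[1] <- log(0.25)
  d_ll <- sum(d$y * log(2) + (1 - d$y) * (log(0.5) - log(0.75)))
  d_prior <- (log(0.25)^2 - log(0.5)^2) / (2 * priors$fixed_effect_sd^2)
  expect_equal(log_posterior(theta, d, priors) -
                 log_posterior(theta2, d, priors),
               d_ll + d_prior, tolerance = 1e-10)
  # outside the log-link support the density is zero
  theta$beta[1] <- 0.1
  expect_identical(log_posterior(theta, d, priors), -Inf)
  theta$beta[1] <- NaN
  expect_error(log_posterior(theta, d, priors), "non-finite")
})

test_that("identical seed and configuration give identical draws", {
  tr <- small_trial(n_triplets = 2, n_weeks = 10, per_cluster = 10, seed = 41)
  rows <- build_analysis_rows(tr$pw, "rti")
  f1 <- quiet_fit(rows, iter = 400, chains = 2, seed = 7, check = "none")
  f2 <- quiet_fit(rows, iter = 400, chains = 2, seed = 7, check = "none")
  expect_identical(f1$draws, f2$draws)
  f3 <- quiet_fit(rows, iter = 400, chains = 2, seed = 8, check = "none")
  expect_false(identical(f1$draws, f3$draws))
})

test_that("intercept-only sampling agrees with the analytic proportion posterior", {
  # single person/cluster with a near-degenerate RE prior: the posterior of
  # exp(beta0) under a flat log-scale prior is Beta(k, n - k + 1)
  set.seed(9)
  n <- 600L
  y <- as.numeric(runif(n) < 0.15)
  k <- sum(y)
  res <- handrct:::.mwg_sampler(
    y, matrix(1, n, 1), rep(0L, n), rep(0L, n),
    10, 1e-4, 1e-4, 6000L, 3000L, 1L, c(log(mean(y))), 1e-5, 1e-5)
  p_draws <- exp(res$beta[, 1])
  target_mean <- k / (n + 1)
  mc_se <- sd(p_draws) / sqrt(unname(coda::effectiveSize(p_draws)))
  expect_lt(abs(mean(p_draws) - target_mean), 4 * mc_se + 1e-4)
  expect_equal(sd(p_draws),
               sqrt(target_mean * (1 - target_mean) / (n + 2)),
               tolerance = 0.15)
})

test_that("credibly null interactions collapse; strong interactions do not", {
  tr <- small_trial(n_triplets = 3, n_weeks = 20, per_cluster = 25, seed = 43,
                    beta_arm = list(rti = c(soap_water = 0, alcohol_rub = 0),
                                    gti = c(soap_water = 0, alcohol_rub = 0)),
                    beta_interact = list(rti = c(soap_water = 0, alcohol_rub = 0),
                                         gti = c(soap_water = 0, alcohol_rub = 0)))
  rows <- build_analysis_rows(tr$pw, "rti")
  fit0 <- quiet_fit(rows, iter = 1500, chains = 2, seed = 11, check = "none")
  spec0 <- collapse_interaction(fit0)
  expect_true(attr(spec0, "collapsed"))
  expect_false(spec0$interaction)

  tr2 <- small_trial(n_triplets = 5, n_weeks = 30, per_cluster = 25, seed = 44,
                     beta_interact = list(
                       rti = c(soap_water = -0.5, alcohol_rub = -0.5),
                       gti = c(soap_water = 0, alcohol_rub = 0)))
  rows2 <- build_analysis_rows(tr2$pw, "rti")
  fit1 <- quiet_fit(rows2, iter = 1500, chains = 2, seed = 12, check = "none")
  spec1 <- collapse_interaction(fit1)
  expect_false(attr(spec1, "collapsed"))
  expect_true(spec1$interaction)

  fit_no <- quiet_fit(rows, interaction = FALSE, iter = 400, chains = 2,
                      seed = 13, check = "none")
  expect_error(collapse_interaction(fit_no), "no interaction")
})

test_that("triplet adjustment and prior scale barely move the arm contrasts", {
  tr <- small_trial(n_triplets = 3, n_weeks = 20, per_cluster = 25, seed = 45)
  rows <- build_analysis_rows(tr$pw, "rti")
  triplet_of <- setNames(tr$design$triplet, tr$design$cluster_id)
  f_plain <- quiet_fit(rows, iter = 1500, chains = 2, seed = 21, check = "none")
  f_trip <- quiet_fit(rows, triplet = TRUE, triplet_of = triplet_of,
                      iter = 1500, chains = 2, seed = 21, check = "none")
  for (par in c("arm_soap_water", "arm_alcohol_rub")) {
    sd_ref <- sd(f_plain$draws[, par])
    expect_lt(abs(median(f_plain$draws[, par]) - median(f_trip$draws[, par])),
              0.5 * sd_ref)
  }
  f_wide <- quiet_fit(rows, priors = prior_spec(fixed_effect_sd = 20),
                      iter = 1500, chains = 2, seed = 21, check = "none")
  for (par in c("arm_soap_water", "exposed")) {
    sd_ref <- sd(f_plain$draws[, par])
    expect_lt(abs(median(f_plain$draws[, par]) - median(f_wide$draws[, par])),
              0.5 * sd_ref)
  }
})

test_that("summary, coef and draw export expose the posterior", {
  tr <- small_trial(n_triplets = 2, n_weeks = 10, per_cluster = 10, seed = 46)
  rows <- build_analysis_rows(tr$pw, "rti")
  fit <- quiet_fit(rows, iter = 600, chains = 2, seed = 31, check = "none")
  s <- summary(fit)
  expect_true(all(c("(Intercept)", "sigma_person", "sigma_cluster") %in%
                    s$parameter))
  expect_true(all(s$q2.5 <= s$median & s$median <= s$q97.5))
  expect_equal(unname(coef(fit)["(Intercept)"]),
               unname(median(fit$draws[, "(Intercept)"])))
  expect_equal(dim(as.matrix(fit))[1], nrow(fit$draws))
  expect_output(print(fit), "log-binomial")
  # all retained draws satisfy the support constraint at observed patterns
  X <- fit$design$X
  p_cols <- seq_len(ncol(X))
  ok <- vapply(seq_len(nrow(fit$draws)), function(i) {
    eta <- X %*% fit$draws[i, p_cols] +
      fit$u[i, fit$design$person + 1L] + fit$v[i, fit$design$cluster + 1L]
    all(eta < 0)
  }, logical(1))
  expect_true(all(ok))
})

test_that("posterior medians agree with an independent likelihood fitter", {
  tr <- small_trial(n_triplets = 3, n_weeks = 25, per_cluster = 25, seed = 47,
                    beta_exp_lag = c(rti = 0, gti = 0))
  rows <- build_analysis_rows(tr$pw, "rti")
  fit <- quiet_fit(rows, iter = 2000, chains = 2, seed = 48, check = "none")
  s <- summary(fit)
  rows$arm <- factor(rows$arm, levels = trial_arms())
  rows$month <- factor(rows$month)
  g <- glmmTMB::glmmTMB(
    y ~ arm * exp_same + month + (1 | person_id) + (1 | cluster_id),
    data = rows, family = stats::binomial(link = "log"),
    start = list(beta = c(log(mean(rows$y)),
                          rep(0, length(unique(rows$month)) + 4))))
  co <- summary(g)$coefficients$cond
  pairs <- rbind(c("exposed", "exp_sameTRUE"),
                 c("arm_soap_water", "armsoap_water"),
                 c("arm_alcohol_rub", "armalcohol_rub"))
  for (i in seq_len(nrow(pairs))) {
    med <- s$median[s$parameter == pairs[i, 1]]
    sdv <- s$sd[s$parameter == pairs[i, 1]]
    expect_lt(abs(med - co[pairs[i, 2], 1]),
              2 * sqrt(sdv^2 + co[pairs[i, 2], 2]^2))
  }
})
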