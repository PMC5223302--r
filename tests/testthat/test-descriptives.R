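test_that("published counts reproduce the printed proportions exactly", {
  rti <- arm_summary(reference_rows("rti", "same_week"))
  gti <- arm_summary(reference_rows("gti", "same_week"))
  get <- function(df, arm, col) df[[col]][df$arm == arm]
  expect_identical(get(rti, "control", "n_weeks"), 11644L)
  expect_equal(round(get(rti, "control", "prevalence"), 3), 0.126)
  expect_equal(round(get(gti, "soap_water", "prevalence"), 3), 0.019)
  expect_equal(round(get(rti, "control", "exposure_proportion"), 3), 0.282)
  expect_equal(round(100 * get(gti, "soap_water", "site_only_elsewhere") /
                       get(gti, "soap_water", "n_exposure_weeks"), 1), 52.6)
  # exact integer-ratio arithmetic: proportions recompute bit-identically
  expect_identical(rti$prevalence,
                   rti$n_symptom_weeks / rti$n_weeks)
})

test_that("exposure-stratified proportions and ReR match the printed tables", {
  rer_rti <- rer_summary(reference_rows("rti", "same_week"), "same_week")
  ctrl <- rer_rti[rer_rti$arm == "control", ]
  expect_equal(round(ctrl$exposed_prop, 3), 0.298)
  expect_equal(ctrl$rer, (976 / 3279) / (494 / 8365))
  expect_gt(ctrl$rer, 4)
  rer_gti <- rer_summary(reference_rows("gti", "same_week"), "same_week")
  gctl <- rer_gti[rer_gti$arm == "control", ]
  expect_equal(round(gctl$exposed_prop, 3), 0.207)
  expect_equal(round(gctl$unexposed_prop, 3), 0.014)
})

test_that("ReR equals a brute-force 2x2 contingency computation", {
  tr <- small_trial(seed = 31)
  rows <- build_analysis_rows(tr$pw, "rti")
  for (tm in c("same_week", "following_week")) {
    got <- rer_summary(rows, tm)
    use <- if (tm == "following_week") rows[!is.na(rows$exp_lag), ] else rows
    expo <- if (tm == "following_week") use$exp_lag else use$exp_same
    for (a in trial_arms()) {
      tab <- table(factor(expo[use$arm == a], c(FALSE, TRUE)),
                   factor(use$y[use$arm == a], 0:1))
      want <- (tab["TRUE", "1"] / sum(tab["TRUE", ])) /
        (tab["FALSE", "1"] / sum(tab["FALSE", ]))
      expect_equal(got$rer[got$arm == a], want)
      expect_equal(got$exposed_n[got$arm == a] + got$unexposed_n[got$arm == a],
                   nrow(use[use$arm == a, ]))
    }
  }
})

test_that("with no exposure effect the ReR converges to one", {
  tr <- small_trial(n_triplets = 7, n_weeks = 40, per_cluster = 30, seed = 33,
                    beta_exp_same = c(rti = 0, gti = 0),
                    beta_exp_lag = c(rti = 0, gti = 0),
                    sigma_person = 0, sigma_cluster = 0)
  rows <- build_analysis_rows(tr$pw, "rti")
  s <- rer_summary(rows, "same_week")
  ctrl <- s[s$arm == "control", ]
  se <- sqrt((1 - ctrl$exposed_prop) / ctrl$exposed_k +
               (1 - ctrl$unexposed_prop) / ctrl$unexposed_k)
  expect_lt(abs(log(ctrl$rer)), 3 * se)
})

test_that("descriptive RRa divides by the control ReR and flags degeneracies", {
  tab <- data.frame(arm = trial_arms(), outcome = "RTI", timing = "same_week",
                    exposed_n = 100, exposed_k = c(40, 20, 10),
                    exposed_prop = c(0.4, 0.2, 0.1),
                    unexposed_n = 100, unexposed_k = 10, unexposed_prop = 0.1,
                    rer = c(4, 2, 1), flag = "", stringsAsFactors = FALSE)
  out <- rra_descriptive(tab)
  expect_equal(out$rra[out$arm == "soap_water"], 0.5)
  expect_true(is.na(out$rra[out$arm == "control"]))
  expect_equal(out$rra_flag[out$arm == "control"], "not relevant")
  # undefined control ReR poisons every RRa
  tab$rer[tab$arm == "control"] <- NA
  out <- rra_descriptive(tab)
  expect_true(all(is.na(out$rra)))
  expect_match(out$rra_flag[out$arm == "soap_water"], "undefined")
})

test_that("an empty or symptom-free unexposed stratum flags the ReR", {
  rows <- data.frame(
    person_id = sprintf("P%02d", 1:20), cluster_id = "C01",
    arm = rep(trial_arms(), length.out = 20), week_index = 1L, month = 1L,
    y = rep(c(1L, 0L), 10), exp_same = rep(c(TRUE, FALSE), 10),
    exp_lag = NA, site = "none", outcome = "RTI", stringsAsFactors = FALSE)
  rows$y[!rows$exp_same] <- 0L  # unexposed weeks exist but are symptom-free
  s <- rer_summary(rows, "same_week")
  expect_true(all(is.na(s$rer)))
  expect_match(s$flag[1], "undefined")
})

test_that("arm summaries carry Jeffreys intervals that bracket the estimate", {
  rows <- reference_rows("rti", "same_week")
  a <- arm_summary(rows)
  expect_true(all(a$prev_lower < a$prevalence & a$prevalence < a$prev_upper))
  ci <- jeffreys_interval(3279, 11644)
  expect_equal(unname(a[a$arm == "control", c("exp_lower", "exp_upper")]),
               unname(as.data.frame(ci)), tolerance = 1e-12)
})
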