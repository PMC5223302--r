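# shared helpers: small cohorts, independent oracles

quiet_fit <- function(...) suppressWarnings(fit_prevalence(...))

# simulate a reduced trial; params overrides go through default_calibration
small_trial <- function(n_triplets = 3, n_weeks = 20, per_cluster = 20,
                        seed = 1, ...) {
  design <- randomize_arms(
    assign_triplets(make_clusters(3L * n_triplets, seed = seed)),
    seed = seed + 1L)
  params <- default_calibration(n_weeks = n_weeks,
                                reporters_per_cluster = per_cluster,
                                include_days = FALSE, ...)
  pw <- simulate_trial(design, params, seed = seed + 2L)
  list(design = design, params = params, pw = pw)
}

# a calibrated parameter set with every arm effect switched off
null_arm_params <- function(...) {
  default_calibration(
    beta_arm = list(rti = c(soap_water = 0, alcohol_rub = 0),
                    gti = c(soap_water = 0, alcohol_rub = 0)),
    beta_interact = list(rti = c(soap_water = 0, alcohol_rub = 0),
                         gti = c(soap_water = 0, alcohol_rub = 0)),
    ...)
}

# term-by-term reimplementation of the log posterior, written to be
# obviously correct rather than fast
naive_log_posterior <- function(theta, design, priors) {
  n <- length(design$y)
  out <- 0
  for (i in seq_len(n)) {
    eta <- 0
    for (k in seq_len(ncol(design$X))) eta <- eta + design$X[i, k] * theta$beta[k]
    eta <- eta + theta$u[design$person[i] + 1] + theta$v[design$cluster[i] + 1]
    p <- exp(eta)
    if (p >= 1) return(-Inf)
    out <- out + if (design$y[i] == 1) log(p) else log(1 - p)
  }
  for (b in theta$beta)
    out <- out - b^2 / (2 * priors$fixed_effect_sd^2) -
      log(priors$fixed_effect_sd) - 0.5 * log(2 * pi)
  for (s in c(theta$sigma_person, theta$sigma_cluster))
    out <- out + log(sqrt(2 / pi) / priors$re_scale) -
      s^2 / (2 * priors$re_scale^2)
  for (x in theta$u)
    out <- out - x^2 / (2 * theta$sigma_person^2) -
      log(theta$sigma_person) - 0.5 * log(2 * pi)
  for (x in theta$v)
    out <- out - x^2 / (2 * theta$sigma_cluster^2) -
      log(theta$sigma_cluster) - 0.5 * log(2 * pi)
  as.numeric(out)
}

# brute-force day-by-day run-length scanner over the full calendar
brute_episodes <- function(pw) {
  res <- list()
  for (o in c("rti", "gti")) {
    day_cols <- paste0(o, "_d", 1:7)
    for (pid in unique(pw$person_id)) {
      rows <- pw[pw$person_id == pid, , drop = FALSE]
      max_day <- max(rows$week_index) * 7L
      status <- rep(0L, max_day)  # 1 = symptomatic observed day
      for (r in seq_len(nrow(rows))) {
        if (!isTRUE(rows$reported[r])) next
        days <- as.integer(rows[r, day_cols])
        idx <- (rows$week_index[r] - 1L) * 7L + 1:7
        status[idx] <- ifelse(days == 1L, 1L, 0L)
      }
      run_len <- 0L
      for (d in seq_len(max_day + 1L)) {
        on <- d <= max_day && status[d] == 1L
        if (on) {
          run_len <- run_len + 1L
        } else if (run_len > 0L) {
          res[[length(res) + 1L]] <- data.frame(
            person_id = pid, outcome = toupper(o),
            start_day = d - run_len, length_days = run_len,
            stringsAsFactors = FALSE)
          run_len <- 0L
        }
      }
    }
  }
  if (!length(res))
    return(data.frame(person_id = character(), outcome = character(),
                      start_day = integer(), length_days = integer()))
  out <- do.call(rbind, res)
  out[order(out$outcome, out$person_id, out$start_day), ]
}

# hand-build person-week rows with day vectors for endpoint tests
pw_from_days <- function(person_id, week_index, rti_days, reported = TRUE) {
  n <- length(week_index)
  pw <- data.frame(person_id = person_id, cluster_id = "C01", arm = "control",
                   week_index = week_index,
                   month = rep(1L, n), reported = reported,
                   stringsAsFactors = FALSE)
  dm <- do.call(rbind, rti_days)
  colnames(dm) <- paste0("rti_d", 1:7)
  zm <- matrix(0L, n, 7L, dimnames = list(NULL, paste0("gti_d", 1:7)))
  dm[!pw$reported, ] <- NA_integer_
  zm[!pw$reported, ] <- NA_integer_
  pw <- cbind(pw, dm, zm)
  pw$rti_exposure <- pw$reported & FALSE
  pw$gti_exposure <- pw$reported & FALSE
  pw$rti_site <- ifelse(pw$reported, "none", NA)
  pw$gti_site <- ifelse(pw$reported, "none", NA)
  pw
}

# minimal hand-built logbinfit-like object for margin tests
fake_fit <- function(rows, draws) {
  design <- build_design(rows, "same_week", interaction = TRUE)
  structure(list(draws = draws, design = design,
                 spec = list(outcome = "RTI", timing = "same_week",
                             interaction = TRUE, triplet = FALSE)),
            class = "logbinfit")
}
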