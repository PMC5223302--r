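#' Simulation parameters for a synthetic trial cohort
#'
#' Collects every generative coefficient of the weekly log-risk model plus
#' the adherence model. Coefficients live on the log-risk scale, so
#' `exp(beta)` is a risk ratio. The weekly symptom risk for outcome
#' `o` of person `i` in cluster `j`, week `t`, is
#' `p = exp(beta0 + beta_arm + beta_exp_same * E_t + beta_exp_lag * E_{t-1}
#' + beta_interact * (arm x E_t) + beta_month[month(t)] + u_i + v_j)`
#' with `u_i ~ N(0, sigma_person^2)` and `v_j ~ N(0, sigma_cluster^2)`
#' shared between the two outcomes. The defaults are calibrated so that a
#' simulated trial at full size reproduces the weekly prevalences
#' (RTI ~ 0.11-0.13, GTI ~ 0.02-0.03), exposure-week proportions
#' (RTI ~ 0.27-0.29, GTI ~ 0.06-0.07), same-week exposure effects
#' (~5x RTI, ~15x GTI) and arm/interaction structure of a 21-cluster
#' office trial. Arm and interaction defaults are derived from the raw
#' exposure-stratum symptom proportions (the generator targets observed
#' proportions, not model-standardized margins).
#'
#' Because the log link requires `exp(eta) < 1`, the constructor validates
#' the parameter set by maximizing `eta` over every admissible covariate
#' pattern with both random effects at +4 SD, and refuses parameter sets
#' that can produce risks at or above one. This constraint is what bounds
#' the admissible random-intercept SDs given the large exposure effects.
#'
#' @param beta0 Named numeric, log baseline weekly risk per outcome
#'   (`rti`, `gti`) in the reference month for an unexposed control person.
#' @param beta_arm List per outcome of named numeric
#'   (`soap_water`, `alcohol_rub`): log risk ratio of each intervention arm
#'   vs control in unexposed weeks.
#' @param beta_exp_same,beta_exp_lag Named numeric per outcome: log risk
#'   ratio of a reported homologous exposure in the same / previous week.
#' @param beta_interact List per outcome of named numeric: arm x same-week
#'   exposure interaction on the log scale.
#' @param beta_month Matrix `12 x 2` (columns `rti`, `gti`) of calendar
#'   month effects; the reference month (January) must be 0.
#' @param sigma_person,sigma_cluster SDs of the normal person / cluster
#'   random intercepts on the log scale.
#' @param exposure_rate List per outcome of named numeric per arm: weekly
#'   probability of a reported homologous exposure.
#' @param site_probs List per outcome of length-3 numeric
#'   (`work`, `elsewhere`, `both`) summing to 1: conditional distribution
#'   of the reported site given an exposure.
#' @param n_weeks Follow-up length in weeks.
#' @param reporters_per_cluster Number of reporters recruited per cluster.
#' @param report_prob Per-person weekly probability of sending the report.
#' @param dropout_hazard Weekly hazard of permanently ceasing to report
#'   (geometric dropout time; default mean 250 weeks, i.e. well beyond
#'   follow-up).
#' @param include_days If `TRUE`, draw per-day symptom vectors consistent
#'   with the weekly flags.
#' @param start_date A Monday anchoring week 1; months are taken from each
#'   week's Monday.
#' @param seed Default seed used by [simulate_trial()] when none is given.
#' @return An object of class `sim_params` (a validated list).
#' @seealso [default_calibration()], [simulate_trial()]
#' @export
sim_params <- function(
    beta0 = c(rti = -2.842, gti = -4.205),
    beta_arm = list(
      rti = c(soap_water = -0.270, alcohol_rub = 0.007),
      gti = c(soap_water = -0.483, alcohol_rub = -0.189)
    ),
    beta_exp_same = c(rti = log(5.05), gti = log(14.8)),
    beta_exp_lag  = c(rti = log(1.8),  gti = log(2.0)),
    beta_interact = list(
      rti = c(soap_water = 0.229, alcohol_rub = -0.010),
      gti = c(soap_water = 0.286, alcohol_rub = 0.034)
    ),
    beta_month = seasonal_months(amplitude = c(rti = 0.25, gti = 0.15)),
    sigma_person = 0.08,
    sigma_cluster = 0.03,
    exposure_rate = list(
      rti = c(control = 0.282, soap_water = 0.268, alcohol_rub = 0.293),
      gti = c(control = 0.066, soap_water = 0.062, alcohol_rub = 0.067)
    ),
    site_probs = list(
      rti = c(work = 0.32, elsewhere = 0.45, both = 0.23),
      gti = c(work = 0.33, elsewhere = 0.56, both = 0.11)
    ),
    n_weeks = 70L,
    reporters_per_cluster = 38L,
    report_prob = 0.85,
    dropout_hazard = 0.004,
    include_days = TRUE,
    start_date = as.Date("2009-01-05"),
    seed = NULL) {
  p <- structure(
    list(beta0 = beta0, beta_arm = beta_arm, beta_exp_same = beta_exp_same,
         beta_exp_lag = beta_exp_lag, beta_interact = beta_interact,
         beta_month = beta_month, sigma_person = sigma_person,
         sigma_cluster = sigma_cluster, exposure_rate = exposure_rate,
         site_probs = site_probs, n_weeks = as.integer(n_weeks),
         reporters_per_cluster = as.integer(reporters_per_cluster),
         report_prob = report_prob, dropout_hazard = dropout_hazard,
         include_days = isTRUE(include_days),
         start_date = as.Date(start_date), seed = seed),
    class = "sim_params")
  validate_sim_params(p)
  p
}

#' Cosine-shaped calendar-month effects with a winter peak
#'
#' Month effects on the log-risk scale, `amplitude * (cos(2*pi*(m-1)/12) - 1)`,
#' so January is the (zero) reference and July the trough.
#'
#' @param amplitude Named numeric per outcome (`rti`, `gti`), log-scale
#'   peak-to-reference amplitude.
#' @return A `12 x 2` matrix with columns `rti`, `gti`.
#' @export
seasonal_months <- function(amplitude = c(rti = 0.25, gti = 0.15)) {
  m <- 1:12
  shape <- cos(2 * pi * (m - 1) / 12) - 1
  out <- cbind(rti = amplitude[["rti"]] * shape,
               gti = amplitude[["gti"]] * shape)
  rownames(out) <- month.abb
  out
}

outcomes <- function() c("rti", "gti")

# largest achievable linear predictor for one outcome, REs at +k SD;
# terms are added conditionally so a -Inf baseline cannot produce 0 * Inf
max_eta <- function(p, outcome, k_sd = 4) {
  arms <- trial_arms()
  best <- -Inf
  for (arm in arms) {
    b_arm <- if (arm == "control") 0 else p$beta_arm[[outcome]][[arm]]
    b_int <- if (arm == "control") 0 else p$beta_interact[[outcome]][[arm]]
    for (e_same in c(FALSE, TRUE)) for (e_lag in c(FALSE, TRUE)) {
      eta <- p$beta0[[outcome]] + b_arm + max(p$beta_month[, outcome])
      if (e_same) eta <- eta + p$beta_exp_same[[outcome]] + b_int
      if (e_lag) eta <- eta + p$beta_exp_lag[[outcome]]
      best <- max(best, eta)
    }
  }
  best + k_sd * (p$sigma_person + p$sigma_cluster)
}

validate_sim_params <- function(p) {
  chk01 <- function(x, what) {
    if (any(x < 0 | x > 1)) stop(what, " must lie in [0, 1]", call. = FALSE)
  }
  for (o in outcomes()) {
    chk01(p$exposure_rate[[o]], paste0("exposure_rate$", o))
    if (abs(sum(p$site_probs[[o]]) - 1) > 1e-8)
      stop("site_probs$", o, " must sum to 1", call. = FALSE)
    chk01(p$site_probs[[o]], paste0("site_probs$", o))
  }
  chk01(p$report_prob, "report_prob")
  chk01(p$dropout_hazard, "dropout_hazard")
  if (p$sigma_person < 0 || p$sigma_cluster < 0)
    stop("random-intercept SDs must be non-negative", call. = FALSE)
  if (!identical(dim(p$beta_month), c(12L, 2L)) &&
      !identical(dim(p$beta_month), c(12L, 2L) * 1))
    stop("beta_month must be a 12 x 2 matrix", call. = FALSE)
  if (any(p$beta_month[1L, ] != 0))
    stop("the reference month (row 1) of beta_month must be 0", call. = FALSE)
  for (o in outcomes()) {
    me <- max_eta(p, o)
    if (is.finite(me) && me >= 0)
      stop(sprintf(paste0(
        "log-link support violated for outcome '%s': the maximal linear ",
        "predictor over covariate patterns with random effects at +4 SD ",
        "is %.3f >= 0 (weekly risk exp(eta) would reach or exceed 1); ",
        "reduce effect sizes or random-intercept SDs"), o, me),
        call. = FALSE)
  }
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic cohort parameters (log-risk scale)\n")
  cat(sprintf("  baseline weekly risk: RTI %.4f, GTI %.4f\n",
              exp(x$beta0[["rti"]]), exp(x$beta0[["gti"]])))
  cat(sprintf("  same-week exposure RR: RTI %.2f, GTI %.2f\n",
              exp(x$beta_exp_same[["rti"]]), exp(x$beta_exp_same[["gti"]])))
  cat(sprintf("  random intercept SDs: person %.3f, cluster %.3f\n",
              x$sigma_person, x$sigma_cluster))
  cat(sprintf("  %d weeks, %d reporters/cluster, report prob %.2f\n",
              x$n_weeks, x$reporters_per_cluster, x$report_prob))
  invisible(x)
}

#' Calibrated default simulation parameters
#'
#' Returns the package's calibrated parameter set: at the full trial size
#' (21 clusters, 70 weeks, ~266 reporters per arm) the simulated arm-level
#' weekly prevalences and exposure-week proportions fall within 20% of the
#' reference trial's descriptive tables.
#'
#' @param ... Overrides passed to [sim_params()].
#' @return A `sim_params` object.
#' @export
default_calibration <- function(...) sim_params(...)

# month (1-12) of the Monday of each week index
week_months <- function(start_date, n_weeks) {
  as.POSIXlt(start_date + 7 * (seq_len(n_weeks) - 1L))$mon + 1L
}

site_levels <- function() c("none", "work", "elsewhere", "both")

#' Simulate a longitudinal weekly self-report dataset
#'
#' Generates one person-week record per person and follow-up week up to the
#' person's (geometric) dropout time. Each retained week is reported with
#' probability `report_prob`; unreported weeks keep their row but carry no
#' symptom or exposure values. For reported weeks, homologous exposures are
#' drawn per outcome at the arm's exposure rate, a site is drawn for
#' exposed weeks, and symptoms are Bernoulli with the log-linear weekly
#' risk described in [sim_params()]. Exposure is generated causally prior
#' to same-week symptoms. The lagged exposure used in generation is the
#' previous week's reported exposure, false for week 1 or when the previous
#' week was unreported. RTI and GTI share the person and cluster random
#' intercepts but are otherwise independent draws.
#'
#' @param design A fully randomized `trial_design`.
#' @param params A `sim_params` object.
#' @param seed Integer seed; defaults to `params$seed`. One root seed
#'   governs all randomness, so identical inputs reproduce the dataset
#'   exactly.
#' @return A data frame of person-week records (class `person_weeks`):
#'   `person_id`, `cluster_id`, `arm`, `week_index`, `month`, `reported`,
#'   `rti_symptoms`, `gti_symptoms`, `rti_exposure`, `gti_exposure`,
#'   `rti_site`, `gti_site`, and if `params$include_days` the day columns
#'   `rti_d1..rti_d7`, `gti_d1..gti_d7`.
#' @export
simulate_trial <- function(design, params, seed = params$seed) {
  if (!inherits(params, "sim_params")) stop("params must be a sim_params object")
  if (any(is.na(design$arm))) stop("design arms must be randomized first")
  if (!is.null(seed)) set.seed(seed)

  n_cl <- nrow(design)
  npc <- params$reporters_per_cluster
  n_person <- n_cl * npc
  person_cl <- rep(seq_len(n_cl), each = npc)
  person_id <- sprintf("P%04d", seq_len(n_person))

  u <- stats::rnorm(n_person, 0, params$sigma_person)
  v <- stats::rnorm(n_cl, 0, params$sigma_cluster)

  # geometric dropout: number of weeks actually followed
  last_week <- if (params$dropout_hazard > 0) {
    pmin(params$n_weeks, stats::rgeom(n_person, params$dropout_hazard) + 1L)
  } else rep(params$n_weeks, n_person)

  months <- week_months(params$start_date, params$n_weeks)

  pid <- rep(seq_len(n_person), last_week)
  wk <- sequence(last_week)
  n_rows <- length(pid)
  cl_idx <- person_cl[pid]
  arm <- design$arm[cl_idx]
  reported <- stats::rbinom(n_rows, 1L, params$report_prob) == 1L

  pw <- data.frame(
    person_id = person_id[pid],
    cluster_id = design$cluster_id[cl_idx],
    arm = arm,
    week_index = wk,
    month = months[wk],
    reported = reported,
    stringsAsFactors = FALSE
  )

  # row index of the same person's previous week (rows are person-ordered)
  prev_same_person <- c(FALSE, pid[-1L] == pid[-n_rows])

  for (o in outcomes()) {
    exp_rate <- params$exposure_rate[[o]][arm]
    exposed <- reported & (stats::runif(n_rows) < exp_rate)
    exp_lag <- logical(n_rows)
    exp_lag[which(prev_same_person)] <- exposed[which(prev_same_person) - 1L]

    b_arm <- ifelse(arm == "control", 0, unname(params$beta_arm[[o]][arm]))
    b_int <- ifelse(arm == "control", 0, unname(params$beta_interact[[o]][arm]))
    eta <- params$beta0[[o]] + b_arm +
      ifelse(exposed, params$beta_exp_same[[o]] + b_int, 0) +
      ifelse(exp_lag, params$beta_exp_lag[[o]], 0) +
      params$beta_month[pw$month, o] + u[pid] + v[cl_idx]
    p <- exp(eta)
    bad <- which(reported & p >= 1)
    if (length(bad)) {
      b <- bad[1L]
      stop(sprintf(paste0(
        "generated weekly risk >= 1 (p = %.3f) for outcome '%s', pattern: ",
        "arm=%s, exposed=%s, lagged=%s, month=%d, person RE=%.2f, ",
        "cluster RE=%.2f"), p[b], o, arm[b], exposed[b], exp_lag[b],
        pw$month[b], u[pid[b]], v[cl_idx[b]]), call. = FALSE)
    }
    symp <- reported & (stats::runif(n_rows) < p)

    site <- rep(NA_character_, n_rows)
    site[reported] <- "none"
    ei <- which(exposed)
    if (length(ei))
      site[ei] <- sample(c("work", "elsewhere", "both"), length(ei),
                         replace = TRUE, prob = params$site_probs[[o]])

    pw[[paste0(o, "_symptoms")]] <- ifelse(reported, symp, NA)
    pw[[paste0(o, "_exposure")]] <- ifelse(reported, exposed, NA)
    pw[[paste0(o, "_site")]] <- site

    if (params$include_days) {
      days <- matrix(NA_integer_, n_rows, 7L)
      days[reported, ] <- 0L
      si <- which(symp)
      if (length(si)) {
        len <- pmin(7L, 1L + stats::rpois(length(si), 1.5))
        start <- 1L + floor(stats::runif(length(si)) * (8L - len))
        for (k in seq_along(si)) {
          days[si[k], start[k]:(start[k] + len[k] - 1L)] <- 1L
        }
      }
      colnames(days) <- paste0(o, "_d", 1:7)
      pw <- cbind(pw, as.data.frame(days))
    }
  }
  class(pw) <- c("person_weeks", "data.frame")
  pw
}

#' Write / read person-week records as CSV
#'
#' The on-disk dialect is comma-delimited UTF-8 with a header row, booleans
#' as 0/1 and missing values as empty fields.
#'
#' @param pw A person-week data frame.
#' @param path File path.
#' @return `write_person_weeks` returns `path` invisibly;
#'   `read_person_weeks` returns a `person_weeks` data frame.
#' @export
write_person_weeks <- function(pw, path) {
  out <- as.data.frame(pw)
  for (nm in names(out)) {
    if (is.logical(out[[nm]])) out[[nm]] <- as.integer(out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_person_weeks
#' @export
read_person_weeks <- function(path) {
  pw <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = "")
  for (nm in c("reported", "rti_symptoms", "gti_symptoms",
               "rti_exposure", "gti_exposure")) {
    if (nm %in% names(pw)) pw[[nm]] <- pw[[nm]] == 1L
  }
  class(pw) <- c("person_weeks", "data.frame")
  pw
}
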