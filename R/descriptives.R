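#' Jeffreys 95% interval for a binomial proportion
#'
#' Central Beta(x + 1/2, n - x + 1/2) interval, the standard objective
#' Bayesian interval for a raw proportion.
#'
#' @param x Number of events.
#' @param n Number of trials.
#' @param level Coverage level.
#' @return A two-column matrix `lower`, `upper`.
#' @export
jeffreys_interval <- function(x, n, level = 0.95) {
  a <- (1 - level) / 2
  cbind(lower = stats::qbeta(a, x + 0.5, n - x + 0.5),
        upper = stats::qbeta(1 - a, x + 0.5, n - x + 0.5))
}

#' Arm-level descriptive summaries of symptom and exposure weeks
#'
#' For each trial arm: the count and proportion of reported person-weeks
#' with symptoms of the target outcome (weekly prevalence), the count and
#' proportion of weeks with a reported homologous exposure, and the site
#' breakdown of the exposure weeks. Proportions are exact integer ratios;
#' display rounding is left to the caller (`round()` is half-even).
#'
#' @param rows Analysis rows from [build_analysis_rows()].
#' @return A data frame, one row per arm, with Jeffreys 95% intervals for
#'   the prevalence and exposure proportions. Arms with zero reported
#'   weeks get `NA` proportions and `flag = "no weeks"`.
#' @export
arm_summary <- function(rows) {
  stopifnot(nrow(rows) > 0)
  arms <- intersect(trial_arms(), unique(rows$arm))
  out <- do.call(rbind, lapply(arms, function(a) {
    r <- rows[rows$arm == a, , drop = FALSE]
    n <- nrow(r)
    k <- sum(r$y)
    ne <- sum(r$exp_same)
    sites <- c(only_work = sum(r$site %in% "work"),
               only_elsewhere = sum(r$site %in% "elsewhere"),
               both = sum(r$site %in% "both"))
    data.frame(
      arm = a, outcome = rows$outcome[1L],
      n_weeks = n, n_symptom_weeks = k,
      prevalence = if (n > 0) k / n else NA_real_,
      prev_lower = if (n > 0) jeffreys_interval(k, n)[, 1L] else NA_real_,
      prev_upper = if (n > 0) jeffreys_interval(k, n)[, 2L] else NA_real_,
      n_exposure_weeks = ne,
      exposure_proportion = if (n > 0) ne / n else NA_real_,
      exp_lower = if (n > 0) jeffreys_interval(ne, n)[, 1L] else NA_real_,
      exp_upper = if (n > 0) jeffreys_interval(ne, n)[, 2L] else NA_real_,
      site_only_work = sites[["only_work"]],
      site_only_elsewhere = sites[["only_elsewhere"]],
      site_both = sites[["both"]],
      flag = if (n == 0) "no weeks" else "",
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Exposure-conditioned relative risk (ReR) per arm
#'
#' The ReR is the ratio of conditional weekly symptom proportions,
#' `P(symptoms | homologous exposure at the stated timing) /
#' P(symptoms | no such exposure)`, computed within each arm. Same-week
#' timing conditions on the same week's exposure; following-week timing
#' conditions on the previous week's exposure (`exp_lag`) and drops rows
#' whose lag is missing. An empty or symptom-free unexposed stratum makes
#' the ReR undefined (flagged, not an error).
#'
#' @param rows Analysis rows.
#' @param timing `"same_week"` or `"following_week"`.
#' @return A data frame per arm with stratum counts/proportions, `rer` and
#'   a `flag` column.
#' @export
rer_summary <- function(rows, timing = c("same_week", "following_week")) {
  timing <- match.arg(timing)
  if (timing == "following_week") {
    rows <- rows[!is.na(rows$exp_lag), , drop = FALSE]
    expo <- rows$exp_lag
  } else {
    expo <- rows$exp_same
  }
  arms <- intersect(trial_arms(), unique(rows$arm))
  out <- do.call(rbind, lapply(arms, function(a) {
    in_arm <- rows$arm == a
    n1 <- sum(in_arm & expo); k1 <- sum(rows$y[in_arm & expo])
    n0 <- sum(in_arm & !expo); k0 <- sum(rows$y[in_arm & !expo])
    p1 <- if (n1 > 0) k1 / n1 else NA_real_
    p0 <- if (n0 > 0) k0 / n0 else NA_real_
    flag <- ""
    rer <- if (!is.na(p1) && !is.na(p0) && p0 > 0) p1 / p0 else {
      flag <- "undefined ReR (empty or symptom-free unexposed stratum)"
      NA_real_
    }
    data.frame(arm = a, outcome = rows$outcome[1L], timing = timing,
               exposed_n = n1, exposed_k = k1, exposed_prop = p1,
               unexposed_n = n0, unexposed_k = k0, unexposed_prop = p0,
               rer = rer, flag = flag, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Descriptive arm risk ratio (RRa) from ReRs
#'
#' Divides each intervention arm's ReR by the control arm's ReR. The
#' control row is marked not relevant; if the control ReR is undefined,
#' every RRa is undefined.
#'
#' @param rer_tab Output of [rer_summary()].
#' @return `rer_tab` with added columns `rra` and `rra_flag`.
#' @export
rra_descriptive <- function(rer_tab) {
  ctrl <- rer_tab$rer[rer_tab$arm == "control"]
  rer_tab$rra <- NA_real_
  rer_tab$rra_flag <- ""
  if (length(ctrl) != 1L || is.na(ctrl) || ctrl <= 0) {
    rer_tab$rra_flag <- "control ReR undefined; RRa undefined"
  } else {
    iv <- rer_tab$arm != "control"
    rer_tab$rra[iv] <- rer_tab$rer[iv] / ctrl
  }
  rer_tab$rra_flag[rer_tab$arm == "control"] <- "not relevant"
  rer_tab
}

#' Write the descriptive report tables
#'
#' Emits the arm-summary and ReR/RRa tables for both outcomes and both
#' timings as CSV files plus a short plain-text report.
#'
#' @param rows_rti,rows_gti Analysis rows for each outcome.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named list of written file paths.
#' @export
write_descriptives <- function(rows_rti, rows_gti, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  summaries <- rbind(arm_summary(rows_rti), arm_summary(rows_gti))
  paths$arm_summary <- file.path(dir, "arm_summary.csv")
  utils::write.csv(summaries, paths$arm_summary, row.names = FALSE)
  rer_all <- do.call(rbind, lapply(list(rows_rti, rows_gti), function(r)
    do.call(rbind, lapply(c("same_week", "following_week"), function(tm)
      rra_descriptive(rer_summary(r, tm))))))
  paths$rer <- file.path(dir, "rer_rra.csv")
  utils::write.csv(rer_all, paths$rer, row.names = FALSE)
  txt <- c("Descriptive report: weekly prevalence and exposure-conditioned ReR/RRa",
           "Proportions are exact count ratios; intervals are Jeffreys central 95%.",
           "", utils::capture.output(print(summaries, digits = 3)),
           "", utils::capture.output(print(rer_all, digits = 3)))
  paths$report <- file.path(dir, "descriptives.txt")
  writeLines(txt, paths$report)
  invisible(paths)
}

#' Published count structure of the reference trial's tables
#'
#' The per-arm week counts printed in the reference trial's descriptive
#' tables: total reported person-weeks, symptom weeks, exposure weeks and
#' site breakdown per outcome, and the symptom-week counts within exposure
#' strata at both timings. These printed counts are the worked-example
#' inputs for the descriptive engine (the underlying participant-level
#' data were never deposited).
#'
#' @return A list of data frames: `totals` (per arm), `outcome_totals`
#'   (per outcome x arm), and `strata` (per outcome x timing x arm x
#'   exposure stratum).
#' @export
reference_counts <- function() {
  arms <- trial_arms()
  totals <- data.frame(
    arm = arms,
    n_weeks = c(11644L, 15014L, 11986L),
    stringsAsFactors = FALSE
  )
  outcome_totals <- data.frame(
    outcome = rep(c("RTI", "GTI"), each = 3L),
    arm = rep(arms, 2L),
    n_symptom_weeks = c(1470L, 1646L, 1546L, 313L, 282L, 274L),
    n_exposure_weeks = c(3279L, 4031L, 3507L, 767L, 937L, 806L),
    site_only_work = c(1068L, 1308L, 882L, 261L, 313L, 251L),
    site_only_elsewhere = c(1448L, 1826L, 1672L, 437L, 493L, 463L),
    site_both = c(763L, 897L, 953L, 69L, 131L, 92L),
    stringsAsFactors = FALSE
  )
  strata <- rbind(
    data.frame(outcome = "RTI", timing = "same_week",
               arm = rep(arms, each = 2L),
               exposed = rep(c(TRUE, FALSE), 3L),
               n_weeks = c(3279L, 8365L, 4031L, 10983L, 3507L, 8476L),
               n_symptom_weeks = c(976L, 494L, 1151L, 495L, 1042L, 504L)),
    data.frame(outcome = "RTI", timing = "following_week",
               arm = rep(arms, each = 2L),
               exposed = rep(c(TRUE, FALSE), 3L),
               n_weeks = c(3279L, 8365L, 4031L, 10983L, 3507L, 8476L),
               n_symptom_weeks = c(805L, 594L, 848L, 707L, 838L, 627L)),
    data.frame(outcome = "GTI", timing = "same_week",
               arm = rep(arms, each = 2L),
               exposed = rep(c(TRUE, FALSE), 3L),
               n_weeks = c(767L, 10877L, 937L, 14107L, 806L, 11180L),
               n_symptom_weeks = c(159L, 154L, 159L, 123L, 143L, 131L)),
    data.frame(outcome = "GTI", timing = "following_week",
               arm = rep(arms, each = 2L),
               exposed = rep(c(TRUE, FALSE), 3L),
               n_weeks = c(767L, 10877L, 937L, 14107L, 806L, 11180L),
               n_symptom_weeks = c(67L, 226L, 51L, 210L, 63L, 193L))
  )
  list(totals = totals, outcome_totals = outcome_totals, strata = strata)
}
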