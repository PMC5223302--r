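#' Posterior predictive margins of weekly prevalence for all arms
#'
#' For every retained posterior draw, each row of the standardization
#' population (the reported person-weeks used by the fit, pooled across
#' arms, months as observed) is assigned the target exposure status, the
#' random effects are integrated over by drawing a fresh person and
#' cluster intercept for every row (a "new individual" margin), and the
#' weekly risks `exp(eta)` are averaged. Risks reaching 1 are truncated to
#' just below 1 and the truncation rate is recorded. All arms are
#' evaluated on the same random-effect noise within a draw, so the
#' per-draw margins are paired and arm ratios are exact coefficient
#' contrasts in the absence of truncation.
#'
#' @param fit A `logbinfit`.
#' @param exposure `"exposed"`, `"unexposed"` or `"observed"` (keep each
#'   row's own exposure status).
#' @param ndraws Number of posterior draws to use (evenly spaced subset;
#'   default all).
#' @param seed Optional seed for the random-effect integration.
#' @param strict If `TRUE`, a truncation rate above 1% is an error instead
#'   of a warning.
#' @return A matrix (draws x arms) of per-draw margins with attribute
#'   `truncation_rate`.
#' @export
margins_set <- function(fit, exposure = c("exposed", "unexposed", "observed"),
                        ndraws = NULL, seed = NULL, strict = FALSE) {
  exposure <- match.arg(exposure)
  if (!is.null(seed)) set.seed(seed)
  d <- fit$draws
  if (!is.null(ndraws) && ndraws < nrow(d))
    d <- d[round(seq(1L, nrow(d), length.out = ndraws)), , drop = FALSE]
  n_d <- nrow(d)
  des <- fit$design
  n <- length(des$y)
  arms <- trial_arms()
  cols <- des$cols
  e <- switch(exposure, exposed = rep(1, n), unexposed = rep(0, n),
              observed = as.numeric(des$exposed))
  # row-level non-arm fixed part: months (+ triplets)
  mt_cols <- c(cols$month, cols$triplet)
  Xmt <- des$X[, mt_cols, drop = FALSE]
  bound <- 1 - 1e-9
  out <- matrix(NA_real_, n_d, length(arms), dimnames = list(NULL, arms))
  trunc_n <- 0
  for (k in seq_len(n_d)) {
    beta <- d[k, ]
    sd_tot <- sqrt(beta[["sigma_person"]]^2 + beta[["sigma_cluster"]]^2)
    base <- beta[["(Intercept)"]] +
      (if (length(mt_cols)) drop(Xmt %*% beta[mt_cols]) else 0) +
      e * beta[[cols$exposure]] + stats::rnorm(n, 0, sd_tot)
    for (a in arms) {
      shift <- 0
      if (a != "control") {
        shift <- beta[[paste0("arm_", a)]]
        int_col <- paste0("exposed_x_arm_", a)
        if (int_col %in% names(beta)) shift <- shift + e * beta[[int_col]]
      }
      risk <- exp(base + shift)
      over <- risk >= 1
      trunc_n <- trunc_n + sum(over)
      if (any(over)) risk[over] <- bound
      out[k, a] <- mean(risk)
    }
  }
  rate <- trunc_n / (n_d * n * length(arms))
  attr(out, "truncation_rate") <- rate
  if (rate > 0.01) {
    msg <- sprintf("margin truncation rate %.2f%% exceeds 1%%", 100 * rate)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  out
}

#' Posterior sample of the predictive margin for one arm
#'
#' @inheritParams margins_set
#' @param arm One of the trial arms.
#' @return Numeric vector of per-draw margins with attribute
#'   `truncation_rate`.
#' @export
predictive_margin <- function(fit, arm = trial_arms(),
                              exposure = c("exposed", "unexposed", "observed"),
                              ndraws = NULL, seed = NULL, strict = FALSE) {
  arm <- match.arg(arm)
  m <- margins_set(fit, exposure, ndraws = ndraws, seed = seed, strict = strict)
  out <- m[, arm]
  attr(out, "truncation_rate") <- attr(m, "truncation_rate")
  out
}

#' Posterior risk ratio of two margin samples
#'
#' Per-draw ratio of paired margin samples, with the posterior median,
#' central 95% credible interval, and the posterior probability that the
#' ratio is below one.
#'
#' @param margins_a,margins_control Per-draw margin samples from the same
#'   posterior draws (paired; equal lengths required).
#' @return A list: `draws`, `median`, `lower`, `upper`, `p_below_1`.
#' @export
risk_ratio <- function(margins_a, margins_control) {
  if (length(margins_a) != length(margins_control))
    stop("unpaired margin samples (unequal lengths)", call. = FALSE)
  r <- as.numeric(margins_a) / as.numeric(margins_control)
  q <- stats::quantile(r, c(0.5, 0.025, 0.975), names = FALSE)
  list(draws = r, median = q[1L], lower = q[2L], upper = q[3L],
       p_below_1 = mean(r < 1))
}

summarize_margin_col <- function(m) {
  q <- apply(m, 2L, stats::quantile, probs = c(0.5, 0.025, 0.975))
  data.frame(arm = colnames(m), margin = q[1L, ], lower = q[2L, ],
             upper = q[3L, ], row.names = NULL, stringsAsFactors = FALSE)
}

stratum_counts <- function(rows, timing) {
  expo <- if (timing == "following_week") {
    rows <- rows[!is.na(rows$exp_lag), , drop = FALSE]
    rows$exp_lag
  } else rows$exp_same
  do.call(rbind, lapply(trial_arms(), function(a) {
    do.call(rbind, lapply(c(TRUE, FALSE), function(ex) {
      sel <- rows$arm == a & expo == ex
      data.frame(arm = a, exposure = if (ex) "exposed" else "unexposed",
                 n_weeks = sum(sel), n_symptom_weeks = sum(rows$y[sel]),
                 proportion = if (sum(sel)) sum(rows$y[sel]) / sum(sel) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
}

#' Full margin report for both outcomes and both timings
#'
#' Runs the inferential stage end to end: for each outcome, fits the
#' same-week model with arm-by-exposure interactions; fits the
#' following-week model with interactions and, when every interaction's
#' 95% credible interval covers zero, collapses and refits without them so
#' a single arm-level risk ratio applies to both exposure strata; computes
#' predictive margins, risk ratios vs control with credible intervals and
#' `P(RRa < 1)` per arm and exposure stratum; and an overall (observed
#' exposure) prevalence table in the style of an arm-level summary table.
#'
#' @param rows_rti,rows_gti Analysis rows per outcome.
#' @param iter,chains,seed MCMC settings passed to [fit_prevalence()].
#' @param ndraws Posterior draws used for the margins.
#' @param strict Escalate margin truncation above 1% to an error.
#' @param check Convergence handling passed to [fit_prevalence()]; a fit
#'   failing diagnostics under `check = "error"` aborts the report with
#'   the offending fit named.
#' @return A `margin_report` list: per outcome, the overall table and the
#'   per-timing stratified tables plus collapse indicators and the fits.
#' @export
margin_report <- function(rows_rti, rows_gti, iter = 4000, chains = 2,
                          seed = NULL, ndraws = 500, strict = FALSE,
                          check = "error") {
  rows_by <- list(RTI = rows_rti, GTI = rows_gti)
  report <- list()
  for (oc in names(rows_by)) {
    rows <- rows_by[[oc]]
    fits <- list()
    tabs <- list()
    for (tm in c("same_week", "following_week")) {
      fit <- tryCatch(
        fit_prevalence(rows, timing = tm, interaction = TRUE,
                       iter = iter, chains = chains, seed = seed,
                       check = check),
        error = function(e) stop("report aborted at fit [", oc, ", ", tm,
                                 "]: ", conditionMessage(e), call. = FALSE))
      collapsed <- FALSE
      if (tm == "following_week") {
        spec <- collapse_interaction(fit)
        collapsed <- attr(spec, "collapsed")
        if (collapsed)
          fit <- fit_prevalence(rows, timing = tm, interaction = FALSE,
                                iter = iter, chains = chains, seed = seed,
                                check = check)
      }
      fits[[tm]] <- fit
      counts <- stratum_counts(rows, tm)
      strata_tab <- list()
      rra_by_arm <- NULL
      for (ex in c("exposed", "unexposed")) {
        m <- margins_set(fit, ex, ndraws = ndraws, seed = seed,
                         strict = strict)
        sm <- summarize_margin_col(m)
        if (collapsed) {
          # single arm-level estimate: one RRa per arm, shared by strata
          if (is.null(rra_by_arm))
            rra_by_arm <- lapply(trial_arms()[-1L], function(a)
              risk_ratio(m[, a], m[, "control"]))
          rr <- rra_by_arm
        } else {
          rr <- lapply(trial_arms()[-1L], function(a)
            risk_ratio(m[, a], m[, "control"]))
        }
        names(rr) <- trial_arms()[-1L]
        sm$exposure <- ex
        sm$rra <- sm$rra_lower <- sm$rra_upper <- sm$p_below_1 <- NA_real_
        for (a in names(rr)) {
          i <- sm$arm == a
          sm$rra[i] <- rr[[a]]$median
          sm$rra_lower[i] <- rr[[a]]$lower
          sm$rra_upper[i] <- rr[[a]]$upper
          sm$p_below_1[i] <- rr[[a]]$p_below_1
        }
        strata_tab[[ex]] <- sm
      }
      tab <- do.call(rbind, strata_tab)
      tab <- merge(counts, tab, by = c("arm", "exposure"), sort = FALSE)
      tab$outcome <- oc
      tab$timing <- tm
      tab$collapsed <- collapsed
      rownames(tab) <- NULL
      tabs[[tm]] <- tab
    }
    # overall weekly prevalence (observed exposure), same-week fit
    m_all <- margins_set(fits$same_week, "observed", ndraws = ndraws,
                         seed = seed, strict = strict)
    overall <- summarize_margin_col(m_all)
    overall$rra <- overall$rra_lower <- overall$rra_upper <-
      overall$p_below_1 <- NA_real_
    for (a in trial_arms()[-1L]) {
      rr <- risk_ratio(m_all[, a], m_all[, "control"])
      i <- overall$arm == a
      overall$rra[i] <- rr$median
      overall$rra_lower[i] <- rr$lower
      overall$rra_upper[i] <- rr$upper
      overall$p_below_1[i] <- rr$p_below_1
    }
    arm_n <- vapply(trial_arms(), function(a) sum(rows$arm == a), 0L)
    arm_k <- vapply(trial_arms(), function(a) sum(rows$y[rows$arm == a]), 0)
    overall <- cbind(overall,
                     n_weeks = arm_n[overall$arm],
                     n_symptom_weeks = arm_k[overall$arm],
                     prevalence = arm_k[overall$arm] / arm_n[overall$arm])
    overall$outcome <- oc
    rownames(overall) <- NULL
    report[[oc]] <- list(overall = overall, same_week = tabs$same_week,
                         following_week = tabs$following_week,
                         fits = fits)
  }
  class(report) <- "margin_report"
  report
}

#' @export
print.margin_report <- function(x, ...) {
  for (oc in names(x)) {
    cat("==", oc, "overall weekly prevalence (predictive margins) ==\n")
    print.data.frame(x[[oc]]$overall, digits = 3, row.names = FALSE)
    for (tm in c("same_week", "following_week")) {
      cat("--", oc, tm, if (isTRUE(x[[oc]][[tm]]$collapsed[1L]))
        "(interaction collapsed: single arm-level RRa)" else "", "--\n")
      print.data.frame(x[[oc]][[tm]][
        c("arm", "exposure", "n_weeks", "n_symptom_weeks", "proportion",
          "margin", "lower", "upper", "rra", "rra_lower", "rra_upper",
          "p_below_1")], digits = 3, row.names = FALSE)
    }
  }
  invisible(x)
}

#' Write a margin report as CSV files and a text report
#'
#' @param report A `margin_report`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_margin_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  overall <- do.call(rbind, lapply(report, function(r) r$overall))
  paths$overall <- file.path(dir, "margins_overall.csv")
  utils::write.csv(overall, paths$overall, row.names = FALSE)
  strata <- do.call(rbind, lapply(report, function(r)
    rbind(r$same_week, r$following_week)))
  paths$strata <- file.path(dir, "margins_by_exposure.csv")
  utils::write.csv(strata, paths$strata, row.names = FALSE)
  paths$report <- file.path(dir, "margins.txt")
  writeLines(utils::capture.output(print(report)), paths$report)
  invisible(paths)
}
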