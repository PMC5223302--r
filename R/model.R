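#' Prior specification for the Bayesian log-binomial model
#'
#' Vague but proper priors: Normal(0, `fixed_effect_sd`^2) on every fixed
#' effect (log-risk scale) and half-normal(`re_scale`) on the person and
#' cluster random-intercept SDs.
#'
#' @param fixed_effect_sd Prior SD of the fixed effects (log scale).
#' @param re_scale Scale of the half-normal prior on both random-effect SDs.
#' @return A `prior_spec` list.
#' @export
prior_spec <- function(fixed_effect_sd = 10, re_scale = 2) {
  stopifnot(fixed_effect_sd > 0, re_scale > 0)
  structure(list(fixed_effect_sd = fixed_effect_sd, re_scale = re_scale),
            class = "prior_spec")
}

#' Build the fixed-effect design for the weekly-prevalence model
#'
#' Reference coding: control arm, unexposed, January (or the earliest
#' observed month when January is absent) as the month reference. Columns
#' are the intercept, two arm indicators, one homologous-exposure
#' indicator at the chosen timing, optionally two arm-by-exposure
#' interaction columns, the observed non-reference month indicators, and
#' optionally triplet indicators. Person and cluster index vectors carry
#' the random-effect structure. Rows with a missing lagged exposure are
#' dropped for the following-week timing.
#'
#' @param rows Analysis rows from [build_analysis_rows()].
#' @param timing `"same_week"` or `"following_week"`.
#' @param interaction Include arm x exposure interaction columns.
#' @param triplet Include triplet fixed effects (needs `triplet_of`).
#' @param triplet_of Named integer vector mapping cluster id to triplet.
#' @return A list: `y`, `X`, `person`, `cluster` (0-based indices),
#'   `person_ids`, `cluster_ids`, `rows` (the rows actually used), column
#'   bookkeeping (`cols`), and the exposure vector used.
#' @export
build_design <- function(rows, timing = c("same_week", "following_week"),
                         interaction = TRUE, triplet = FALSE,
                         triplet_of = NULL) {
  timing <- match.arg(timing)
  if (timing == "following_week") {
    rows <- rows[!is.na(rows$exp_lag), , drop = FALSE]
    exposed <- rows$exp_lag
  } else {
    exposed <- rows$exp_same
  }
  if (!nrow(rows)) stop("no usable rows for timing ", timing, call. = FALSE)
  arms <- trial_arms()
  missing_arms <- setdiff(arms, unique(rows$arm))
  if (length(missing_arms))
    stop("arm level(s) unseen in data: ", paste(missing_arms, collapse = ", "),
         call. = FALSE)
  if (all(exposed) || !any(exposed))
    stop("exposure column is constant; model not identifiable", call. = FALSE)

  n <- nrow(rows)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  arm_cols <- paste0("arm_", arms[-1L])
  for (a in arms[-1L]) X <- cbind(X, as.numeric(rows$arm == a))
  colnames(X)[2:3] <- arm_cols
  X <- cbind(X, exposed = as.numeric(exposed))
  int_cols <- character()
  if (interaction) {
    int_cols <- paste0("exposed_x_arm_", arms[-1L])
    for (a in arms[-1L]) X <- cbind(X, as.numeric(exposed & rows$arm == a))
    colnames(X)[c(ncol(X) - 1L, ncol(X))] <- int_cols
  }
  months_present <- sort(unique(rows$month))
  month_cols <- character()
  ref_month <- if (1L %in% months_present) 1L else months_present[1L]
  if (length(months_present) < 2L) {
    warning("single calendar month observed; month effects dropped")
  } else {
    for (m in setdiff(months_present, ref_month)) {
      X <- cbind(X, as.numeric(rows$month == m))
      month_cols <- c(month_cols, paste0("month_", m))
      colnames(X)[ncol(X)] <- paste0("month_", m)
    }
  }
  triplet_cols <- character()
  if (triplet) {
    if (is.null(triplet_of))
      stop("triplet = TRUE needs triplet_of (cluster id -> triplet)", call. = FALSE)
    trs <- sort(unique(triplet_of[rows$cluster_id]))
    for (tr in trs[-1L]) {
      X <- cbind(X, as.numeric(triplet_of[rows$cluster_id] == tr))
      triplet_cols <- c(triplet_cols, paste0("triplet_", tr))
      colnames(X)[ncol(X)] <- paste0("triplet_", tr)
    }
  }
  csums <- colSums(X)
  bad <- which(csums[-1L] == 0 | csums[-1L] == n) + 1L
  if (length(bad))
    stop("degenerate design column(s): ",
         paste(colnames(X)[bad], collapse = ", "), call. = FALSE)

  person_ids <- sort(unique(rows$person_id))
  cluster_ids <- sort(unique(rows$cluster_id))
  list(y = as.numeric(rows$y), X = X,
       person = match(rows$person_id, person_ids) - 1L,
       cluster = match(rows$cluster_id, cluster_ids) - 1L,
       person_ids = person_ids, cluster_ids = cluster_ids,
       rows = rows, exposed = exposed,
       cols = list(arm = arm_cols, exposure = "exposed",
                   interaction = int_cols, month = month_cols,
                   triplet = triplet_cols, ref_month = ref_month),
       timing = timing)
}

log1mexp <- function(eta) {
  ifelse(eta < -log(2), log1p(-exp(eta)), log(-expm1(eta)))
}

#' Log posterior density of the log-binomial GLMM
#'
#' Bernoulli log-likelihood with `log p = X beta + u[person] + v[cluster]`,
#' plus Normal log-priors on the fixed effects, half-normal log-priors on
#' the random-effect SDs, and the Normal log-densities of the realized
#' random effects. Returns `-Inf` whenever any fitted probability reaches
#' 1 (the log-link support boundary) or an SD is non-positive.
#'
#' @param theta List with elements `beta`, `u`, `v`, `sigma_person`,
#'   `sigma_cluster`.
#' @param design Design structure from [build_design()].
#' @param priors A [prior_spec()].
#' @return A single finite number, or `-Inf` outside the support.
#' @export
log_posterior <- function(theta, design, priors = prior_spec()) {
  stopifnot(is.list(theta), length(theta$beta) == ncol(design$X))
  if (any(!is.finite(c(theta$beta, theta$u, theta$v,
                       theta$sigma_person, theta$sigma_cluster))))
    stop("non-finite parameter value", call. = FALSE)
  if (theta$sigma_person <= 0 || theta$sigma_cluster <= 0) return(-Inf)
  eta <- drop(design$X %*% theta$beta) + theta$u[design$person + 1L] +
    theta$v[design$cluster + 1L]
  if (any(eta >= 0)) return(-Inf)
  ll <- sum(design$y * eta + (1 - design$y) * log1mexp(eta))
  lp <- sum(stats::dnorm(theta$beta, 0, priors$fixed_effect_sd, log = TRUE)) +
    stats::dnorm(theta$sigma_person, 0, priors$re_scale, log = TRUE) + log(2) +
    stats::dnorm(theta$sigma_cluster, 0, priors$re_scale, log = TRUE) + log(2) +
    sum(stats::dnorm(theta$u, 0, theta$sigma_person, log = TRUE)) +
    sum(stats::dnorm(theta$v, 0, theta$sigma_cluster, log = TRUE))
  ll + lp
}

# split-half R-hat (potential scale reduction) over a list of chains
split_rhat <- function(chains) {
  halves <- list()
  for (ch in chains) {
    m <- length(ch) %/% 2L
    halves <- c(halves, list(ch[seq_len(m)], ch[m + seq_len(m)]))
  }
  m <- length(halves); n <- length(halves[[1L]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit the Bayesian weekly-prevalence model by MCMC
#'
#' Fits the hierarchical log-link binary regression of weekly symptom
#' status on trial arm, reported homologous exposure (same or previous
#' week), their interaction, calendar month, and optionally randomization
#' triplet, with normally distributed person and cluster random intercepts
#' on the log scale. Sampling is adaptive random-walk
#' Metropolis-within-Gibbs with proposals violating the `p < 1` support
#' rejected; proposal scales adapt during burn-in only. Chains start from
#' jittered initial values; the first half of each chain is discarded and
#' the rest thinned to at most `max_stored` draws per chain. Convergence
#' is summarized by split R-hat and effective sample size per reported
#' parameter (fixed effects and both SDs); by default the fit fails
#' loudly when any R-hat exceeds 1.05 or any ESS falls below 200.
#'
#' @param rows Analysis rows from [build_analysis_rows()].
#' @param timing `"same_week"` or `"following_week"`.
#' @param interaction Include arm x exposure interactions.
#' @param triplet Include triplet fixed effects.
#' @param triplet_of Named map cluster id -> triplet (if `triplet`).
#' @param priors A [prior_spec()].
#' @param iter Iterations per chain (including burn-in).
#' @param chains Number of chains (>= 2).
#' @param seed Integer seed; chain c uses `seed + c - 1`.
#' @param max_stored Cap on stored post-burn-in draws per chain.
#' @param check `"error"` (default), `"warn"` or `"none"`: what to do when
#'   diagnostics fail.
#' @return An object of class `logbinfit`.
#' @examples
#' \donttest{
#' design <- randomize_arms(assign_triplets(make_clusters(9, seed = 1)), seed = 2)
#' pars <- default_calibration(n_weeks = 20, reporters_per_cluster = 20)
#' pw <- simulate_trial(design, pars, seed = 3)
#' rows <- build_analysis_rows(pw, "rti")
#' fit <- fit_prevalence(rows, iter = 1500, seed = 4, check = "warn")
#' summary(fit)
#' }
#' @export
fit_prevalence <- function(rows, timing = c("same_week", "following_week"),
                           interaction = TRUE, triplet = FALSE,
                           triplet_of = NULL, priors = prior_spec(),
                           iter = 4000, chains = 2, seed = NULL,
                           max_stored = 2000,
                           check = c("error", "warn", "none")) {
  timing <- match.arg(timing)
  check <- match.arg(check)
  stopifnot(chains >= 2, iter >= 200)
  design <- build_design(rows, timing, interaction, triplet, triplet_of)
  p <- ncol(design$X)
  burnin <- iter %/% 2L
  thin <- max(1L, ceiling((iter - burnin) / max_stored))
  base_init <- c(log(max(mean(design$y), 1 / (2 * length(design$y)))),
                 rep(0, p - 1L))

  chain_draws <- vector("list", chains)
  for (ch in seq_len(chains)) {
    if (!is.null(seed)) set.seed(seed + ch - 1L)
    repeat {
      init <- base_init + stats::rnorm(p, 0, 0.05)
      if (all(design$X %*% init < 0)) break
    }
    res <- .mwg_sampler(design$y, design$X, design$person, design$cluster,
                        priors$fixed_effect_sd, priors$re_scale,
                        priors$re_scale, as.integer(iter),
                        as.integer(burnin), as.integer(thin), init,
                        stats::runif(1, 0.05, 0.3), stats::runif(1, 0.05, 0.3))
    colnames(res$beta) <- colnames(design$X)
    chain_draws[[ch]] <- res
  }

  par_names <- c(colnames(design$X), "sigma_person", "sigma_cluster")
  mats <- lapply(chain_draws, function(r)
    cbind(r$beta, sigma_person = r$sigma_person, sigma_cluster = r$sigma_cluster))
  draws <- do.call(rbind, mats)
  chain_id <- rep(seq_len(chains), vapply(mats, nrow, 0L))

  rhat <- vapply(par_names, function(nm)
    split_rhat(lapply(mats, function(m) m[, nm])), 0)
  ess <- vapply(par_names, function(nm)
    sum(vapply(mats, function(m) unname(coda::effectiveSize(m[, nm])), 0)), 0)
  diag <- data.frame(parameter = par_names, rhat = rhat, ess = ess,
                     row.names = NULL, stringsAsFactors = FALSE)
  bad <- diag[diag$rhat > 1.05 | diag$ess < 200, , drop = FALSE]
  converged <- nrow(bad) == 0L
  if (!converged && check != "none") {
    msg <- paste0("MCMC convergence check failed for: ",
                  paste(sprintf("%s (R-hat %.3f, ESS %.0f)", bad$parameter,
                                bad$rhat, bad$ess), collapse = "; "))
    if (check == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }

  structure(list(
    draws = draws, chain_id = chain_id, chains = chains,
    u = do.call(rbind, lapply(chain_draws, `[[`, "u")),
    v = do.call(rbind, lapply(chain_draws, `[[`, "v")),
    diagnostics = diag, converged = converged,
    design = design, priors = priors,
    spec = list(outcome = rows$outcome[1L], timing = timing,
                interaction = interaction, triplet = triplet),
    iter = iter, burnin = burnin, thin = thin, seed = seed,
    call = match.call()
  ), class = "logbinfit")
}

#' @export
print.logbinfit <- function(x, ...) {
  cat(sprintf("Bayesian log-binomial GLMM: outcome %s, timing %s\n",
              x$spec$outcome, x$spec$timing))
  cat(sprintf("  %d rows, %d persons, %d clusters\n", length(x$design$y),
              length(x$design$person_ids), length(x$design$cluster_ids)))
  cat(sprintf("  %d chains x %d iterations (burn-in %d, thin %d); %d draws kept\n",
              x$chains, x$iter, x$burnin, x$thin, nrow(x$draws)))
  cat(sprintf("  max split R-hat %.3f, min ESS %.0f%s\n",
              max(x$diagnostics$rhat), min(x$diagnostics$ess),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
summary.logbinfit <- function(object, ...) {
  d <- object$draws
  qs <- t(apply(d, 2L, stats::quantile, probs = c(0.5, 0.025, 0.975)))
  out <- data.frame(
    parameter = colnames(d),
    median = qs[, 1L], sd = apply(d, 2L, stats::sd),
    q2.5 = qs[, 2L], q97.5 = qs[, 3L],
    rr = exp(qs[, 1L]),
    rhat = object$diagnostics$rhat, ess = object$diagnostics$ess,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out$rr[out$parameter %in% c("sigma_person", "sigma_cluster")] <- NA
  class(out) <- c("summary.logbinfit", "data.frame")
  out
}

#' @export
print.summary.logbinfit <- function(x, ...) {
  cat("Posterior summary (medians, 95% credible intervals; rr = exp(median))\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
coef.logbinfit <- function(object, ...) {
  p <- ncol(object$design$X)
  apply(object$draws[, seq_len(p), drop = FALSE], 2L, stats::median)
}

#' @export
as.matrix.logbinfit <- function(x, ...) x$draws

#' @export
plot.logbinfit <- function(x, parameters = NULL, ...) {
  pars <- parameters %||% intersect(
    c("(Intercept)", x$design$cols$arm, x$design$cols$exposure,
      "sigma_person", "sigma_cluster"), colnames(x$draws))
  op <- graphics::par(mfrow = c(min(3L, length(pars)),
                                ceiling(length(pars) / 3)), mar = c(3, 3, 2, 1))
  on.exit(graphics::par(op))
  for (nm in pars) {
    graphics::plot(x$draws[, nm], type = "n", main = nm, xlab = "", ylab = "")
    for (ch in seq_len(x$chains)) {
      sel <- x$chain_id == ch
      graphics::lines(which(sel) - min(which(sel)) + 1L, x$draws[sel, nm],
                      col = ch)
    }
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Decide whether to collapse the arm-by-exposure interaction
#'
#' If every interaction coefficient's central 95% credible interval
#' contains zero, the interaction is deemed credibly null and the returned
#' specification has `interaction = FALSE` (the caller refits to obtain a
#' single arm-level estimate); otherwise the specification is returned
#' unchanged.
#'
#' @param fit A `logbinfit` fitted with interactions.
#' @return The fit's spec list, with attribute `collapsed` (`TRUE`/`FALSE`).
#' @export
collapse_interaction <- function(fit) {
  int_cols <- fit$design$cols$interaction
  if (!length(int_cols))
    stop("fit has no interaction terms", call. = FALSE)
  ci <- apply(fit$draws[, int_cols, drop = FALSE], 2L, stats::quantile,
              probs = c(0.025, 0.975))
  all_null <- all(ci[1L, ] <= 0 & ci[2L, ] >= 0)
  spec <- fit$spec
  if (all_null) spec$interaction <- FALSE
  attr(spec, "collapsed") <- all_null
  spec
}

#' Write posterior draws and diagnostics to disk
#'
#' Draws go to a long-format CSV (`chain`, `iteration`, `parameter`,
#' `value`); diagnostics to a JSON summary.
#'
#' @param fit A `logbinfit`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- fit$draws
  long <- data.frame(
    chain = rep(fit$chain_id, ncol(d)),
    iteration = rep(stats::ave(fit$chain_id, fit$chain_id, FUN = seq_along),
                    ncol(d)),
    parameter = rep(colnames(d), each = nrow(d)),
    value = as.vector(d)
  )
  paths <- list(draws = file.path(dir, sprintf("draws_%s_%s.csv",
                                               tolower(fit$spec$outcome),
                                               fit$spec$timing)),
                diagnostics = file.path(dir, sprintf("diagnostics_%s_%s.json",
                                                     tolower(fit$spec$outcome),
                                                     fit$spec$timing)))
  utils::write.csv(long, paths$draws, row.names = FALSE)
  jsonlite::write_json(
    list(spec = fit$spec, converged = fit$converged,
         diagnostics = fit$diagnostics,
         iter = fit$iter, chains = fit$chains, seed = fit$seed),
    paths$diagnostics, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
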