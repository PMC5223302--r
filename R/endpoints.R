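#' Collapse daily symptom diaries to weekly symptom flags
#'
#' The analysis endpoint is the "week with reported symptoms": a report
#' week counts as symptomatic when at least one of its seven diary days is
#' symptomatic. Day columns (`rti_d1..d7`, `gti_d1..d7`) must be present;
#' all other fields pass through unchanged. The operation is idempotent.
#'
#' @param pw A person-week data frame with day columns.
#' @return The same data frame with `rti_symptoms` / `gti_symptoms`
#'   recomputed from the day vectors.
#' @export
daily_to_weekly <- function(pw) {
  for (o in outcomes()) {
    day_cols <- paste0(o, "_d", 1:7)
    flag_col <- paste0(o, "_symptoms")
    if (!all(day_cols %in% names(pw))) {
      if (!flag_col %in% names(pw))
        stop("records carry neither ", o, " day vectors nor a weekly flag",
             call. = FALSE)
      next
    }
    days <- as.matrix(pw[day_cols])
    pw[[flag_col]] <- rowSums(days == 1L, na.rm = TRUE) > 0
    pw[[flag_col]][rowSums(!is.na(days)) == 0L] <- NA
  }
  pw
}

#' Extract designated episodes from daily diaries
#'
#' A designated episode is a maximal run of successive symptomatic days of
#' one outcome for one person. Runs continue across a reported week
#' boundary (a Saturday-Monday episode is one episode even though it flags
#' two weeks), while unreported weeks contribute no observed days and so
#' terminate any run. RTI and GTI episodes are extracted independently and
#' may overlap in time.
#'
#' @param pw A person-week data frame with day columns.
#' @return A data frame with one row per episode: `person_id`, `outcome`,
#'   `start_day` (absolute day index, week 1 day 1 = 1), `length_days`.
#' @export
episodes_from_daily <- function(pw) {
  out <- list()
  for (o in outcomes()) {
    day_cols <- paste0(o, "_d", 1:7)
    if (!all(day_cols %in% names(pw)))
      stop("records carry no ", o, " day vectors", call. = FALSE)
    rep_rows <- which(pw$reported %in% TRUE)
    if (!length(rep_rows)) next
    days <- as.matrix(pw[rep_rows, day_cols])
    sympt <- which(days == 1L, arr.ind = TRUE)
    if (!nrow(sympt)) next
    abs_day <- (pw$week_index[rep_rows[sympt[, 1L]]] - 1L) * 7L + sympt[, 2L]
    person <- pw$person_id[rep_rows[sympt[, 1L]]]
    ord <- order(person, abs_day)
    person <- person[ord]; abs_day <- abs_day[ord]
    # a new episode starts where the person changes or days are not adjacent
    new_run <- c(TRUE, person[-1L] != person[-length(person)] |
                   abs_day[-1L] != abs_day[-length(abs_day)] + 1L)
    run_id <- cumsum(new_run)
    starts <- which(new_run)
    out[[o]] <- data.frame(
      person_id = person[starts],
      outcome = toupper(o),
      start_day = abs_day[starts],
      length_days = as.integer(tabulate(run_id)),
      stringsAsFactors = FALSE
    )
  }
  if (!length(out))
    return(data.frame(person_id = character(), outcome = character(),
                      start_day = integer(), length_days = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build model-ready analysis rows for one outcome
#'
#' Produces one row per reported person-week with the target outcome's
#' weekly symptom indicator `y`, the same-week homologous exposure
#' `exp_same`, and the previous week's exposure `exp_lag`. `exp_lag` is
#' missing when the immediately preceding calendar week of the same person
#' was unreported or does not exist; such rows are used by same-week
#' analyses but excluded from following-week analyses. The reported site
#' of exposure is carried through for descriptive use only.
#'
#' @param pw A person-week data frame with weekly symptom flags.
#' @param outcome `"rti"` or `"gti"`.
#' @return A data frame of analysis rows: `person_id`, `cluster_id`,
#'   `arm`, `week_index`, `month`, `y`, `exp_same`, `exp_lag`, `site`,
#'   `outcome`.
#' @export
build_analysis_rows <- function(pw, outcome = c("rti", "gti")) {
  outcome <- match.arg(outcome)
  flag <- pw[[paste0(outcome, "_symptoms")]]
  expo <- pw[[paste0(outcome, "_exposure")]]
  if (is.null(flag)) stop("weekly symptom flags absent; run daily_to_weekly first",
                          call. = FALSE)
  rep_idx <- which(pw$reported %in% TRUE)
  rows <- data.frame(
    person_id = pw$person_id[rep_idx],
    cluster_id = pw$cluster_id[rep_idx],
    arm = pw$arm[rep_idx],
    week_index = pw$week_index[rep_idx],
    month = pw$month[rep_idx],
    y = as.integer(flag[rep_idx]),
    exp_same = expo[rep_idx] %in% TRUE,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(rows[c("person_id", "week_index")]))
    stop("duplicate (person, week) report", call. = FALSE)
  # previous-week exposure of the same person, NA when that week is absent
  key <- paste(rows$person_id, rows$week_index)
  prev_key <- paste(rows$person_id, rows$week_index - 1L)
  prev_idx <- match(prev_key, key)
  rows$exp_lag <- rows$exp_same[prev_idx]
  site <- pw[[paste0(outcome, "_site")]]
  rows$site <- if (is.null(site)) NA_character_ else site[rep_idx]
  rows$outcome <- toupper(outcome)
  rows
}

#' Write / read analysis rows as CSV
#'
#' Same CSV dialect as the person-week files: booleans as 0/1, missing as
#' empty fields.
#'
#' @param rows Analysis-row data frame from [build_analysis_rows()].
#' @param path File path.
#' @export
write_analysis_rows <- function(rows, path) {
  out <- rows
  for (nm in c("exp_same", "exp_lag"))
    out[[nm]] <- as.integer(out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_analysis_rows
#' @export
read_analysis_rows <- function(path) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  for (nm in c("exp_same", "exp_lag"))
    if (nm %in% names(rows)) rows[[nm]] <- rows[[nm]] == 1L
  rows
}
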