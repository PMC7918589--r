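# Utility trajectories, LOCF imputation and QALY area-under-the-curve.
#
# A cohort is a long-format data frame with one row per patient per
# assessment week: columns patient_id, arm ("DN" or "PNE"), week, utility
# (NA when the assessment is missing) and observed (logical flag; imputed
# values keep observed = FALSE so they remain distinguishable).

trial_arms <- c("DN", "PNE")
default_weeks <- c(0, 4, 8, 12, 26, 52)

#' Assemble and validate a cohort data frame
#'
#' @param df Data frame with columns \code{patient_id}, \code{arm},
#'   \code{week}, \code{utility} and optionally \code{observed} (defaults to
#'   \code{!is.na(utility)}).
#' @return The validated cohort, ordered by patient then week, with class
#'   \code{c("needle_cohort", "data.frame")}.
#' @export
as_cohort <- function(df) {
  df <- as.data.frame(df)
  need <- c("patient_id", "arm", "week", "utility")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(df$arm %in% trial_arms))
    stop("arm must be one of ", paste(trial_arms, collapse = "/"),
         call. = FALSE)
  if (is.null(df$observed)) df$observed <- !is.na(df$utility)
  df <- df[order(df$arm, df$patient_id, df$week), , drop = FALSE]
  # weeks must form a strictly increasing grid starting at 0 per patient
  by_pat <- split(df$week, df$patient_id)
  for (w in by_pat) {
    if (w[1] != 0 || any(diff(w) <= 0))
      stop("each patient needs a strictly increasing week grid starting at 0",
           call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("needle_cohort", "data.frame")
  df
}

#' Last-observation-carried-forward imputation
#'
#' Fills every missing follow-up utility with the most recent observed value
#' at an earlier week, per patient (intention-to-treat convention). The
#' \code{observed} flags are preserved, so imputed points remain
#' distinguishable. The operation is idempotent. Patients whose baseline
#' (week 0) utility is missing cannot be anchored and are excluded with a
#' warning; their ids are attached as \code{attr(, "excluded")}.
#'
#' @param cohort A cohort data frame (see \code{\link{as_cohort}}).
#' @return The cohort with \code{utility} complete, baseline-missing patients
#'   removed.
#' @export
locf_impute <- function(cohort) {
  cohort <- as_cohort(cohort)
  base <- cohort[cohort$week == 0, ]
  excluded <- unique(as.character(base$patient_id[is.na(base$utility)]))
  if (length(excluded)) {
    warning("excluding ", length(excluded),
            " patient(s) with missing baseline utility (LOCF needs an ",
            "origin): ", paste(excluded, collapse = ", "), call. = FALSE)
    cohort <- cohort[!(cohort$patient_id %in% excluded), , drop = FALSE]
  }
  cohort$utility <- stats::ave(
    cohort$utility, cohort$patient_id,
    FUN = function(u) zoo::na.locf(u, na.rm = FALSE))
  attr(cohort, "excluded") <- excluded
  cohort
}

# trapezoid over one patient's complete trajectory, in utility-weeks
trapezoid_auc <- function(weeks, utilities) {
  sum(diff(weeks) * (utilities[-length(utilities)] + utilities[-1]) / 2)
}

#' Per-patient QALYs by trapezoidal area under the utility curve
#'
#' Integrates each patient's utility trajectory over the follow-up horizon
#' by the trapezoid rule and converts utility-weeks to QALYs with the
#' 52-weeks-per-year convention (so a 52-week horizon yields QALYs
#' directly; a constant utility of 1 accrues exactly 1 QALY).
#'
#' Two summaries are returned per patient: \code{total_qaly}, the integral
#' itself, and \code{baseline_anchored_gain}, the integral minus the
#' baseline utility held constant over the horizon (the QALY gain relative
#' to "no change from baseline"). A constant trajectory has a gain of 0.
#'
#' @param cohort A complete (post-LOCF) cohort.
#' @param horizon_weeks Horizon; must equal each patient's last assessment
#'   week (default 52).
#' @param weeks_per_year Year convention (default 52).
#' @return Data frame with columns \code{patient_id}, \code{arm},
#'   \code{total_qaly}, \code{baseline_anchored_gain}.
#' @export
qaly_auc <- function(cohort, horizon_weeks = 52, weeks_per_year = 52) {
  cohort <- as_cohort(cohort)
  if (anyNA(cohort$utility))
    stop("trajectory incomplete: impute first (see locf_impute)",
         call. = FALSE)
  res <- do.call(rbind, lapply(split(cohort, cohort$patient_id), function(p) {
    if (max(p$week) != horizon_weeks)
      stop("patient ", p$patient_id[1], ": last assessment week ",
           max(p$week), " does not match horizon ", horizon_weeks,
           call. = FALSE)
    tq <- trapezoid_auc(p$week, p$utility) / weeks_per_year
    data.frame(patient_id = p$patient_id[1], arm = p$arm[1],
               total_qaly = tq,
               baseline_anchored_gain =
                 tq - p$utility[p$week == 0] * horizon_weeks / weeks_per_year,
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

#' QALYs for a single mean trajectory
#'
#' Convenience wrapper for group-level curves (e.g. trapezoid on arm means).
#'
#' @param weeks Assessment weeks, strictly increasing from 0.
#' @param utilities Utility at each week.
#' @param weeks_per_year Year convention (default 52).
#' @return Total QALYs over the trajectory's span.
#' @export
qaly_auc_curve <- function(weeks, utilities, weeks_per_year = 52) {
  stopifnot(length(weeks) == length(utilities), weeks[1] == 0,
            all(diff(weeks) > 0), !anyNA(utilities))
  trapezoid_auc(weeks, utilities) / weeks_per_year
}

#' Group-level descriptive table of utilities
#'
#' Per assessment week and arm: mean and SD of the utility index, the
#' within-arm mean change from baseline, and the between-group (PNE - DN)
#' difference with its SD (computed as \eqn{\sqrt{sd_{DN}^2 + sd_{PNE}^2}},
#' the SD of the difference of independent individual observations).
#'
#' @param cohort A cohort data frame; missing utilities are ignored per cell
#'   (pass a post-LOCF cohort for the intention-to-treat version).
#' @return Data frame with one row per week.
#' @export
group_mean_table <- function(cohort) {
  cohort <- as_cohort(cohort)
  for (a in trial_arms)
    if (!any(cohort$arm == a)) stop("arm ", a, " is empty", call. = FALSE)
  cell <- function(a, w, f)
    f(cohort$utility[cohort$arm == a & cohort$week == w], na.rm = TRUE)
  weeks <- sort(unique(cohort$week))
  mean_ <- function(x, na.rm) mean(x, na.rm = na.rm)
  # SD of a single observation reported as 0 (degenerate cells), not NA
  sd_ <- function(x, na.rm) {
    x <- x[!is.na(x)]
    if (length(x) < 2) 0 else stats::sd(x)
  }
  dn_m <- vapply(weeks, function(w) cell("DN", w, mean_), 0)
  pne_m <- vapply(weeks, function(w) cell("PNE", w, mean_), 0)
  dn_s <- vapply(weeks, function(w) cell("DN", w, sd_), 0)
  pne_s <- vapply(weeks, function(w) cell("PNE", w, sd_), 0)
  data.frame(
    week = weeks,
    dn_mean = dn_m, dn_sd = dn_s, dn_change = dn_m - dn_m[1],
    pne_mean = pne_m, pne_sd = pne_s, pne_change = pne_m - pne_m[1],
    diff = pne_m - dn_m,
    diff_sd = sqrt(dn_s^2 + pne_s^2))
}
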