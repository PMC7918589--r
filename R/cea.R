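# Incremental cost-effectiveness analysis and probabilistic sensitivity
# analysis for a two-arm trial: ICER with dominance classification,
# nonparametric bootstrap of cost-QALY pairs (independent within-arm
# resampling with arm sizes fixed), the cost-effectiveness plane, and the
# cost-effectiveness acceptability curve (CEAC).
#
# Conventions: deltas are PNE - DN. Incremental net benefit at a
# willingness-to-pay threshold lambda is INB = lambda * dQALY - dCost; a
# bootstrap pair counts as cost-effective only when INB is strictly
# positive (ties count against).

# quadrant of the CE plane from the signs of (delta_cost, delta_qaly);
# boundary cases (a zero delta) are assigned to the "not more effective" /
# "not costlier" side so that counts are exhaustive
ce_quadrant <- function(delta_cost, delta_qaly) {
  ifelse(delta_qaly > 0,
         ifelse(delta_cost > 0, "NE", "SE"),
         ifelse(delta_cost > 0, "NW", "SW"))
}

#' Combine per-patient QALYs and costs into CEA outcomes
#'
#' @param q Output of \code{\link{qaly_auc}}.
#' @param costs Data frame with columns \code{patient_id} and \code{cost}.
#' @param effect Which QALY summary to analyse: \code{"total_qaly"}
#'   (default; used for incremental analysis) or
#'   \code{"baseline_anchored_gain"}.
#' @return Data frame with columns \code{patient_id}, \code{arm},
#'   \code{cost}, \code{qaly}.
#' @export
ce_outcomes <- function(q, costs,
                        effect = c("total_qaly", "baseline_anchored_gain")) {
  effect <- match.arg(effect)
  out <- merge(q, costs[, c("patient_id", "cost")], by = "patient_id")
  data.frame(patient_id = out$patient_id, arm = out$arm,
             cost = out$cost, qaly = out[[effect]],
             stringsAsFactors = FALSE)
}

check_two_arms <- function(outcomes) {
  outcomes <- as.data.frame(outcomes)
  need <- c("patient_id", "arm", "cost", "qaly")
  miss <- setdiff(need, names(outcomes))
  if (length(miss))
    stop("outcomes lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (a in trial_arms)
    if (!any(outcomes$arm == a))
      stop("incremental analysis needs both arms; arm ", a, " is empty",
           call. = FALSE)
  if (any(outcomes$cost < 0)) stop("costs must be >= 0", call. = FALSE)
  outcomes
}

#' Incremental cost-effectiveness analysis
#'
#' Computes arm mean cost and QALYs, the incremental cost and QALYs
#' (PNE - DN), the ICER when defined, and the cost-effectiveness-plane
#' quadrant: NE costlier & more effective, SE cheaper & more effective
#' (PNE dominant), NW costlier & less effective (PNE dominated), SW cheaper
#' & less effective.
#'
#' @param outcomes Data frame with columns \code{patient_id}, \code{arm},
#'   \code{cost} (EUR) and \code{qaly}.
#' @return Object of class \code{ce_result}: arm means, \code{delta_cost},
#'   \code{delta_qaly}, \code{icer} (NA when \code{delta_qaly} is 0, flagged
#'   by \code{icer_defined}), \code{quadrant}, \code{dominance}.
#' @export
incremental_analysis <- function(outcomes) {
  outcomes <- check_two_arms(outcomes)
  mean_by <- function(col)
    vapply(trial_arms, function(a) mean(outcomes[[col]][outcomes$arm == a]), 0)
  mc <- mean_by("cost"); mq <- mean_by("qaly")
  dc <- unname(mc["PNE"] - mc["DN"]); dq <- unname(mq["PNE"] - mq["DN"])
  defined <- dq != 0
  structure(list(
    mean_cost = mc, mean_qaly = mq,
    delta_cost = dc, delta_qaly = dq,
    icer = if (defined) dc / dq else NA_real_,
    icer_defined = defined,
    quadrant = ce_quadrant(dc, dq),
    dominance = switch(ce_quadrant(dc, dq),
                       SE = "PNE dominant", NW = "PNE dominated",
                       "none"),
    n = table(outcomes$arm)
  ), class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat("Incremental analysis (PNE - DN)\n")
  cat(sprintf("  mean cost: DN %.2f, PNE %.2f  -> delta %.2f EUR\n",
              round_currency(x$mean_cost["DN"]),
              round_currency(x$mean_cost["PNE"]),
              round_currency(x$delta_cost)))
  cat(sprintf("  mean QALY: DN %.4f, PNE %.4f -> delta %.4f\n",
              x$mean_qaly["DN"], x$mean_qaly["PNE"], x$delta_qaly))
  if (x$icer_defined) {
    cat(sprintf("  ICER: %.2f EUR/QALY  [quadrant %s, %s]\n",
                x$icer, x$quadrant, x$dominance))
  } else {
    cat("  ICER undefined (delta QALY is zero)\n")
  }
  invisible(x)
}

#' Nonparametric bootstrap of cost-QALY pairs
#'
#' Each replicate resamples patients with replacement independently within
#' each arm (arm sizes fixed, preserving the randomization structure),
#' recomputes arm mean cost and mean QALY, and stores the incremental pair
#' (delta_cost, delta_qaly). Reproducible for a fixed seed; the caller's RNG
#' state is left untouched.
#'
#' @param outcomes As for \code{\link{incremental_analysis}}.
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed, or NULL to draw from the current RNG stream.
#' @return Object of class \code{ce_bootstrap}: \code{pairs} (data frame of
#'   \code{delta_cost}, \code{delta_qaly}), \code{n_reps}, \code{seed},
#'   \code{point} (the non-resampled \code{ce_result}).
#' @export
bootstrap_ce <- function(outcomes, n_reps = 1000L, seed = NULL) {
  outcomes <- check_two_arms(outcomes)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  arm_mat <- function(a, col, idx) {
    v <- outcomes[[col]][outcomes$arm == a]
    colMeans(matrix(v[idx], nrow = sum(outcomes$arm == a)))
  }
  pairs <- with_local_seed(seed, {
    idx <- lapply(trial_arms, function(a) {
      n <- sum(outcomes$arm == a)
      matrix(sample.int(n, n * n_reps, replace = TRUE), nrow = n)
    })
    names(idx) <- trial_arms
    data.frame(
      delta_cost = arm_mat("PNE", "cost", idx$PNE) -
                   arm_mat("DN", "cost", idx$DN),
      delta_qaly = arm_mat("PNE", "qaly", idx$PNE) -
                   arm_mat("DN", "qaly", idx$DN))
  })
  structure(list(pairs = pairs, n_reps = as.integer(n_reps), seed = seed,
                 point = incremental_analysis(outcomes)),
            class = "ce_bootstrap")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold lambda, the probability that PNE is
#' cost-effective versus DN: the fraction of bootstrap pairs with strictly
#' positive incremental net benefit lambda * delta_qaly - delta_cost. At
#' lambda = 0 this is the fraction of cost-saving pairs; as lambda grows it
#' approaches the fraction of QALY-gaining pairs.
#'
#' @param cloud A \code{\link{bootstrap_ce}} result.
#' @param thresholds Non-negative lambda grid in EUR/QALY (default 0 to
#'   25000 in steps of 50 — 25000 EUR/QALY is the customary decision
#'   threshold).
#' @return Data frame with columns \code{threshold} and \code{probability}.
#' @export
ceac <- function(cloud, thresholds = seq(0, 25000, by = 50)) {
  stopifnot(inherits(cloud, "ce_bootstrap"))
  if (any(thresholds < 0))
    stop("willingness-to-pay thresholds must be >= 0", call. = FALSE)
  p <- vapply(thresholds, function(l)
    mean(l * cloud$pairs$delta_qaly - cloud$pairs$delta_cost > 0), 0)
  data.frame(threshold = thresholds, probability = p)
}

#' Bootstrap-averaged ICER
#'
#' Mean of the per-replicate ratios delta_cost / delta_qaly over the
#' replicates in the NE and SW quadrants (where the ratio is economically
#' interpretable), reported alongside the ratio-of-means ICER. Averaged
#' ICERs are numerically unstable when replicates have delta_qaly near 0; a
#' warning is issued when any contributing |delta_qaly| is very small.
#'
#' @param cloud A \code{\link{bootstrap_ce}} result.
#' @param eps |delta_qaly| below which a warning about instability fires.
#' @return List with \code{mean_icer}, \code{n_used} (replicates averaged),
#'   and \code{ratio_of_means} (the point-estimate ICER).
#' @export
mean_icer <- function(cloud, eps = 1e-4) {
  stopifnot(inherits(cloud, "ce_bootstrap"))
  dc <- cloud$pairs$delta_cost; dq <- cloud$pairs$delta_qaly
  keep <- (dc > 0 & dq > 0) | (dc < 0 & dq < 0)
  if (any(abs(dq[keep]) < eps))
    warning("averaged ICER is unstable: some replicates have |delta QALY| < ",
            eps, call. = FALSE)
  list(mean_icer = if (any(keep)) mean(dc[keep] / dq[keep]) else NA_real_,
       n_used = sum(keep),
       ratio_of_means = cloud$point$icer)
}

#' Cost-effectiveness plane export
#'
#' Plot-ready table of the bootstrap cloud with quadrant labels; quadrant
#' counts are exhaustive and sum to the number of replicates.
#'
#' @param cloud A \code{\link{bootstrap_ce}} result.
#' @return Data frame with columns \code{delta_qaly}, \code{delta_cost},
#'   \code{quadrant}; quadrant counts attached as
#'   \code{attr(, "quadrant_counts")}.
#' @export
ce_plane_export <- function(cloud) {
  stopifnot(inherits(cloud, "ce_bootstrap"))
  df <- data.frame(delta_qaly = cloud$pairs$delta_qaly,
                   delta_cost = cloud$pairs$delta_cost)
  df$quadrant <- ce_quadrant(df$delta_cost, df$delta_qaly)
  counts <- table(factor(df$quadrant, levels = c("NE", "SE", "NW", "SW")))
  attr(df, "quadrant_counts") <- counts
  df
}

#' Probability cost-effective by follow-up week
#'
#' For each requested follow-up week t, per-patient QALYs are recomputed on
#' the truncated horizon [0, t] (trapezoid, 52-weeks-per-year convention),
#' the within-arm bootstrap is re-run, and the CEAC probability at the given
#' threshold is reported. By default the full course cost is attributed at
#' every horizon ("full"); "accrued" scales the course cost by the fraction
#' of the 4 weekly sessions delivered by week t (identical to "full" at all
#' assessment weeks >= 4).
#'
#' @param cohort A complete (post-LOCF) cohort.
#' @param costs Data frame with columns \code{patient_id}, \code{arm},
#'   \code{cost} (full-course cost per patient).
#' @param weeks Follow-up weeks at which to evaluate; must be assessment
#'   weeks, baseline excluded. Default: all follow-up weeks in the cohort.
#' @param lambda Willingness-to-pay threshold (EUR/QALY, default 25000).
#' @param n_reps Bootstrap replicates per week (default 1000).
#' @param seed Base seed; week k uses seed + k so the per-week clouds are
#'   reproducible yet distinct.
#' @param cost_attribution \code{"full"} or \code{"accrued"}.
#' @param n_course_weeks Weeks over which sessions are delivered (4).
#' @return Data frame with columns \code{week}, \code{probability},
#'   \code{delta_qaly}, \code{delta_cost}.
#' @export
prob_ce_series <- function(cohort, costs, weeks = NULL, lambda = 25000,
                           n_reps = 1000L, seed = NULL,
                           cost_attribution = c("full", "accrued"),
                           n_course_weeks = 4) {
  cohort <- as_cohort(cohort)
  cost_attribution <- match.arg(cost_attribution)
  grid <- sort(unique(cohort$week))
  if (is.null(weeks)) weeks <- grid[grid > 0]
  if (any(!(weeks %in% grid)) || any(weeks == 0))
    stop("weeks must be follow-up assessment weeks (baseline excluded)",
         call. = FALSE)
  rows <- lapply(seq_along(weeks), function(k) {
    t <- weeks[k]
    sub <- cohort[cohort$week <= t, , drop = FALSE]
    q <- qaly_auc(sub, horizon_weeks = t)
    cst <- costs
    if (cost_attribution == "accrued")
      cst$cost <- cst$cost * min(t, n_course_weeks) / n_course_weeks
    out <- ce_outcomes(q, cst)
    cloud <- bootstrap_ce(out, n_reps = n_reps,
                          seed = if (is.null(seed)) NULL else seed + k)
    data.frame(week = t,
               probability = ceac(cloud, lambda)$probability,
               delta_qaly = cloud$point$delta_qaly,
               delta_cost = cloud$point$delta_cost)
  })
  do.call(rbind, rows)
}
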