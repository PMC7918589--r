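# End-to-end analysis driver: costing + QALY + incremental analysis +
# bootstrap + CEAC + per-week series + overhead sensitivity, with run
# metadata (seed, configuration hash) and optional CSV/figure output.

#' Run the full cost-utility analysis
#'
#' Pipeline: (1) LOCF imputation with audited intention-to-treat exclusions,
#' (2) per-arm cost table under both equipment paths, (3) group quality-of-
#' life table, (4) per-patient QALYs and the point incremental result,
#' (5) bootstrap cloud and CEAC, (6) probability-cost-effective by follow-up
#' week, (7) overhead sensitivity re-analysis (all direct costs uplifted by
#' the model's overhead fraction; the QALY delta is untouched, the cost
#' delta scales by exactly 1 + fraction). Deterministic for a fixed seed.
#'
#' @param cohort A cohort data frame (raw; imputation happens here).
#' @param model A \code{\link{cost_model}}.
#' @param n_reps Bootstrap replicates (default 1000).
#' @param seed Integer seed for all resampling.
#' @param thresholds CEAC willingness-to-pay grid.
#' @param lambda Threshold for the per-week probability series.
#' @param pne_path PNE costing path, see \code{\link{arm_course_costs}}.
#' @param out_dir If non-NULL, CSV outputs and run metadata are written
#'   there (created if needed).
#' @param plots If TRUE (and \code{out_dir} is set), PNG figures of the
#'   quality-of-life curves, the cost-effectiveness plane and the CEAC are
#'   written as well.
#' @return List of class \code{cea_run} with elements \code{cost_table},
#'   \code{qol_table}, \code{outcomes}, \code{ce_result}, \code{cloud},
#'   \code{ceac}, \code{prob_by_week}, \code{overhead}, \code{meta}.
#' @export
run_full_analysis <- function(cohort, model = cost_model(),
                              n_reps = 1000L, seed = 1L,
                              thresholds = seq(0, 25000, by = 50),
                              lambda = 25000,
                              pne_path = "printed_increment",
                              out_dir = NULL, plots = FALSE) {
  cohort <- as_cohort(cohort)
  n_in <- length(unique(cohort$patient_id))
  imputed <- locf_impute(cohort)
  excluded <- attr(imputed, "excluded")
  message("cohort: ", n_in, " patients in, ",
          length(excluded), " excluded (missing baseline), ",
          n_in - length(excluded), " analysed")

  cc <- arm_course_costs(model, pne_path = pne_path)
  cost_table <- cost_table(model)
  qol <- group_mean_table(imputed)

  horizon <- max(imputed$week)
  q <- qaly_auc(imputed, horizon_weeks = horizon)
  costs <- data.frame(
    patient_id = unique(imputed$patient_id),
    stringsAsFactors = FALSE)
  arm_of <- imputed$arm[match(costs$patient_id, imputed$patient_id)]
  costs$arm <- arm_of
  costs$cost <- vapply(arm_of, function(a) cc[[a]]$course_total, 0)
  outcomes <- ce_outcomes(q, costs)

  ce <- incremental_analysis(outcomes)
  cloud <- bootstrap_ce(outcomes, n_reps = n_reps, seed = seed)
  ceac_df <- ceac(cloud, thresholds)
  grid <- sort(unique(imputed$week))
  prob_week <- prob_ce_series(imputed, costs, weeks = grid[grid > 0],
                              lambda = lambda, n_reps = n_reps,
                              seed = seed)

  # overhead sensitivity: direct costs x (1 + fraction), QALYs unchanged
  oh_outcomes <- outcomes
  oh_outcomes$cost <- vapply(oh_outcomes$cost, function(x)
    apply_overhead(x, model$overhead_fraction)$total, 0)
  oh_ce <- incremental_analysis(oh_outcomes)

  meta <- list(seed = seed, n_reps = n_reps,
               n_patients_in = n_in, excluded = as.list(excluded),
               pne_path = pne_path, lambda = lambda,
               overhead_fraction = model$overhead_fraction,
               config_hash = rlang::hash(list(model, n_reps, seed,
                                              thresholds, lambda, pne_path)))

  res <- structure(list(
    cost_table = cost_table, qol_table = qol, outcomes = outcomes,
    ce_result = ce, cloud = cloud, ceac = ceac_df,
    prob_by_week = prob_week,
    overhead = list(fraction = model$overhead_fraction, ce_result = oh_ce),
    meta = meta), class = "cea_run")

  if (!is.null(out_dir)) write_cea_run(res, out_dir, plots = plots)
  res
}

#' Per-arm cost table
#'
#' Tabulates the cost components and totals for both arms: unit costs, the
#' two formula-based equipment scenarios, first-week cost, course total and
#' the overhead-uplifted total. Costs are rounded to cents (reporting
#' boundary).
#'
#' @param model A \code{\link{cost_model}}.
#' @return Data frame with columns \code{item}, \code{DN}, \code{PNE}.
#' @export
cost_table <- function(model) {
  eq_study <- equipment_cost_per_session(
    model, amortization_scenario("study_sessions"))
  eq_clinic <- equipment_cost_per_session(
    model, amortization_scenario("clinic_amortized"))
  cc <- arm_course_costs(model, pne_path = "printed_increment")
  r <- round_currency
  data.frame(
    item = c("sanitary consumables (session)",
             "equipment price",
             "equipment per session (study sessions)",
             "equipment per session (clinic amortized)",
             "physiatrist (session)",
             "physiotherapy (session)",
             "first week of treatment",
             "course total (four sessions)",
             "course total with overhead"),
    DN = c(r(model$consumables_per_session), NA, NA, NA,
           r(model$physiatrist_per_session), r(model$physio_per_session),
           r(cc$DN$first_week_cost), r(cc$DN$course_total),
           r(cc$DN$course_total_with_overhead)),
    PNE = c(r(model$consumables_per_session), r(model$equipment_price),
            r(eq_study), r(eq_clinic),
            r(model$physiatrist_per_session), r(model$physio_per_session),
            r(cc$PNE$first_week_cost), r(cc$PNE$course_total),
            r(cc$PNE$course_total_with_overhead)))
}

round_df <- function(df, cost_cols = character(), util_cols = character()) {
  for (cl in intersect(cost_cols, names(df)))
    df[[cl]] <- round_currency(df[[cl]])
  for (cl in intersect(util_cols, names(df)))
    df[[cl]] <- round(df[[cl]], 3)
  df
}

#' Write an analysis run to disk
#'
#' Emits \code{cost_table.csv}, \code{qol_table.csv}, \code{ce_result.csv},
#' \code{bootstrap_pairs.csv}, \code{ceac.csv}, \code{prob_by_week.csv} and
#' \code{run_metadata.json}; with \code{plots = TRUE} also PNG figures.
#' Published-table analogues are rounded at write time only: costs to 2
#' decimals, utilities/QALYs to 3.
#'
#' @param res A \code{cea_run}.
#' @param out_dir Output directory.
#' @param plots Write PNG figures too?
#' @return \code{out_dir}, invisibly.
#' @export
write_cea_run <- function(res, out_dir, plots = FALSE) {
  stopifnot(inherits(res, "cea_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                        row.names = FALSE, na = "")
  w(res$cost_table, "cost_table.csv")
  w(round_df(res$qol_table,
             util_cols = c("dn_mean", "dn_sd", "dn_change", "pne_mean",
                           "pne_sd", "pne_change", "diff", "diff_sd")),
    "qol_table.csv")
  ce <- res$ce_result; oh <- res$overhead$ce_result
  w(data.frame(
    analysis = c("direct", "with_overhead"),
    delta_cost = round_currency(c(ce$delta_cost, oh$delta_cost)),
    delta_qaly = round(c(ce$delta_qaly, oh$delta_qaly), 3),
    icer = round_currency(c(ce$icer, oh$icer)),
    quadrant = c(ce$quadrant, oh$quadrant),
    dominance = c(ce$dominance, oh$dominance)), "ce_result.csv")
  w(round_df(ce_plane_export(res$cloud), cost_cols = "delta_cost",
             util_cols = "delta_qaly"), "bootstrap_pairs.csv")
  w(res$ceac, "ceac.csv")
  w(round_df(res$prob_by_week, cost_cols = "delta_cost",
             util_cols = "delta_qaly"), "prob_by_week.csv")
  jsonlite::write_json(res$meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (plots) {
    save_plot <- function(p, f)
      ggplot2::ggsave(file.path(out_dir, f), p, width = 6, height = 4,
                      dpi = 150)
    save_plot(plot_qol(res$qol_table), "qol_curves.png")
    save_plot(plot_ce_plane(res$cloud), "ce_plane.png")
    save_plot(plot_ceac(res$ceac), "ceac.png")
  }
  invisible(out_dir)
}

#' @export
print.cea_run <- function(x, ...) {
  cat("Cost-utility analysis run (seed ", x$meta$seed, ", ",
      x$cloud$n_reps, " bootstrap reps)\n\n", sep = "")
  print(x$ce_result)
  cat(sprintf("\nWith %.0f%% overhead uplift:\n",
              100 * x$overhead$fraction))
  print(x$overhead$ce_result)
  cat("\nProbability cost-effective by week (lambda = ",
      x$meta$lambda, "):\n", sep = "")
  print(round_df(x$prob_by_week, cost_cols = "delta_cost",
                 util_cols = "delta_qaly"), row.names = FALSE)
  invisible(x)
}

#' Quality-of-life curves by arm
#'
#' @param qol_table Output of \code{\link{group_mean_table}}.
#' @return A ggplot object.
#' @export
plot_qol <- function(qol_table) {
  long <- rbind(
    data.frame(week = qol_table$week, arm = "DN", mean = qol_table$dn_mean),
    data.frame(week = qol_table$week, arm = "PNE", mean = qol_table$pne_mean))
  ggplot2::ggplot(long, ggplot2::aes(.data$week, .data$mean,
                                     colour = .data$arm)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "week", y = "mean EQ-5D-5L utility index",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness plane
#'
#' @param cloud A \code{\link{bootstrap_ce}} result.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(cloud) {
  df <- ce_plane_export(cloud)
  ggplot2::ggplot(df, ggplot2::aes(.data$delta_qaly, .data$delta_cost,
                                   colour = .data$quadrant)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "incremental QALYs (PNE - DN)",
                  y = "incremental cost (EUR)", colour = "quadrant") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve
#'
#' @param ceac_df Output of \code{\link{ceac}}.
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_df) {
  ggplot2::ggplot(ceac_df, ggplot2::aes(.data$threshold,
                                        .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "willingness to pay (EUR/QALY)",
                  y = "P(PNE cost-effective)") +
    ggplot2::theme_minimal()
}
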