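# Reading trial CSVs and cost configuration files.
#
# Trial CSV (long format): columns patient_id, arm, week, then either the
# five EQ-5D-5L dimension levels mo,sc,ua,pd,ad (integers 1-5) or a
# precomputed utility column (float); an empty cell marks a missing
# assessment.

#' Read a trial cohort from CSV
#'
#' If the file carries dimension-level responses they are scored with the
#' supplied value set; if it carries a \code{utility} column the value set
#' is bypassed.
#'
#' @param path CSV path.
#' @param vs An \code{\link{value_set}}; required when the file has
#'   dimension columns and no \code{utility} column.
#' @return A cohort data frame (see \code{\link{as_cohort}}).
#' @export
read_trial_csv <- function(path, vs = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "arm", "week") %in% names(df)))
    stop("trial CSV needs columns patient_id, arm, week", call. = FALSE)
  if (!"utility" %in% names(df)) {
    if (!all(eq5d_dimensions %in% names(df)))
      stop("trial CSV needs either a utility column or the five dimension ",
           "columns ", paste(eq5d_dimensions, collapse = ","), call. = FALSE)
    if (is.null(vs))
      stop("a value set is required to score dimension-level responses",
           call. = FALSE)
    has_state <- stats::complete.cases(df[, eq5d_dimensions])
    df$utility <- NA_real_
    if (any(has_state)) {
      codes <- do.call(health_state, as.list(df[has_state, eq5d_dimensions]))
      df$utility[has_state] <- apply_value_set(codes, vs)
    }
  }
  as_cohort(df[, c("patient_id", "arm", "week", "utility")])
}

#' Write a cohort to CSV
#'
#' Emits the same long-format dialect \code{\link{read_trial_csv}} reads
#' (utility column; missing assessments as empty cells).
#'
#' @param cohort A cohort data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_trial_csv <- function(cohort, path) {
  cohort <- as_cohort(cohort)
  utils::write.csv(cohort[, c("patient_id", "arm", "week", "utility")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cost configuration file
#'
#' YAML file whose keys mirror the arguments of \code{\link{cost_model}}
#' and, under \code{scenario:}, of \code{\link{amortization_scenario}}.
#' Unknown keys raise an error rather than being silently ignored.
#'
#' @param path YAML path.
#' @return List with \code{model} (a \code{cost_model}) and \code{scenario}
#'   (an \code{amortization_scenario}, or NULL if the file has none).
#' @export
read_cost_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  sc_cfg <- cfg$scenario
  cfg$scenario <- NULL
  known <- names(formals(cost_model))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown cost-config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  model <- do.call(cost_model, cfg)
  scenario <- NULL
  if (!is.null(sc_cfg)) {
    bad <- setdiff(names(sc_cfg), names(formals(amortization_scenario)))
    if (length(bad))
      stop("unknown scenario key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    scenario <- do.call(amortization_scenario, sc_cfg)
  }
  list(model = model, scenario = scenario)
}
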