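# Fixture builders shared across the suite. Everything is generated in code;
# nothing is read from disk except the bundled synthetic value set.

wk6 <- c(0, 4, 8, 12, 26, 52)

# long cohort from a named list of per-patient utility vectors; names like
# "DN1", "PNE2" give arm + id; NA marks a missing assessment
make_cohort <- function(trajectories, weeks = wk6) {
  rows <- lapply(names(trajectories), function(id) {
    arm <- if (startsWith(id, "PNE")) "PNE" else "DN"
    data.frame(patient_id = id, arm = arm, week = weeks,
               utility = trajectories[[id]], stringsAsFactors = FALSE)
  })
  as_cohort(do.call(rbind, rows))
}

# published arm-level utility means/SDs used as calibration constants
trial_means <- list(
  DN  = c(0.630, 0.777, 0.721, 0.641, 0.644, 0.660),
  PNE = c(0.669, 0.757, 0.737, 0.694, 0.722, 0.764))

# cohort of identical patients per arm pinned at the arm means
degenerate_cohort <- function(n_per_arm = 2) {
  tr <- c(
    stats::setNames(rep(list(trial_means$DN), n_per_arm),
                    paste0("DN", seq_len(n_per_arm))),
    stats::setNames(rep(list(trial_means$PNE), n_per_arm),
                    paste0("PNE", seq_len(n_per_arm))))
  make_cohort(tr)
}

# outcomes table straight from per-patient (cost, qaly) vectors
make_outcomes <- function(dn_cost, dn_qaly, pne_cost, pne_qaly) {
  data.frame(
    patient_id = c(paste0("DN", seq_along(dn_qaly)),
                   paste0("PNE", seq_along(pne_qaly))),
    arm = c(rep("DN", length(dn_qaly)), rep("PNE", length(pne_qaly))),
    cost = c(dn_cost, pne_cost),
    qaly = c(dn_qaly, pne_qaly), stringsAsFactors = FALSE)
}

# independent AUC oracle: piecewise-linear interpolation on a 0.1-week grid,
# integrated by summing thin trapezoids (never calls the package's AUC path)
dense_auc_oracle <- function(weeks, utilities, weeks_per_year = 52) {
  grid <- seq(min(weeks), max(weeks), by = 0.1)
  u <- stats::approx(weeks, utilities, xout = grid)$y
  sum(diff(grid) * (u[-length(u)] + u[-1]) / 2) / weeks_per_year
}

# hand-made bootstrap cloud for CEAC / plane tests
make_cloud <- function(delta_cost, delta_qaly) {
  structure(list(pairs = data.frame(delta_cost = delta_cost,
                                    delta_qaly = delta_qaly),
                 n_reps = length(delta_cost), seed = NULL, point = NULL),
            class = "ce_bootstrap")
}
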