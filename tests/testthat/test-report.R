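test_that("trial CSV round-trips, including missing assessments", {
  coh <- make_cohort(list(DN1 = c(0.6, 0.8, NA, NA, NA, NA),
                          PNE1 = c(0.5, NA, 0.7, 0.7, 0.9, 0.9)))
  f <- tempfile(fileext = ".csv")
  write_trial_csv(coh, f)
  back <- read_trial_csv(f)
  expect_equal(back$utility, coh$utility)
  expect_equal(back$observed, coh$observed)
})

test_that("dimension-level responses are scored through the value set", {
  vs <- synthetic_value_set()
  df <- data.frame(patient_id = rep(c("DN1", "PNE1"), each = 2),
                   arm = rep(c("DN", "PNE"), each = 2),
                   week = c(0, 4, 0, 4),
                   mo = c(1, 2, 1, NA), sc = c(1, 1, 1, NA),
                   ua = c(1, 1, 1, NA), pd = c(1, 3, 2, NA),
                   ad = c(1, 1, 1, NA))
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE, na = "")
  coh <- read_trial_csv(f, vs = vs)
  expect_equal(coh$utility[coh$patient_id == "DN1"],
               apply_value_set(c("11111", "21131"), vs))
  expect_true(is.na(coh$utility[coh$patient_id == "PNE1" & coh$week == 4]))
  expect_error(read_trial_csv(f), "value set is required")
})

test_that("cost configuration files build validated models", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("physio_per_session: 50.0",
               "overhead_fraction: 0.25",
               "scenario:",
               "  kind: clinic_amortized",
               "  uses_per_year: 1000"), f)
  cfg <- read_cost_config(f)
  expect_equal(cfg$model$physio_per_session, 50)
  expect_equal(cfg$model$overhead_fraction, 0.25)
  expect_equal(cfg$scenario$kind, "clinic_amortized")
  writeLines("physio_cost: 50.0", f)
  expect_error(read_cost_config(f), "unknown cost-config key")
})

test_that("the full analysis is deterministic for a fixed seed", {
  g <- generate_cohort(cohort_spec(n_per_arm = 15), seed = 8)
  r1 <- suppressMessages(run_full_analysis(g$cohort, n_reps = 100, seed = 9))
  r2 <- suppressMessages(run_full_analysis(g$cohort, n_reps = 100, seed = 9))
  r1$meta$config_hash <- r2$meta$config_hash <- NULL
  expect_identical(r1[setdiff(names(r1), "meta")],
                   r2[setdiff(names(r2), "meta")])
  # and the written CSVs are byte-identical
  d1 <- file.path(tempdir(), "runA"); d2 <- file.path(tempdir(), "runB")
  write_cea_run(r1, d1); write_cea_run(r2, d2)
  for (f in c("ce_result.csv", "bootstrap_pairs.csv", "ceac.csv",
              "prob_by_week.csv", "qol_table.csv", "cost_table.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("overhead re-analysis rescales costs only", {
  g <- generate_cohort(cohort_spec(n_per_arm = 12), seed = 14)
  res <- suppressMessages(run_full_analysis(g$cohort, n_reps = 50, seed = 2))
  expect_equal(res$overhead$ce_result$delta_qaly, res$ce_result$delta_qaly)
  expect_equal(res$overhead$ce_result$delta_cost,
               1.30 * res$ce_result$delta_cost, tolerance = 1e-9)
})

test_that("identical arms yield an equipment-only cost delta and a flagged ICER", {
  u <- replicate(6, runif(6, 0.4, 0.9), simplify = FALSE)
  tr <- c(stats::setNames(u, paste0("DN", 1:6)),
          stats::setNames(u, paste0("PNE", 1:6)))
  res <- suppressMessages(
    run_full_analysis(make_cohort(tr), n_reps = 50, seed = 3))
  expect_equal(res$ce_result$delta_cost, 22.04)
  expect_equal(res$ce_result$delta_qaly, 0)
  expect_false(res$ce_result$icer_defined)
})

test_that("intention-to-treat exclusions are audited in the run metadata", {
  coh <- make_cohort(list(DN1 = c(NA, rep(0.7, 5)),
                          DN2 = rep(0.6, 6), DN3 = rep(0.65, 6),
                          PNE1 = rep(0.7, 6), PNE2 = rep(0.75, 6)))
  expect_warning(
    res <- suppressMessages(run_full_analysis(coh, n_reps = 20, seed = 1)),
    "missing baseline")
  expect_equal(res$meta$excluded, list("DN1"))
  expect_equal(nrow(res$outcomes), 4)
})

test_that("plot builders return ggplot objects", {
  g <- generate_cohort(cohort_spec(n_per_arm = 10), seed = 4)
  res <- suppressMessages(run_full_analysis(g$cohort, n_reps = 50, seed = 5))
  expect_s3_class(plot_qol(res$qol_table), "ggplot")
  expect_s3_class(plot_ce_plane(res$cloud), "ggplot")
  expect_s3_class(plot_ceac(res$ceac), "ggplot")
})
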