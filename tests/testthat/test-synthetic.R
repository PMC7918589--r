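calib_spec <- function(...) {
  cohort_spec(dropout_hazard = 0, truncate = FALSE, ...)
}

test_that("a degenerate spec reproduces the arm means exactly", {
  prof <- needlecea:::default_utility_profile()
  spec <- cohort_spec(n_per_arm = 3, sds = 0 * prof$sds,
                      dropout_hazard = 0)
  g <- generate_cohort(spec, seed = 1)
  tab <- group_mean_table(g$cohort)
  expect_equal(tab$dn_mean, unname(prof$means["DN", ]))
  expect_equal(tab$pne_mean, unname(prof$means["PNE", ]))
  expect_equal(tab$dn_sd, rep(0, 6))
})

test_that("generation is reproducible per seed and all-observed without dropout", {
  spec <- calib_spec()
  g1 <- generate_cohort(spec, seed = 42)
  g2 <- generate_cohort(spec, seed = 42)
  expect_identical(g1, g2)
  expect_false(anyNA(g1$cohort$utility))
  g3 <- generate_cohort(spec, seed = 43)
  expect_false(identical(g1$cohort$utility, g3$cohort$utility))
})

test_that("pre-truncation moments converge to the spec's means and SDs", {
  spec <- calib_spec(n_per_arm = 5000)
  g <- generate_cohort(spec, seed = 7)
  tab <- group_mean_table(g$cohort)
  prof <- needlecea:::default_utility_profile()
  expect_equal(tab$dn_mean, unname(prof$means["DN", ]), tolerance = 0.01)
  expect_equal(tab$pne_mean, unname(prof$means["PNE", ]), tolerance = 0.01)
  # total SD per cell is restored by the random-effect + occasion split
  expect_equal(tab$dn_sd, unname(prof$sds["DN", ]), tolerance = 0.02)
  expect_equal(tab$pne_sd, unname(prof$sds["PNE", ]), tolerance = 0.02)
})

test_that("dropout is monotone and roughly matches the hazard", {
  spec <- cohort_spec(n_per_arm = 400, dropout_hazard = 0.2)
  g <- generate_cohort(spec, seed = 3)
  by_pat <- split(!is.na(g$cohort$utility), g$cohort$patient_id)
  for (obs in by_pat) {
    expect_true(obs[1])  # baseline always observed
    if (any(!obs)) expect_true(all(!obs[which(!obs)[1]:length(obs)]))
  }
  miss_week4 <- mean(is.na(g$cohort$utility[g$cohort$week == 4]))
  expect_equal(miss_week4, 0.2, tolerance = 0.05)
})

test_that("generated utilities respect the floor and ceiling when truncated", {
  spec <- cohort_spec(n_per_arm = 300)
  g <- generate_cohort(spec, seed = 5)
  u <- g$cohort$utility[!is.na(g$cohort$utility)]
  expect_true(all(u <= 1 & u >= spec$utility_floor))
  expect_true(all(g$truncation_bias <= 0))  # clamping at 1 dominates here
})

test_that("infeasible variance decompositions are refused", {
  expect_error(cohort_spec(re_sd = c(DN = 0.5, PNE = 0.5)), "infeasible")
})

test_that("costs are deterministic per arm and taken from the cost model", {
  g <- generate_cohort(cohort_spec(n_per_arm = 4), seed = 1)
  expect_equal(unique(g$costs$cost[g$costs$arm == "DN"]), 178.86)
  expect_equal(unique(g$costs$cost[g$costs$arm == "PNE"]), 200.90)
})

test_that("analytic spec QALYs match the trapezoid on the mean curves", {
  truth <- spec_true_qaly(cohort_spec())
  expect_equal(unname(truth["DN"]), 34.481 / 52, tolerance = 1e-12)
  expect_equal(unname(truth["PNE"]), 37.932 / 52, tolerance = 1e-12)
})

test_that("recovery experiment is unbiased under a symmetric null", {
  prof <- needlecea:::default_utility_profile()
  null_means <- prof$means; null_means["PNE", ] <- null_means["DN", ]
  null_sds <- prof$sds; null_sds["PNE", ] <- null_sds["DN", ]
  m <- cost_model(pne_course_increment = 0)
  spec <- calib_spec(means = null_means, sds = null_sds, model = m,
                     n_per_arm = 30)
  r <- recovery_experiment(spec, n_sims = 40, reps_per_sim = 200,
                           lambda = 25000, seed = 11)
  expect_equal(r$true_delta_qaly, 0)
  expect_lt(abs(r$bias), 0.03)
  expect_gt(mean(r$ceac_prob), 0.35)
  expect_lt(mean(r$ceac_prob), 0.65)
  expect_error(recovery_experiment(spec, n_sims = 1), ">= 2")
})

test_that("a dominant configuration drives the CEAC probability to 1", {
  prof <- needlecea:::default_utility_profile()
  dom_means <- prof$means; dom_means["PNE", ] <- dom_means["DN", ] + 0.25
  m <- cost_model(pne_course_increment = 0)  # PNE no costlier
  spec <- calib_spec(means = dom_means, model = m, n_per_arm = 40)
  r <- recovery_experiment(spec, n_sims = 10, reps_per_sim = 200, seed = 13)
  expect_true(all(r$ceac_prob > 0.99))
})
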