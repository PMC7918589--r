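test_that("incremental analysis reproduces the overhead ICER arithmetic", {
  # degenerate one-patient arms at the overhead-uplifted course totals with
  # a QALY gap of 0.054
  out <- make_outcomes(232.52, 0.600, 261.17, 0.654)
  ce <- incremental_analysis(out)
  expect_equal(ce$delta_cost, 28.65)
  expect_equal(ce$delta_qaly, 0.054)
  expect_equal(ce$icer, 28.65 / 0.054, tolerance = 1e-12)  # 530.56
  expect_equal(ce$quadrant, "NE")
})

test_that("dominance and undefined-ICER cases are classified", {
  dominant <- incremental_analysis(make_outcomes(100, 0.5, 95, 0.55))
  expect_equal(dominant$quadrant, "SE")
  expect_equal(dominant$dominance, "PNE dominant")
  dominated <- incremental_analysis(make_outcomes(100, 0.5, 120, 0.45))
  expect_equal(dominated$dominance, "PNE dominated")
  tied <- incremental_analysis(make_outcomes(100, 0.5, 120, 0.5))
  expect_false(tied$icer_defined)
  expect_true(is.na(tied$icer))
  single_arm <- make_outcomes(100, 0.5, 120, 0.6)
  expect_error(incremental_analysis(single_arm[single_arm$arm == "DN", ]),
               "both arms")
})

test_that("bootstrap is seed-reproducible and respects arm structure", {
  set.seed(99)
  out <- make_outcomes(rep(178.86, 20), runif(20, 0.3, 0.9),
                       rep(200.90, 20), runif(20, 0.4, 1.0))
  c1 <- bootstrap_ce(out, n_reps = 500, seed = 7)
  c2 <- bootstrap_ce(out, n_reps = 500, seed = 7)
  expect_identical(c1$pairs, c2$pairs)
  expect_equal(nrow(c1$pairs), 500)
  # arm costs are constant within arm, so every replicate's delta cost must
  # equal the between-arm difference: resampling never mixes arms
  expect_true(all(c1$pairs$delta_cost == 200.90 - 178.86))
  expect_error(bootstrap_ce(out, n_reps = 0), ">= 1")
})

test_that("zero-variance cohorts bootstrap to the point estimate", {
  out <- make_outcomes(rep(100, 5), rep(0.6, 5), rep(120, 5), rep(0.7, 5))
  cloud <- bootstrap_ce(out, n_reps = 100, seed = 1)
  expect_true(all(cloud$pairs$delta_cost == 20))
  expect_true(all(abs(cloud$pairs$delta_qaly - 0.1) < 1e-12))
})

test_that("bootstrap means converge to the point estimate (law of large numbers)", {
  set.seed(5)
  out <- make_outcomes(rep(178.86, 30), rnorm(30, 0.6, 0.2),
                       rep(200.90, 30), rnorm(30, 0.7, 0.2))
  cloud <- bootstrap_ce(out, n_reps = 50000, seed = 2)
  point <- incremental_analysis(out)
  mc_se <- sd(cloud$pairs$delta_qaly) / sqrt(cloud$n_reps)
  expect_lt(abs(mean(cloud$pairs$delta_qaly) - point$delta_qaly), 3 * mc_se)
})

test_that("CEAC follows the strict net-benefit rule, ties counting against", {
  cloud <- make_cloud(rep(10, 4), rep(0.1, 4))
  expect_equal(ceac(cloud, c(50, 100, 200))$probability, c(0, 0, 1))
  expect_error(ceac(cloud, -10), ">= 0")
})

test_that("a half-dominant half-dominated cloud sits at 0.5 for any positive threshold", {
  cloud <- make_cloud(c(rep(-5, 50), rep(5, 50)),
                      c(rep(0.1, 50), rep(-0.1, 50)))
  p <- ceac(cloud, c(1, 100, 5000, 25000))$probability
  expect_equal(p, rep(0.5, 4))
})

test_that("CEAC limits equal the quadrant fractions on random clouds", {
  set.seed(21)
  for (i in 1:5) {
    cloud <- make_cloud(rnorm(400, 10, 30), rnorm(400, 0.02, 0.05))
    p0 <- ceac(cloud, 0)$probability
    expect_equal(p0, mean(cloud$pairs$delta_cost < 0))
    # beyond every pair's |delta_cost/delta_qaly| the net benefit's sign is
    # the sign of delta_qaly (including cost-saving QALY-losing pairs)
    big <- 10 * max(abs(cloud$pairs$delta_cost / cloud$pairs$delta_qaly))
    p_inf <- ceac(cloud, big)$probability
    expect_equal(p_inf, mean(cloud$pairs$delta_qaly > 0))
  }
})

test_that("CE-plane export conserves and labels all replicates", {
  set.seed(31)
  cloud <- make_cloud(rnorm(1000, 5, 30), rnorm(1000, 0.01, 0.05))
  df <- ce_plane_export(cloud)
  counts <- attr(df, "quadrant_counts")
  expect_equal(sum(counts), 1000)
  # independent recount straight from the signs
  dc <- cloud$pairs$delta_cost; dq <- cloud$pairs$delta_qaly
  expect_equal(unname(counts["NE"]), sum(dc > 0 & dq > 0))
  expect_equal(unname(counts["SE"]), sum(dc <= 0 & dq > 0))
  expect_equal(unname(counts["NW"]), sum(dc > 0 & dq <= 0))
  expect_equal(unname(counts["SW"]), sum(dc <= 0 & dq <= 0))
  all_dom <- ce_plane_export(make_cloud(rep(-1, 10), rep(0.1, 10)))
  expect_true(all(all_dom$quadrant == "SE"))
})

test_that("averaged ICER uses only the interpretable quadrants", {
  cloud <- make_cloud(c(10, 20, -10, -5), c(0.1, 0.2, 0.1, -0.05))
  # NE: (10, .1), (20, .2); SW: (-5, -.05); SE (-10, .1) excluded
  mi <- suppressWarnings(mean_icer(cloud))
  expect_equal(mi$n_used, 3)
  expect_equal(mi$mean_icer, mean(c(100, 100, 100)))
})

test_that("per-week probability series honours dominance, symmetry and the grid", {
  # PNE strictly dominant: higher utility everywhere, lower cost
  coh <- make_cohort(list(DN1 = rep(0.5, 6), DN2 = rep(0.5, 6),
                          PNE1 = rep(0.8, 6), PNE2 = rep(0.8, 6)))
  costs <- data.frame(patient_id = c("DN1", "DN2", "PNE1", "PNE2"),
                      arm = c("DN", "DN", "PNE", "PNE"),
                      cost = c(200, 200, 150, 150))
  ser <- prob_ce_series(coh, costs, n_reps = 50, seed = 1)
  expect_equal(ser$probability, rep(1, 5))
  # identical arms hover near 0.5
  set.seed(41)
  u <- replicate(20, runif(6, 0.3, 0.9), simplify = FALSE)
  tr <- c(stats::setNames(u[1:10], paste0("DN", 1:10)),
          stats::setNames(u[1:10], paste0("PNE", 1:10)))
  coh2 <- make_cohort(tr)
  costs2 <- data.frame(patient_id = names(tr),
                       arm = rep(c("DN", "PNE"), each = 10),
                       cost = 178.86)
  ser2 <- prob_ce_series(coh2, costs2, weeks = 52, lambda = 25000,
                         n_reps = 2000, seed = 2)
  expect_gt(ser2$probability, 0.3)
  expect_lt(ser2$probability, 0.7)
  expect_error(prob_ce_series(coh, costs, weeks = 5), "assessment")
  expect_error(prob_ce_series(coh, costs, weeks = 0), "assessment")
})
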