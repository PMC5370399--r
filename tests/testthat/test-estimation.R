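test_that("sensitivity intersection hits grid nodes exactly", {
  grid <- seq(0, 20, length.out = 21)
  target_node <- 6
  clr_node <- ss_clr(80, oatp_clint = grid[target_node])
  est <- estimate_clint_by_sensitivity(clr_node, 80, clint_grid = grid)
  expect_equal(est, grid[target_node], tolerance = 1e-6)
})

test_that("sensitivity intersection agrees with direct bisection", {
  for (obs in c(100, 136.1, 180)) {
    est <- estimate_clint_by_sensitivity(obs, 80)
    oracle <- uniroot(function(ci) ss_clr(80, oatp_clint = ci) - obs,
                      c(0, 20), tol = 1e-9)$root
    expect_equal(est, oracle, tolerance = 0.005)
  }
})

test_that("estimator recovers the generating CL_int,T from simulated CL_R", {
  set.seed(909)
  for (truth in runif(10, 0.2, 18)) {
    clr <- ss_clr(80, oatp_clint = truth)
    est <- estimate_clint_by_sensitivity(clr, 80)
    expect_equal(est, truth, tolerance = 0.005)
  }
})

test_that("observed CL_R outside the simulated range raises a no-crossing error", {
  expect_error(estimate_clint_by_sensitivity(10, 80), "no crossing")
  expect_error(estimate_clint_by_sensitivity(5000, 80), "no crossing")
})

test_that("the creatinine band widens the estimate about twofold", {
  band <- creatinine_sensitivity_band(136.1)
  expect_equal(band$ratio, 2, tolerance = 0.25)
  # degenerate band collapses to a single estimate
  same <- creatinine_sensitivity_band(136.1, scr_low = 80, scr_high = 80)
  expect_equal(same$estimate_low, same$estimate_high)
  # widening the band never shrinks the estimate interval
  wider <- creatinine_sensitivity_band(136.1, scr_low = 50, scr_high = 130)
  expect_lte(wider$estimate_low, band$estimate_low + 1e-9)
  expect_gte(wider$estimate_high, band$estimate_high - 1e-9)
})

test_that("the simulated CL_R surface is monotone in both axes", {
  surf <- clr_surface(clint_grid = seq(0, 20, length.out = 6),
                      scr_grid = exp(seq(log(40), log(800), length.out = 6)))
  expect_true(all(apply(surf$clr, 2, function(col) all(diff(col) > 0))))
  expect_true(all(apply(surf$clr, 1, function(row) all(diff(row) <= 1e-9))))
})

test_that("profile fitting recovers the truth and honours the zero boundary", {
  design0 <- synthetic_study_design(prop_sd = 0, seed = 5)
  # same output grid the generator simulated on
  reg <- dosing_regimen(design0$dose_mg, design0$infusion_min,
                        t_end = max(design0$plasma_times,
                                    design0$urine_intervals) * 1.05)
  ds <- gen_clinical_dataset(design0, ref_cmp(oatp_clint = 4.14))
  fit <- fit_clint_to_profile(ds$plasma, ref_sub(), reg)
  expect_true(fit$converged)
  expect_equal(fit$estimate, 4.14, tolerance = 0.01)
  ds0 <- gen_clinical_dataset(design0, ref_cmp(oatp_clint = 0))
  fit0 <- fit_clint_to_profile(ds0$plasma, ref_sub(), reg)
  expect_identical(fit0$estimate, 0)
  expect_true(fit0$at_boundary)
  expect_error(fit_clint_to_profile(ds$plasma[1:3, ], ref_sub(), reg),
               "at least 4")
})

test_that("profile-fit error grows with residual noise and stays bounded", {
  reg <- dosing_regimen(0.75, 30, t_end = 1512, n_times = 61)
  err_at <- function(sd, seeds) {
    vapply(seeds, function(s) {
      ds <- gen_clinical_dataset(synthetic_study_design(prop_sd = sd,
                                                        seed = s),
                                 ref_cmp(oatp_clint = 4.14))
      abs(fit_clint_to_profile(ds$plasma, ref_sub(), reg,
                               tol = 1e-3)$estimate - 4.14)
    }, numeric(1))
  }
  # residual on a mean profile of n = 12 subjects: between-subject CV
  # shrinks by sqrt(n)
  n_sub <- 12
  e0 <- median(err_at(0, 1))
  e5 <- median(err_at(0.05 / sqrt(n_sub), 1:7))
  e15 <- median(err_at(0.15 / sqrt(n_sub), 1:20))
  expect_lt(e0, e5)
  expect_lt(e5, e15)
  # median recovery within 25% at 15% between-subject noise
  expect_lt(e15 / 4.14, 0.25)
})

test_that("subject-weighted pooling matches the nine-study table", {
  vals <- c(8.20, 1.10, 0, 0.09, 5.56, 3.30, 0, 0, 0)
  wts <- c(12, 12, 12, 8, 8, 8, 9, 9, 9)
  wm <- weighted_mean_sd(vals, wts)
  # direct subject-weighted mean of the printed per-study fits
  expect_equal(wm$mean, 2.106, tolerance = 0.001)
  expect_equal(weighted_mean_sd(c(2, 4), c(1, 1))$mean, 3)
  expect_equal(weighted_mean_sd(5, 3)$mean, 5)
  expect_identical(weighted_mean_sd(5, 3)$sd, 0)
  expect_error(weighted_mean_sd(numeric(0), numeric(0)), "empty")
  expect_error(weighted_mean_sd(c(1, 2), 1))
})
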