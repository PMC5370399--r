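test_that("the scenario grid reproduces the printed rows", {
  g <- table_scenario_grid()
  p <- printed_scenario_grid
  expect_equal(g$gfr_norm, p$gfr)
  expect_true(all(abs(g$scr - p$scr) < ifelse(p$gfr >= 40, 0.2, 2)))
  expect_equal(round(g$oatp_factor, 2), p$oatp)
  expect_equal(round(g$ptcpgk, 1), p$ptcpgk)
  # PTCPGK and abundance share the same proportional factor exactly
  expect_equal(g$ptcpgk / 60, g$oatp_factor)
})

test_that("representative mechanism curves order as expected", {
  curves <- run_representative_curves()
  byg <- split(curves, curves$gfr_norm)
  at <- function(gfr, mech)
    curves$clr[curves$gfr_norm == gfr & curves$mechanism == mech]
  # no perturbation at baseline: all mechanisms coincide
  expect_equal(at(136.4, "GFR_only"), at(136.4, "GFR+OATP4C1"),
               tolerance = 1e-10)
  expect_equal(at(136.4, "GFR_only"), at(136.4, "GFR+PTCPGK"),
               tolerance = 1e-10)
  # coupled mechanisms fall below GFR-only once GFR is reduced
  for (gfr in c(100, 60, 20)) {
    expect_gt(at(gfr, "GFR_only"), at(gfr, "GFR+OATP4C1"))
    expect_gt(at(gfr, "GFR_only"), at(gfr, "GFR+PTCPGK"))
  }
  # PTCPGK scaling also removes reabsorption, so wherever cellularity is
  # reduced it sits at or above the OATP4C1 curve
  for (gfr in unique(curves$gfr_norm)[unique(curves$gfr_norm) <= 136.4])
    expect_gte(at(gfr, "GFR+PTCPGK"), at(gfr, "GFR+OATP4C1") - 1e-9)
})

test_that("pure-GFR scenarios preserve the tubular secretion machinery", {
  curves <- run_representative_curves("GFR_only")
  cmp <- ref_cmp()
  uptake <- secretion <- numeric(nrow(curves))
  for (k in seq_len(nrow(curves))) {
    sub <- reference_subject(scr = curves$scr[k])
    m <- build_kidney_model(cmp, sub)
    ss <- steady_state_clr(m)
    # OATP4C1-mediated secretory input (per unit plasma concentration)
    uptake[k] <- sum(m$go * m$fu_p * ss$c_peri)
    fr <- fraction_reabsorbed(m)
    secretion[k] <- curves$clr[k] - sub$fu_plasma * sub$gfr_abs * (1 - fr)
  }
  # the secretion machinery itself is untouched by a pure-GFR reduction --
  # the mechanistic reason GFR-only scenarios underpredict the clinical
  # CL_R decline
  expect_lt(diff(range(uptake)) / mean(uptake), 0.02)
  # net secretion reaching urine matches it at normal-to-mild impairment;
  # at low GFR part of the secreted drug is itself reabsorbed distally
  top <- curves$gfr_norm >= 100
  expect_lt(diff(range(secretion[top])) / mean(secretion[top]), 0.02)
  expect_lt(diff(range(secretion)) / mean(secretion), 0.25)
})

test_that("PTCPGK scaling dominates equal scaling of both transporters", {
  cmp <- ref_cmp()
  for (f in c(0.5, 0.25, 0.125)) {
    sub_t <- ref_sub(oatp_mult = f, pgp_mult = f)
    clr_t <- steady_state_clr(build_kidney_model(cmp, sub_t))$clr
    sub_p <- ref_sub()
    geo_p <- nephron_geometry(sub_p, ptcpgk_mult = f)
    clr_p <- steady_state_clr(build_kidney_model(cmp, sub_p, geo_p))$clr
    expect_gte(clr_p, clr_t)
  }
})

test_that("mechanism sweeps separate systemic and intracellular effects", {
  n <- 12
  reg <- quick_regimen()
  oatp <- run_mechanism_sweep("severe_RI", "OATP4C1", c(1, 0.125),
                              n = n, seed = 21, regimen = reg)
  ptc <- run_mechanism_sweep("severe_RI", "PTCPGK", c(1, 0.125),
                             n = n, seed = 21, regimen = reg)
  pgp <- run_mechanism_sweep("severe_RI", "PGP", c(1, 0.125),
                             n = n, seed = 21, regimen = reg)
  # shared seed pairs the arms: factor-1 rows are identical draws
  expect_equal(oatp$mean_clr[1], ptc$mean_clr[1])
  # reabsorption loss makes the PTCPGK route lose less CL_R
  expect_gt(ptc$clr_ratio[2], oatp$clr_ratio[2])
  # P-gp abundance: negligible for CL_R and AUC, strong for cell Cmax
  expect_equal(pgp$clr_ratio[2], pgp$clr_ratio[1], tolerance = 0.03)
  expect_equal(pgp$aucr[2], pgp$aucr[1], tolerance = 0.03)
  expect_gt(pgp$cmax_pt1_ratio[2], 2 * pgp$cmax_pt1_ratio[1])
  # proximal cell exposure tracks transporter abundance, not cell number
  expect_equal(ptc$cmax_pt1_ratio[2], ptc$cmax_pt1_ratio[1],
               tolerance = 0.10)
  expect_lt(oatp$cmax_pt1_ratio[2], 0.5 * oatp$cmax_pt1_ratio[1])
  expect_error(run_mechanism_sweep("severe_RI", "OATP4C1", c(1, 0)))
  expect_error(run_mechanism_sweep("severe_RI", "OATP4C1", 2))
})

test_that("population summaries report paired percent-of-healthy", {
  s <- population_summary("moderate_RI", n = 8, seed = 31,
                          regimen = quick_regimen())
  expect_true(is.finite(s$pct_clr_of_healthy))
  expect_lt(s$pct_clr_of_healthy, 100)
  expect_gt(s$pct_auc_of_healthy, 100)
  # a population compared with itself is its own control
  h <- population_summary("healthy", n = 8, seed = 31,
                          regimen = quick_regimen(),
                          include_control = TRUE)
  expect_equal(h$pct_clr_of_healthy, 100, tolerance = 1e-12)
})
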