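test_that("with all transport off, CL_R equals fu * GFR to machine precision", {
  sub <- ref_sub()
  cmp <- ref_cmp(cl_pd = 0, oatp_clint = 0, pgp_vmax = 0)
  ss <- steady_state_clr(build_kidney_model(cmp, sub))
  expect_equal(ss$clr, sub$fu_plasma * sub$gfr_abs, tolerance = 1e-12)
})

test_that("rate coefficients scale linearly with abundance and cellularity", {
  sub <- ref_sub()
  m1 <- build_kidney_model(ref_cmp(), sub)
  sub_h <- ref_sub(oatp_mult = 0.5)
  m2 <- build_kidney_model(ref_cmp(), sub_h)
  expect_equal(m2$go, 0.5 * m1$go)
  expect_equal(m2$pd, m1$pd)
  expect_equal(m2$vm, m1$vm)
  # doubling PTCPGK doubles every segment's cellularity and every scaled
  # clearance, including distal passive diffusion
  g2 <- nephron_geometry(sub, ptcpgk_mult = 2)
  m3 <- build_kidney_model(ref_cmp(), sub, g2)
  expect_equal(m3$N, 2 * m1$N)
  expect_equal(m3$pd, 2 * m1$pd)
  expect_equal(m3$go, 2 * m1$go)
  expect_equal(m3$vm, 2 * m1$vm)
})

test_that("passive reabsorption reproduces the calibrated baseline", {
  # filtration + reabsorption only: CL_R ~87.3 ml/min at the representative
  ss <- ss_clr(scr = 76.5, oatp_clint = 0, pgp_vmax = 0)
  expect_equal(ss, 87.3, tolerance = 0.05)
  # fraction reabsorbed 0.12 at CL_PD = 0.01 on every segment
  fr <- fraction_reabsorbed(build_kidney_model(ref_cmp(), ref_sub()))
  expect_equal(fr, 0.12, tolerance = 0.02 / 0.12)
  # no passive permeability, no reabsorption
  fr0 <- fraction_reabsorbed(build_kidney_model(ref_cmp(cl_pd = 0), ref_sub()))
  expect_equal(fr0, 0)
})

test_that("fraction reabsorbed increases monotonically with CL_PD", {
  grid <- c(0, 0.005, 0.01, 0.02, 0.05)
  fr <- vapply(grid, function(pd)
    fraction_reabsorbed(build_kidney_model(ref_cmp(cl_pd = pd), ref_sub())),
    numeric(1))
  expect_true(all(diff(fr) > 0))
})

test_that("steady-state CL_R reproduces the transporter anchor points", {
  expect_equal(ss_clr(80, oatp_clint = 4.14), 133.4, tolerance = 0.10)
  expect_equal(ss_clr(80, oatp_clint = 1.85), 108.8, tolerance = 0.10)
  expect_equal(ss_clr(80, oatp_clint = 0.23), 90.6, tolerance = 0.10)
  high <- ss_clr(80, oatp_clint = 270)
  expect_equal(high, 804.3, tolerance = 0.20)
  sub <- ref_sub(scr = 80)
  expect_lt(high, sub$renal_blood_flow * ref_cmp()$blood_plasma_ratio)
})

test_that("CL_R is nearly linear in CL_int,T at small values", {
  x <- c(0.23, 1.85, 4.14)
  y <- vapply(x, function(ci) ss_clr(80, oatp_clint = ci), numeric(1))
  fit <- lm(y ~ x)
  expect_lt(max(abs(residuals(fit)) / y), 0.05)
})

test_that("CL_R never exceeds renal blood flow x B:P (randomized sweep)", {
  set.seed(2071)
  for (i in 1:25) {
    cmp <- ref_cmp(oatp_clint = exp(runif(1, log(0.01), log(2000))),
                   cl_pd = runif(1, 0, 0.2),
                   pgp_ref = exp(runif(1, log(0.01), log(100))))
    sub <- ref_sub(scr = exp(runif(1, log(40), log(800))))
    ss <- steady_state_clr(build_kidney_model(cmp, sub))
    cap <- sub$renal_blood_flow * cmp$blood_plasma_ratio
    expect_lte(ss$clr, cap * (1 + 1e-9))
    expect_gte(ss$clr, 0)
  }
})

test_that("CL_R is insensitive to the kidney-cell unbound fraction", {
  clr <- vapply(c(0.2, 0.5, 1.0), function(fu)
    ss_clr(80, fu_kidney_cell = fu), numeric(1))
  expect_lt(diff(range(clr)) / mean(clr), 0.10)
})

test_that("a fivefold proximal CL_PD increase barely moves the severe-RI ratio", {
  cmp <- ref_cmp()
  healthy <- ref_sub()
  sev <- virtual_subject(scr = inverse_cockcroft_gault(22.5, 20, 81, "male",
                                                       1.98),
                         kidney_weight = 0.55 * healthy$kidney_weight,
                         fu_plasma = min(1, 1.1 * healthy$fu_plasma),
                         renal_blood_flow = 0.55 * healthy$renal_blood_flow,
                         hematocrit = 0.35)
  ratio_for <- function(pt_mult) {
    clr <- vapply(list(healthy, sev), function(s) {
      m <- build_kidney_model(cmp, s)
      m$pd[1:3] <- m$pd[1:3] * pt_mult
      steady_state_clr(m)$clr
    }, numeric(1))
    clr[2] / clr[1]
  }
  expect_equal(ratio_for(5), ratio_for(1), tolerance = 0.10)
})

test_that("sensitivity sweep shows the transporter contrast", {
  sub <- ref_sub(scr = 80)
  cmp <- ref_cmp()
  reg <- quick_regimen()
  oatp <- sensitivity_sweep(sub, cmp, "oatp_clint",
                            c(0.414, 1.3, 4.14, 13, 41.4), reg)
  expect_true(all(diff(oatp$clr) > 0))
  expect_true(all(diff(oatp$cmax_pt1) > 0))
  pgp <- sensitivity_sweep(sub, cmp, "pgp_ref", c(0.151, 1.51, 15.1), reg)
  expect_true(all(diff(pgp$cmax_pt1) < 0))
  # 100-fold P-gp sweep moves CL_R at least 10-fold less than a 100-fold
  # OATP4C1 sweep
  span <- function(x) diff(range(x)) / mean(x)
  span_oatp <- span(oatp$clr[c(1, 5)])
  expect_lt(span(pgp$clr), span_oatp / 10)
  expect_error(sensitivity_sweep(sub, cmp, "not_a_parameter", 1))
})

test_that("degenerate geometry is rejected", {
  sub <- ref_sub()
  expect_error(build_kidney_model(ref_cmp(), sub,
                                  nephron_geometry(sub, kappa_distal = -1)))
  expect_error(virtual_subject(renal_blood_flow = 50),
               NA) # low flow is a model-build error, not a subject error
  expect_error(build_kidney_model(
    ref_cmp(), virtual_subject(renal_blood_flow = 50)), "blood flow")
})
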