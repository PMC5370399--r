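# Shared fixtures: everything is generated in code at test time.

ref_sub <- function(...) reference_subject(...)
ref_cmp <- function(...) digoxin_compound(...)

# shorter horizon for dynamic runs in tests; CL_R (urine/AUC over the same
# window) is horizon-independent in the linear regime
quick_regimen <- function(dose_mg = 0.75, infusion_min = 30)
  dosing_regimen(dose_mg, infusion_min, t_end = 1440, n_times = 61)

# steady-state CL_R for a compound override at a given serum creatinine
ss_clr <- function(scr = 76.5, ...) {
  sub <- reference_subject(scr = scr)
  steady_state_clr(build_kidney_model(digoxin_compound(...), sub))$clr
}

# printed scenario grid (target GFR, serum creatinine, abundance factor,
# PTCPGK) used by physiology and scenario tests
printed_scenario_grid <- data.frame(
  gfr = c(136.4, 140, 120, 100, 80, 60, 40, 20, 15),
  scr = c(76.5, 74.5, 86.9, 104.3, 130.4, 173.9, 260.8, 521.7, 695.6),
  oatp = c(1, 1.03, 0.88, 0.73, 0.59, 0.44, 0.29, 0.15, 0.11),
  ptcpgk = c(60, 61.6, 52.8, 44.0, 35.2, 26.4, 17.6, 8.8, 6.6))
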