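# Renal-impairment and aging experiment engine: the proportional-scaling
# scenario grid, representative-subject mechanism curves, population
# mechanism sweeps and population exposure summaries.

#' Proportional renal-impairment scenario grid
#'
#' The nine-row scenario grid for the population representative: target
#' normalized GFR, the serum creatinine that produces it (inverse
#' Cockcroft-Gault), and OATP4C1-abundance / PTCPGK values scaled by the
#' relative change in GFR from the 136.4 ml/min/1.73 m^2 baseline.
#'
#' @param gfr_values normalized GFR grid, ml/min/1.73 m^2
#' @param baseline reference GFR for proportional scaling
#' @return data.frame with `gfr_norm`, `scr`, `oatp_factor`, `ptcpgk`
#' @export
table_scenario_grid <- function(gfr_values = c(136.4, 140, 120, 100, 80,
                                               60, 40, 20, 15),
                                baseline = 136.4) {
  stopifnot(all(gfr_values > 0))
  scr <- vapply(gfr_values, inverse_cockcroft_gault, numeric(1),
                age = REF_AGE, weight = REF_WEIGHT, sex = "male",
                bsa = REF_BSA)
  factor <- proportional_ri_scaling(gfr_values, baseline)
  data.frame(gfr_norm = gfr_values, scr = scr, oatp_factor = factor,
             ptcpgk = PTCPGK_REF * factor)
}

#' Representative-subject CL_R curves per mechanism
#'
#' Steady-state renal clearance of the population representative across
#' the scenario grid under three mechanisms: GFR reduction alone, GFR plus
#' proportional OATP4C1-abundance reduction, and GFR plus proportional
#' PTCPGK reduction.
#'
#' @param mechanisms subset of `c("GFR_only", "GFR+OATP4C1", "GFR+PTCPGK")`
#' @param grid scenario grid from [table_scenario_grid()]
#' @param compound an `"nk_compound"`
#' @return data.frame with `mechanism`, `gfr_norm`, `scr`, `clr`
#' @export
run_representative_curves <- function(mechanisms = c("GFR_only",
                                                     "GFR+OATP4C1",
                                                     "GFR+PTCPGK"),
                                      grid = table_scenario_grid(),
                                      compound = digoxin_compound()) {
  mechanisms <- match.arg(mechanisms, several.ok = TRUE)
  rows <- list()
  for (mech in mechanisms) {
    for (k in seq_len(nrow(grid))) {
      f <- grid$oatp_factor[k]
      sub <- reference_subject(
        scr = grid$scr[k],
        oatp_mult = if (mech == "GFR+OATP4C1") f else 1)
      geo <- nephron_geometry(
        sub, ptcpgk_mult = if (mech == "GFR+PTCPGK") f else 1)
      clr <- steady_state_clr(build_kidney_model(compound, sub, geo))$clr
      rows[[length(rows) + 1]] <- data.frame(
        mechanism = mech, gfr_norm = grid$gfr_norm[k], scr = grid$scr[k],
        clr = clr)
    }
  }
  do.call(rbind, rows)
}

# simulate every subject of a population data.frame; returns per-subject
# metrics (dynamic simulation of the given regimen)
simulate_population <- function(pop, compound = digoxin_compound(),
                                regimen = dosing_regimen(),
                                oatp_factor = 1, pgp_factor = 1,
                                ptcpgk_factor = 1) {
  out <- lapply(seq_len(nrow(pop)), function(i) {
    row <- pop[i, , drop = FALSE]
    sub <- subject_from_row(row)
    sub$oatp_mult <- sub$oatp_mult * oatp_factor
    sub$pgp_mult <- sub$pgp_mult * pgp_factor
    geo <- nephron_geometry(sub, ptcpgk_mult = ptcpgk_factor)
    sim <- simulate_iv(sub, compound, regimen, geometry = geo)
    c(clr = sim$clr, auc = sim$auc_0_inf, cmax_pt1 = sim$cmax_pt1,
      gfr_norm = row$gfr_norm)
  })
  as.data.frame(do.call(rbind, out))
}

#' Population exposure summary
#'
#' Simulates `n` virtual subjects of a population after a single
#' intravenous dose and reports mean renal clearance and exposure, with
#' percent-of-healthy columns computed against a paired healthy control
#' population (same `n`, seed offset shared across calls).
#'
#' @param label population label (see [population_spec()])
#' @param n number of subjects (default 100)
#' @param seed integer seed
#' @param regimen an `"nk_regimen"` (default 0.75 mg, 30-min infusion)
#' @param compound an `"nk_compound"`
#' @param include_control if `TRUE` (default) also simulate the healthy
#'   control arm and report ratios
#' @return list with `label`, `n`, `mean_clr`, `mean_auc`, `mean_cmax_pt1`,
#'   `mean_gfr_norm`, `per_subject` (data.frame) and, with a control arm,
#'   `pct_clr_of_healthy`, `pct_auc_of_healthy`, `control`
#' @export
population_summary <- function(label, n = 100, seed = 1L,
                               regimen = dosing_regimen(),
                               compound = digoxin_compound(),
                               include_control = (label != "healthy")) {
  pop <- sample_population(population_spec(label, seed = seed), n)
  per <- simulate_population(pop, compound, regimen)
  res <- list(label = label, n = n, seed = seed,
              mean_clr = mean(per$clr), mean_auc = mean(per$auc),
              mean_cmax_pt1 = mean(per$cmax_pt1),
              mean_gfr_norm = mean(per$gfr_norm), per_subject = per)
  if (include_control) {
    ctrl <- population_summary("healthy", n = n, seed = seed,
                               regimen = regimen, compound = compound,
                               include_control = FALSE)
    res$control <- ctrl
    res$pct_clr_of_healthy <- 100 * res$mean_clr / ctrl$mean_clr
    res$pct_auc_of_healthy <- 100 * res$mean_auc / ctrl$mean_auc
  }
  res
}

#' Mechanism sweep in a renal-impairment population
#'
#' For each abundance/cellularity factor, simulates `n` subjects of the
#' impaired population with the mechanism applied and `n` healthy controls
#' (paired demographic draws via a shared seed), and reports exposure,
#' renal-clearance and proximal-cell Cmax ratios versus healthy. The
#' `PTCPGK` mechanism rescales the cellularity of every tubular segment
#' (hence all transporter totals and all scaled passive clearances); the
#' transporter mechanisms rescale only the named transporter.
#'
#' @param label `"moderate_RI"` or `"severe_RI"` (any population label is
#'   accepted)
#' @param mechanism one of `"OATP4C1"`, `"PGP"`, `"PTCPGK"`
#' @param factors factor grid in (0, 1]
#' @param n subjects per arm (default 100)
#' @param seed integer seed (shared by both arms)
#' @param regimen an `"nk_regimen"`
#' @param compound an `"nk_compound"`
#' @return data.frame with one row per factor: `factor`, `mean_clr`,
#'   `mean_auc`, `mean_cmax_pt1`, `aucr`, `clr_ratio`, `cmax_pt1_ratio`,
#'   plus the control means as attributes
#' @export
run_mechanism_sweep <- function(label, mechanism = c("OATP4C1", "PGP",
                                                     "PTCPGK"),
                                factors = c(1, 0.75, 0.5, 0.25, 0.125),
                                n = 100, seed = 1L,
                                regimen = dosing_regimen(),
                                compound = digoxin_compound()) {
  mechanism <- match.arg(mechanism)
  if (any(factors <= 0)) stop("factors must be positive")
  if (any(factors > 1)) stop("factors must lie in (0, 1]")
  pop <- sample_population(population_spec(label, seed = seed), n)
  ctrl_pop <- sample_population(population_spec("healthy", seed = seed), n)
  ctrl <- simulate_population(ctrl_pop, compound, regimen)
  rows <- lapply(factors, function(f) {
    per <- simulate_population(
      pop, compound, regimen,
      oatp_factor = if (mechanism == "OATP4C1") f else 1,
      pgp_factor = if (mechanism == "PGP") f else 1,
      ptcpgk_factor = if (mechanism == "PTCPGK") f else 1)
    data.frame(factor = f,
               mean_clr = mean(per$clr), mean_auc = mean(per$auc),
               mean_cmax_pt1 = mean(per$cmax_pt1),
               aucr = auc_ratio(mean(per$auc), mean(ctrl$auc)),
               clr_ratio = auc_ratio(mean(per$clr), mean(ctrl$clr)),
               cmax_pt1_ratio = auc_ratio(mean(per$cmax_pt1),
                                          mean(ctrl$cmax_pt1)))
  })
  out <- do.call(rbind, rows)
  attr(out, "control_means") <- c(clr = mean(ctrl$clr), auc = mean(ctrl$auc),
                                  cmax_pt1 = mean(ctrl$cmax_pt1))
  attr(out, "mechanism") <- mechanism
  attr(out, "label") <- label
  out
}
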