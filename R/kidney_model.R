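# Mechanistic nephron model: mass balance over a peritubular plasma pool
# and seven tubular segments, each with a filtrate and a cell compartment.
#
# Internal units: amounts pmol, volumes ml, time min, concentrations
# pmol/ml (= nM). All clearances are canonicalized to ml/min at build time.

#' Assemble the kidney model rate structure
#'
#' Encodes, for each tubular segment i with `N_i` million cells:
#' apical passive flux `CL_PD * N_i * (fu_urine*C_filtrate - fu_cell*C_cell)`,
#' basolateral passive flux `CL_PD * N_i * (fu_plasma*C_peri - fu_cell*C_cell)`,
#' OATP4C1 uptake (proximal segments, blood to cell)
#' `CLint * REF * mult * N_i * fu_plasma * C_peri`, P-gp efflux (proximal
#' segments, cell to filtrate) `Vmax * REF * mult * N_i * Cu/(Km + Cu)` with
#' `Cu = fu_cell * C_cell`, plus filtrate convection: `GFR * fu_plasma`
#' entering PT1 and segment-to-segment flow per the geometry.
#'
#' Glomerular filtration is driven by arterial plasma; the basolateral and
#' OATP fluxes are driven by a well-stirred peritubular plasma pool with
#' plasma-equivalent flow `RBF * B:P - fu_plasma * GFR`, so renal clearance
#' can never exceed `RBF * B:P`.
#'
#' @param compound an `"nk_compound"` (see [digoxin_compound()])
#' @param subject an `"nk_subject"`
#' @param geometry an `"nk_geometry"`; default [nephron_geometry()] of the
#'   subject
#' @return object of class `"nk_kidney_model"`
#' @export
build_kidney_model <- function(compound, subject,
                               geometry = nephron_geometry(subject)) {
  stopifnot(inherits(compound, "nk_compound"), inherits(subject, "nk_subject"),
            inherits(geometry, "nk_geometry"))
  n_seg <- length(geometry$segments)
  if (n_seg != 7 || any(is.na(geometry$cells)) || any(geometry$cells <= 0))
    stop("geometry must provide positive cell counts for all 7 segments")
  is_pt <- geometry$segments %in% c("PT1", "PT2", "PT3")
  N <- geometry$cells                                   # million cells
  fu_p <- subject$fu_plasma
  # per-membrane passive diffusion, ml/min
  pd <- compound$cl_pd * subject$clpd_mult * geometry$sa_factor * N / 1000
  # OATP4C1 uptake coefficient, ml/min (proximal only)
  go <- ifelse(is_pt,
               compound$oatp_clint * compound$oatp_ref * subject$oatp_mult *
                 N / 1000, 0)
  # P-gp capacity pmol/min and Km in pmol/ml (proximal only)
  vm <- ifelse(is_pt,
               compound$pgp_vmax * compound$pgp_ref * subject$pgp_mult * N, 0)
  km <- compound$pgp_km * 1000
  gfr <- geometry$gfr_abs
  q_eff <- subject$renal_blood_flow * compound$blood_plasma_ratio
  if (q_eff <= fu_p * gfr)
    stop("renal blood flow too low for the requested GFR")
  m <- list(compound = compound, subject = subject, geometry = geometry,
            is_pt = is_pt, N = N, pd = pd, go = go, vm = vm, km = km,
            fu_p = fu_p, fu_u = compound$fu_urine,
            fu_c = compound$fu_kidney_cell,
            gfr = gfr, q_exit = unname(geometry$q_exit),
            q_peri = q_eff - fu_p * gfr, q_eff = q_eff)
  class(m) <- "nk_kidney_model"
  m
}

# Solve the linearized steady state for given P-gp conductances gp (ml/min).
# Unknowns x = [C_peri, Cc(7), Cf(7)]; arterial plasma concentration cp.
solve_linear_ss <- function(m, cp, gp) {
  A <- matrix(0, 15, 15)
  b <- numeric(15)
  fu_p <- m$fu_p; fu_u <- m$fu_u; fu_c <- m$fu_c
  # peritubular pool balance
  A[1, 1] <- m$q_peri + fu_p * sum(m$pd + m$go)
  A[1, 2:8] <- -m$pd * fu_c
  b[1] <- m$q_peri * cp
  for (i in 1:7) {
    rc <- 1 + i     # cell row
    rf <- 8 + i     # filtrate row
    out_c <- (2 * m$pd[i] + gp[i]) * fu_c
    if (out_c > 0) {
      A[rc, rc] <- out_c
      A[rc, 1] <- -(m$pd[i] + m$go[i]) * fu_p
      A[rc, rf] <- -m$pd[i] * fu_u
    } else {
      A[rc, rc] <- 1        # degenerate: no exchange, cell stays empty
    }
    A[rf, rf] <- m$q_exit[i] + m$pd[i] * fu_u
    A[rf, rc] <- A[rf, rc] - (m$pd[i] + gp[i]) * fu_c
    if (i == 1) b[rf] <- m$fu_p * m$gfr * cp
    else A[rf, 8 + i - 1] <- -m$q_exit[i - 1]
  }
  tryCatch(solve(A, b),
           error = function(e) stop("degenerate kidney geometry: ",
                                    conditionMessage(e)))
}

#' Steady-state renal clearance
#'
#' Solves the segment mass balances at a fixed arterial plasma
#' concentration. P-gp saturation is handled by damped fixed-point
#' iteration on the unbound cell concentration; in the linear range
#' (`Cu << Km`) the first iteration is already exact.
#'
#' @param model an `"nk_kidney_model"`
#' @param plasma_conc arterial plasma concentration, pmol/ml (the result is
#'   concentration-independent in the linear range)
#' @param tol relative convergence tolerance on unbound cell concentration
#' @return object of class `"nk_kidney_ss"`: list with `clr` (ml/min,
#'   plasma-referenced), `cl_filtration` (ml/min), `excretion_rate`
#'   (pmol/min), `c_peri`, `c_cell`, `c_filtrate` (pmol/ml), `c_cell_pt1`,
#'   `urine_flow`
#' @export
steady_state_clr <- function(model, plasma_conc = 1, tol = 1e-12) {
  stopifnot(inherits(model, "nk_kidney_model"), plasma_conc > 0)
  gp <- model$vm / model$km          # linear-range conductance
  x <- solve_linear_ss(model, plasma_conc, gp)
  for (iter in 1:50) {
    cu <- model$fu_c * x[2:8]
    gp_new <- model$vm / (model$km + pmax(cu, 0))
    x_new <- solve_linear_ss(model, plasma_conc, gp_new)
    delta <- max(abs(x_new - x) / pmax(abs(x), 1e-300))
    x <- x_new
    if (delta < tol) break
  }
  excretion <- model$q_exit[7] * x[15]
  res <- list(clr = excretion / plasma_conc,
              cl_filtration = model$fu_p * model$gfr,
              excretion_rate = excretion,
              c_peri = x[1],
              c_cell = setNames(x[2:8], model$geometry$segments),
              c_filtrate = setNames(x[9:15], model$geometry$segments),
              c_cell_pt1 = x[2],
              urine_flow = model$q_exit[7])
  class(res) <- "nk_kidney_ss"
  res
}

#' Fraction of filtered drug reabsorbed
#'
#' Solves the model with active transport disabled and returns
#' `F_reab = (CL_filtration - CL_R,passive) / CL_filtration`.
#'
#' @param model an `"nk_kidney_model"`
#' @return fraction in `[0, 1)`
#' @export
fraction_reabsorbed <- function(model) {
  m0 <- model
  m0$go[] <- 0
  m0$vm[] <- 0
  ss <- steady_state_clr(m0)
  1 - ss$clr / ss$cl_filtration
}

#' One-parameter sensitivity sweep
#'
#' Re-simulates the representative kidney model over a grid of values for
#' one parameter, everything else held fixed, and reports steady-state
#' renal clearance together with the dynamic exposure metrics (AUC and the
#' maximum cell concentration in the first proximal segment) for a 0.75 mg
#' 30-min intravenous infusion.
#'
#' @param subject an `"nk_subject"`
#' @param compound an `"nk_compound"`
#' @param parameter one of `"oatp_clint"`, `"pgp_ref"`, `"cl_pd"`,
#'   `"fu_kidney_cell"`, `"serum_creatinine"`
#' @param values numeric grid (positive; zero allowed for clearances)
#' @param regimen dosing regimen for the dynamic metrics; see
#'   [dosing_regimen()]
#' @param dynamic if `FALSE`, skip the ODE run (AUC and `cmax_pt1` are `NA`)
#' @return data.frame with `value`, `clr`, `auc`, `cmax_pt1`
#' @export
sensitivity_sweep <- function(subject, compound, parameter, values,
                              regimen = dosing_regimen(),
                              dynamic = TRUE) {
  parameter <- match.arg(parameter, c("oatp_clint", "pgp_ref", "cl_pd",
                                      "fu_kidney_cell", "serum_creatinine"))
  stopifnot(is.numeric(values), length(values) >= 1, all(values >= 0))
  out <- lapply(values, function(v) {
    cmp <- compound
    sub <- subject
    if (parameter == "serum_creatinine") {
      if (v <= 0) stop("serum creatinine must be positive")
      sub <- virtual_subject(age = subject$age, weight = subject$weight,
                             sex = subject$sex, bsa = subject$bsa, scr = v,
                             kidney_weight = subject$kidney_weight,
                             hematocrit = subject$hematocrit,
                             fu_plasma = subject$fu_plasma,
                             renal_blood_flow = subject$renal_blood_flow,
                             ptcpgk = subject$ptcpgk,
                             oatp_mult = subject$oatp_mult,
                             pgp_mult = subject$pgp_mult,
                             clpd_mult = subject$clpd_mult)
    } else {
      field <- switch(parameter, oatp_clint = "oatp_clint",
                      pgp_ref = "pgp_ref", cl_pd = "cl_pd",
                      fu_kidney_cell = "fu_kidney_cell")
      if (field == "fu_kidney_cell" && (v <= 0 || v > 1))
        stop("fu_kidney_cell values must lie in (0, 1]")
      args <- setNames(list(v), field)
      cmp <- do.call(digoxin_compound, modifyList(unclass(compound)[
        setdiff(names(unclass(compound)), "name")], args))
    }
    model <- build_kidney_model(cmp, sub)
    clr <- steady_state_clr(model)$clr
    if (dynamic) {
      sim <- simulate_iv(sub, cmp, regimen)
      c(clr = clr, auc = sim$auc_0_inf, cmax_pt1 = sim$cmax_pt1)
    } else c(clr = clr, auc = NA_real_, cmax_pt1 = NA_real_)
  })
  res <- do.call(rbind, out)
  data.frame(value = values, clr = res[, "clr"], auc = res[, "auc"],
             cmax_pt1 = res[, "cmax_pt1"])
}

#' @export
print.nk_kidney_ss <- function(x, ...) {
  cat(sprintf("<kidney steady state> CL_R %.1f ml/min (filtration %.1f); urine flow %.2f ml/min\n",
              x$clr, x$cl_filtration, x$urine_flow))
  invisible(x)
}
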