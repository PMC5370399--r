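# Estimation of the OATP4C1 intrinsic clearance from clinical summary
# data: (a) sensitivity-analysis intersection of the simulated CL_R
# surface with an observed mean CL_R, (b) least-squares fitting to a
# concentration-time profile, (c) subject-weighted pooling.

#' Simulated CL_R surface over CL_int,T and serum creatinine
#'
#' One steady-state solve per grid node for the population representative.
#'
#' @param clint_grid strictly increasing OATP4C1 CL_int,T grid,
#'   µl/min/million PTC (default 21 points over 0-20)
#' @param scr_grid strictly increasing serum creatinine grid, µmol/l
#'   (default 20 points over 40-800, log-spaced)
#' @param compound an `"nk_compound"`; its `oatp_clint` is swept
#' @param subject_fun function(scr) returning the representative subject at
#'   that serum creatinine (default [reference_subject()])
#' @return object of class `"nk_clr_surface"`: list with `clint_grid`,
#'   `scr_grid`, `clr` (matrix, rows = clint, cols = scr)
#' @export
clr_surface <- function(clint_grid = seq(0, 20, length.out = 21),
                        scr_grid = exp(seq(log(40), log(800),
                                           length.out = 20)),
                        compound = digoxin_compound(),
                        subject_fun = reference_subject) {
  stopifnot(all(diff(clint_grid) > 0), all(diff(scr_grid) > 0),
            all(clint_grid >= 0), all(scr_grid > 0))
  clr <- matrix(NA_real_, length(clint_grid), length(scr_grid))
  for (j in seq_along(scr_grid)) {
    sub <- subject_fun(scr = scr_grid[j])
    geo <- nephron_geometry(sub)
    for (i in seq_along(clint_grid)) {
      cmp <- compound
      cmp$oatp_clint <- clint_grid[i]
      clr[i, j] <- steady_state_clr(build_kidney_model(cmp, sub, geo))$clr
    }
  }
  s <- list(clint_grid = clint_grid, scr_grid = scr_grid, clr = clr)
  class(s) <- "nk_clr_surface"
  s
}

# CL_R as a monotone function of CL_int,T at fixed serum creatinine
clr_curve_at_scr <- function(scr, clint_grid, compound, subject_fun) {
  sub <- subject_fun(scr = scr)
  geo <- nephron_geometry(sub)
  vapply(clint_grid, function(ci) {
    cmp <- compound
    cmp$oatp_clint <- ci
    steady_state_clr(build_kidney_model(cmp, sub, geo))$clr
  }, numeric(1))
}

#' Estimate OATP4C1 CL_int,T by sensitivity-analysis intersection
#'
#' Simulates the CL_R(CL_int,T) curve for the population representative at
#' a fixed serum creatinine, interpolates it monotonically (Hyman-filtered
#' cubic) and returns the crossing point with the observed CL_R.
#'
#' @param observed_clr observed mean renal clearance, ml/min
#' @param serum_creatinine fixed serum creatinine, µmol/l (default 80)
#' @param clint_grid CL_int,T grid, µl/min/million PTC
#' @param compound an `"nk_compound"`
#' @param subject_fun representative constructor, `function(scr)`
#' @return estimated CL_int,T, µl/min/million PTC
#' @export
estimate_clint_by_sensitivity <- function(observed_clr, serum_creatinine = 80,
                                          clint_grid = seq(0, 20,
                                                           length.out = 21),
                                          compound = digoxin_compound(),
                                          subject_fun = reference_subject) {
  stopifnot(observed_clr > 0, serum_creatinine > 0, all(diff(clint_grid) > 0))
  clr <- clr_curve_at_scr(serum_creatinine, clint_grid, compound, subject_fun)
  if (observed_clr < min(clr) || observed_clr > max(clr))
    stop(sprintf(
      "no crossing: observed CL_R %.1f outside simulated range [%.1f, %.1f]",
      observed_clr, min(clr), max(clr)))
  f <- splinefun(clint_grid, clr, method = "hyman")
  uniroot(function(x) f(x) - observed_clr,
          range(clint_grid), tol = 1e-10)$root
}

#' Creatinine sensitivity band for the CL_int,T estimate
#'
#' Repeats the sensitivity-analysis estimation at the low and high ends of
#' a serum creatinine band and reports both estimates and their ratio.
#'
#' @param observed_clr observed mean renal clearance, ml/min
#' @param scr_low,scr_high serum creatinine band, µmol/l (defaults 54, 108)
#' @param ... passed to [estimate_clint_by_sensitivity()]
#' @return list with `estimate_low`, `estimate_high`, `ratio`
#' @export
creatinine_sensitivity_band <- function(observed_clr, scr_low = 54,
                                        scr_high = 108, ...) {
  stopifnot(scr_low > 0, scr_high >= scr_low)
  lo <- estimate_clint_by_sensitivity(observed_clr, scr_low, ...)
  hi <- estimate_clint_by_sensitivity(observed_clr, scr_high, ...)
  list(estimate_low = lo, estimate_high = hi,
       ratio = if (lo > 0) hi / lo else Inf)
}

#' Fit OATP4C1 CL_int,T to a plasma concentration-time dataset
#'
#' Bounded one-dimensional least squares on log concentrations
#' (multiplicative residual error). The boundary estimate 0 is permitted
#' and flagged, mirroring boundary fits seen with sparse mean profiles.
#'
#' @param dataset data.frame with columns `time_min` and `conc_ng_ml`
#'   (>= 4 rows, positive concentrations)
#' @param subject an `"nk_subject"`
#' @param regimen an `"nk_regimen"` describing the study dosing
#' @param compound an `"nk_compound"`; all parameters except `oatp_clint`
#'   (notably the P-gp parameters, which are practically nonidentifiable)
#'   stay fixed
#' @param bounds nonnegative search interval for CL_int,T
#' @param tol optimizer tolerance
#' @return object of class `"nk_fit"`: list with `estimate`, `objective`,
#'   `converged`, `at_boundary`, `n_obs`
#' @export
fit_clint_to_profile <- function(dataset, subject, regimen,
                                 compound = digoxin_compound(),
                                 bounds = c(0, 20), tol = 1e-4) {
  stopifnot(is.data.frame(dataset),
            all(c("time_min", "conc_ng_ml") %in% names(dataset)))
  if (nrow(dataset) < 4) stop("need at least 4 observations")
  if (any(dataset$conc_ng_ml <= 0)) stop("concentrations must be positive")
  if (any(bounds < 0) || bounds[2] <= bounds[1])
    stop("bounds must be nonnegative and increasing")
  obs_t <- dataset$time_min
  obs_logc <- log(dataset$conc_ng_ml)
  ssr <- function(clint) {
    cmp <- compound
    cmp$oatp_clint <- clint
    sim <- tryCatch(
      simulate_iv(subject, cmp, regimen),
      error = function(e) NULL)
    if (is.null(sim)) return(1e10)
    pred <- approx(sim$profile$time_min, sim$profile$conc_ng_ml,
                   xout = obs_t, rule = 2)$y
    if (any(pred <= 0)) return(1e10)
    sum((log(pred) - obs_logc)^2)
  }
  opt <- optimize(ssr, bounds, tol = tol)
  est <- opt$minimum
  o_lo <- ssr(bounds[1])
  # optimize() cannot return an exact endpoint; snap if the boundary is
  # at least as good
  if (o_lo <= opt$objective + 1e-12) {
    est <- bounds[1]
    opt$objective <- o_lo
  }
  res <- list(estimate = est, objective = opt$objective,
              converged = is.finite(opt$objective) && opt$objective < 1e10,
              at_boundary = est <= bounds[1] + 1e-9, n_obs = nrow(dataset))
  class(res) <- "nk_fit"
  res
}

#' @export
print.nk_fit <- function(x, ...) {
  cat(sprintf("<fit> CL_int,T = %.3f ul/min/M PTC (SSR %.4g%s)\n",
              x$estimate, x$objective,
              if (x$at_boundary) ", at boundary" else ""))
  invisible(x)
}

#' Subject-weighted mean and standard deviation
#'
#' `sum(w*x)/sum(w)` with the analogous weighted standard deviation, used
#' to pool per-study estimates by subject number.
#'
#' @param values numeric vector
#' @param weights positive weights (subject counts), same length
#' @return list with `mean` and `sd`
#' @export
weighted_mean_sd <- function(values, weights) {
  if (length(values) == 0) stop("empty input")
  if (length(values) != length(weights)) stop("lengths differ")
  if (any(weights <= 0)) stop("weights must be positive")
  m <- sum(weights * values) / sum(weights)
  v <- sum(weights * (values - m)^2) / sum(weights)
  list(mean = m, sd = sqrt(v))
}
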