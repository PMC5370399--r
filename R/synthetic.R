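# Synthetic clinical-study generators: every input the estimation and
# verification machinery needs is generated in code, with the ground
# truth embedded, so parameter-recovery tests close the loop without any
# external data.

#' Synthetic study design
#'
#' @param dose_mg intravenous dose, mg
#' @param infusion_min infusion duration, min (0 = bolus)
#' @param plasma_times plasma sampling times, min (increasing)
#' @param urine_intervals two-column matrix or data.frame of urine
#'   collection intervals (start, end), min
#' @param n_subjects nominal subject count (metadata; mean profiles are
#'   generated)
#' @param prop_sd multiplicative lognormal residual (sd of log
#'   observations; >= 0)
#' @param seed integer seed
#' @return object of class `"nk_design"`
#' @export
synthetic_study_design <- function(dose_mg = 0.75, infusion_min = 30,
                                   plasma_times = c(35, 45, 60, 90, 120,
                                                    180, 240, 360, 480, 720,
                                                    1080, 1440),
                                   urine_intervals = cbind(
                                     start = c(0, 240, 480, 960),
                                     end = c(240, 480, 960, 1440)),
                                   n_subjects = 12, prop_sd = 0.15,
                                   seed = 1L) {
  plasma_times <- as.numeric(plasma_times)
  if (is.unsorted(plasma_times, strictly = TRUE))
    stop("plasma sampling times must be strictly increasing")
  if (prop_sd < 0) stop("residual sd must be >= 0")
  ui <- as.matrix(urine_intervals)
  if (ncol(ui) != 2 || any(ui[, 2] <= ui[, 1]))
    stop("urine intervals must be (start, end) with end > start")
  d <- list(dose_mg = dose_mg, infusion_min = infusion_min,
            plasma_times = plasma_times, urine_intervals = ui,
            n_subjects = as.integer(n_subjects), prop_sd = prop_sd,
            seed = as.integer(seed))
  class(d) <- "nk_design"
  d
}

#' Generate a synthetic clinical dataset
#'
#' Simulates the coupled model at the true parameters and applies
#' multiplicative lognormal residual error per observation. Urine
#' observations are interval amounts (µg per collection interval).
#'
#' @param design an `"nk_design"`
#' @param true_compound an `"nk_compound"` holding the generating
#'   parameters (the embedded ground truth)
#' @param subject an `"nk_subject"`
#' @return list with `plasma` (data.frame `time_min`, `conc_ng_ml`),
#'   `urine` (data.frame `t_start`, `t_end`, `amount_ug`), `truth`
#'   (generating parameters and seed), `design`
#' @export
gen_clinical_dataset <- function(design, true_compound = digoxin_compound(),
                                 subject = reference_subject()) {
  stopifnot(inherits(design, "nk_design"))
  t_end <- max(design$plasma_times, design$urine_intervals) * 1.05
  regimen <- dosing_regimen(design$dose_mg, design$infusion_min,
                            t_end = t_end)
  sim <- simulate_iv(subject, true_compound, regimen)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(design$seed)
  conc <- approx(sim$profile$time_min, sim$profile$conc_ng_ml,
                 xout = design$plasma_times, rule = 2)$y
  conc_obs <- conc * exp(rnorm(length(conc), 0, design$prop_sd))
  cum_u <- approx(sim$profile$time_min, sim$profile$cum_urine_ug,
                  xout = as.vector(design$urine_intervals), rule = 2)$y
  k <- nrow(design$urine_intervals)
  amt <- cum_u[(k + 1):(2 * k)] - cum_u[1:k]
  amt_obs <- amt * exp(rnorm(k, 0, design$prop_sd))
  list(plasma = data.frame(time_min = design$plasma_times,
                           conc_ng_ml = conc_obs),
       urine = data.frame(t_start = design$urine_intervals[, 1],
                          t_end = design$urine_intervals[, 2],
                          amount_ug = amt_obs),
       truth = list(oatp_clint = true_compound$oatp_clint,
                    cl_pd = true_compound$cl_pd,
                    pgp_ref = true_compound$pgp_ref,
                    prop_sd = design$prop_sd, seed = design$seed),
       design = design)
}

#' Generate a study-level meta-analysis fixture
#'
#' Emulates a multi-study renal-clearance literature table: `k` studies
#' with subject counts summing to `n_total` and study-mean CL_R scattered
#' (lognormal) around a generating grand mean. The subject-weighted mean
#' of the fixture recovers the grand mean within Monte-Carlo error.
#'
#' @param k_studies number of studies (>= 1)
#' @param n_total total subjects across studies
#' @param grand_mean generating mean CL_R, ml/min
#' @param spread_cv lognormal CV of study means (0 for exact recovery)
#' @param seed integer seed
#' @return data.frame with `study`, `n`, `clr`
#' @export
gen_meta_analysis_fixture <- function(k_studies = 19, n_total = 214,
                                      grand_mean = 136.1, spread_cv = 0.15,
                                      seed = 1L) {
  if (k_studies < 1) stop("need at least one study")
  stopifnot(n_total >= k_studies, grand_mean > 0, spread_cv >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  # random composition of n_total into k positive counts
  extra <- if (n_total > k_studies)
    tabulate(sample.int(k_studies, n_total - k_studies, replace = TRUE),
             nbins = k_studies) else 0
  n <- rep(1L, k_studies) + extra
  clr <- grand_mean * rlnorm_cv(k_studies, spread_cv)
  data.frame(study = seq_len(k_studies), n = n, clr = clr)
}
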