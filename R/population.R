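#' Population specification
#'
#' Declares the study conditions for one virtual population. Healthy and
#' geriatric populations sample serum creatinine as the primitive quantity
#' (GFR derived by Cockcroft-Gault); renal-impairment populations sample
#' normalized GFR uniformly within their band (serum creatinine derived by
#' the inverse equation). Physiological modifiers (kidney weight, plasma
#' protein binding, hematocrit, renal blood flow) are fixed per population.
#'
#' @param label one of `"healthy"`, `"geriatric"`, `"moderate_RI"`,
#'   `"severe_RI"`
#' @param seed integer seed used by [sample_population()]
#' @param overrides named list replacing any spec field (e.g.
#'   `list(kw_factor = 0.7)`)
#' @return object of class `"nk_popspec"`
#' @export
population_spec <- function(label = c("healthy", "geriatric",
                                      "moderate_RI", "severe_RI"),
                            seed = 1L, overrides = list()) {
  label <- match.arg(label)
  spec <- list(
    label = label,
    seed = as.integer(seed),
    sex_ratio = 0.5,                      # probability male
    age_range = switch(label,
      healthy = c(20, 50), geriatric = c(65, 85),
      moderate_RI = c(40, 70), severe_RI = c(40, 70)),
    weight_mean = switch(label,
      geriatric = c(male = 78, female = 66),
      c(male = 81, female = 68)),
    weight_cv = 0.12,
    height_mean = switch(label,
      geriatric = c(male = 172, female = 160),
      c(male = 176, female = 163)),
    height_sd = 7,
    scr_median = if (label %in% names(POP_SCR_MEDIAN))
      POP_SCR_MEDIAN[[label]] else NULL,
    scr_cv = BSV_CV_SCR,
    gfr_band = if (label %in% names(POP_GFR_BAND))
      POP_GFR_BAND[[label]] else NULL,
    kw_factor = unname(POP_KW_FACTOR[label]),
    fu_factor = unname(POP_FU_FACTOR[label]),
    hematocrit = unname(POP_HCT[label]),
    rbf_factor = unname(POP_RBF_FACTOR[label]),
    cv_clint = BSV_CV_CLINT,
    cv_clpd = BSV_CV_CLPD,
    cv_pgp = BSV_CV_PGP)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(spec))
    if (length(unknown))
      stop("unknown population spec fields: ", paste(unknown, collapse = ", "))
    spec <- modifyList(spec, overrides)
  }
  class(spec) <- "nk_popspec"
  spec
}

# lognormal draws with mean 1 and given coefficient of variation
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Sample a virtual population
#'
#' Reproducible (seeded) sampling of `n` virtual subjects from a
#' [population_spec()]. Between-subject variability on transporter
#' intrinsic clearance, P-gp abundance and passive diffusion clearance is
#' lognormal with the spec's CVs.
#'
#' @param spec an `"nk_popspec"`
#' @param n number of subjects (>= 0)
#' @return data.frame with one row per subject; columns `id`, `sex`, `age`,
#'   `weight`, `height`, `bsa`, `scr`, `gfr_abs`, `gfr_norm`,
#'   `kidney_weight`, `hematocrit`, `fu_plasma`, `renal_blood_flow`,
#'   `ptcpgk`, `oatp_mult`, `pgp_mult`, `clpd_mult`
#' @export
sample_population <- function(spec, n) {
  stopifnot(inherits(spec, "nk_popspec"))
  if (length(n) != 1 || is.na(n) || n < 0) stop("n must be a count >= 0")
  n <- as.integer(n)
  cols <- c("id", "sex", "age", "weight", "height", "bsa", "scr",
            "gfr_abs", "gfr_norm", "kidney_weight", "hematocrit",
            "fu_plasma", "renal_blood_flow", "ptcpgk",
            "oatp_mult", "pgp_mult", "clpd_mult")
  if (n == 0L) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    out$sex <- character(0)
    return(out)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  sex <- ifelse(runif(n) < spec$sex_ratio, "male", "female")
  age <- runif(n, spec$age_range[1], spec$age_range[2])
  wmean <- spec$weight_mean[sex]
  weight <- pmax(40, rnorm(n, wmean, spec$weight_cv * wmean))
  height <- pmax(140, rnorm(n, spec$height_mean[sex], spec$height_sd))
  bsa <- bsa_dubois(weight, height)

  if (!is.null(spec$scr_median)) {
    sdlog <- sqrt(log(1 + spec$scr_cv^2))
    scr <- spec$scr_median[sex] * rlnorm(n, 0, sdlog)
    gfr_abs <- vapply(seq_len(n), function(i)
      gfr_from_scr(age[i], weight[i], sex[i], scr[i]), numeric(1))
    gfr_norm <- gfr_abs * 1.73 / bsa
  } else {
    gfr_norm <- runif(n, spec$gfr_band[1], spec$gfr_band[2])
    scr <- vapply(seq_len(n), function(i)
      inverse_cockcroft_gault(gfr_norm[i], age[i], weight[i], sex[i], bsa[i]),
      numeric(1))
    gfr_abs <- gfr_norm * bsa / 1.73
  }

  data.frame(
    id = seq_len(n), sex = sex, age = age, weight = weight, height = height,
    bsa = bsa, scr = scr, gfr_abs = gfr_abs, gfr_norm = gfr_norm,
    kidney_weight = KW_REF_CAL * (bsa / REF_BSA) * spec$kw_factor,
    hematocrit = rep(spec$hematocrit, n),
    fu_plasma = rep(FU_PLASMA_CAL * spec$fu_factor, n),
    renal_blood_flow = REF_RBF * (bsa / REF_BSA) * spec$rbf_factor,
    ptcpgk = rep(PTCPGK_REF, n),
    oatp_mult = rlnorm_cv(n, spec$cv_clint),
    pgp_mult = rlnorm_cv(n, spec$cv_pgp),
    clpd_mult = rlnorm_cv(n, spec$cv_clpd),
    stringsAsFactors = FALSE)
}

#' Turn one population row into a subject
#'
#' @param row a single row of the data.frame returned by
#'   [sample_population()]
#' @return an `"nk_subject"`
#' @export
subject_from_row <- function(row) {
  stopifnot(nrow(row) == 1)
  virtual_subject(age = row$age, weight = row$weight, sex = row$sex,
                  bsa = row$bsa, scr = row$scr,
                  kidney_weight = row$kidney_weight,
                  hematocrit = row$hematocrit, fu_plasma = row$fu_plasma,
                  renal_blood_flow = row$renal_blood_flow,
                  ptcpgk = row$ptcpgk, oatp_mult = row$oatp_mult,
                  pgp_mult = row$pgp_mult, clpd_mult = row$clpd_mult)
}
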