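#' Body surface area (Du Bois)
#'
#' @param weight body weight, kg
#' @param height height, cm
#' @return body surface area, m^2
#' @export
bsa_dubois <- function(weight, height) {
  stopifnot(all(weight > 0), all(height > 0))
  0.007184 * weight^0.425 * height^0.725
}

#' Cockcroft-Gault creatinine clearance
#'
#' Classic Cockcroft-Gault estimate of creatinine clearance from
#' demographics and serum creatinine, with creatinine in µmol/l
#' (the 72 mg/dl divisor combined with the 88.4 µmol/l per mg/dl
#' conversion, i.e. a multiplier of 88.4/72 on the µmol/l scale).
#'
#' @param age age, years (< 140)
#' @param weight body weight, kg
#' @param sex `"male"` or `"female"`
#' @param scr serum creatinine, µmol/l
#' @return absolute creatinine clearance, ml/min
#' @examples
#' cockcroft_gault(20, 81, "male", 76.5)   # ~156 ml/min
#' @export
cockcroft_gault <- function(age, weight, sex, scr) {
  sex <- match.arg(sex, c("male", "female"))
  if (any(age >= 140)) stop("age must be < 140 years")
  if (any(age <= 0) || any(weight <= 0) || any(scr <= 0))
    stop("age, weight and serum creatinine must be positive")
  cl <- (140 - age) * weight * CG_K / scr
  if (sex == "female") cl <- 0.85 * cl
  cl
}

#' Cockcroft-Gault clearance normalized to 1.73 m^2
#'
#' @inheritParams cockcroft_gault
#' @param bsa body surface area, m^2
#' @return creatinine clearance, ml/min/1.73 m^2
#' @export
cockcroft_gault_normalized <- function(age, weight, sex, scr, bsa) {
  stopifnot(all(bsa > 0))
  cockcroft_gault(age, weight, sex, scr) * 1.73 / bsa
}

#' Invert Cockcroft-Gault for serum creatinine
#'
#' Exact algebraic inverse of [cockcroft_gault()] composed with BSA
#' normalization: the serum creatinine that yields a target normalized
#' GFR for the given demographics.
#'
#' @param gfr_norm target GFR, ml/min/1.73 m^2
#' @inheritParams cockcroft_gault_normalized
#' @return serum creatinine, µmol/l
#' @examples
#' inverse_cockcroft_gault(136.4, 20, 81, "male", 1.98)  # ~76.5 µmol/l
#' @export
inverse_cockcroft_gault <- function(gfr_norm, age, weight, sex, bsa) {
  sex <- match.arg(sex, c("male", "female"))
  if (any(gfr_norm <= 0)) stop("GFR must be positive")
  stopifnot(all(bsa > 0), all(age > 0), all(age < 140), all(weight > 0))
  gfr_abs <- gfr_norm * bsa / 1.73
  k <- (140 - age) * weight * CG_K
  if (sex == "female") k <- 0.85 * k
  k / gfr_abs
}

#' Model GFR from serum creatinine
#'
#' Absolute GFR used by the kidney model: the Cockcroft-Gault estimate
#' capped at a physiological ceiling of 180 ml/min (the hyperfiltration
#' threshold), below which the Cockcroft-Gault estimate at low serum
#' creatinine would grow without bound.
#'
#' @inheritParams cockcroft_gault
#' @return absolute GFR, ml/min
#' @export
gfr_from_scr <- function(age, weight, sex, scr) {
  pmin(cockcroft_gault(age, weight, sex, scr), GFR_MAX)
}

#' Proportional renal-impairment scaling factor
#'
#' Relative change in GFR versus the healthy-representative baseline,
#' applied identically to the OATP4C1 abundance multiplier and (times 60)
#' to proximal tubule cellularity per gram kidney.
#'
#' @param gfr_norm scenario GFR, ml/min/1.73 m^2
#' @param baseline reference GFR, ml/min/1.73 m^2 (default 136.4)
#' @return unitless factor `gfr_norm / baseline`
#' @export
proportional_ri_scaling <- function(gfr_norm, baseline = 136.4) {
  stopifnot(all(gfr_norm > 0), baseline > 0)
  gfr_norm / baseline
}

#' Construct a virtual subject
#'
#' A subject carries the demographics and renal physiology the kidney model
#' needs, plus per-transporter abundance multipliers (default 1).
#'
#' @param age years
#' @param weight kg
#' @param sex `"male"` or `"female"`
#' @param bsa body surface area, m^2
#' @param scr serum creatinine, µmol/l
#' @param kidney_weight both kidneys, g
#' @param hematocrit fraction in (0, 1)
#' @param fu_plasma unbound fraction in plasma, (0, 1]
#' @param renal_blood_flow ml/min
#' @param ptcpgk million proximal tubule cells per g kidney
#' @param oatp_mult,pgp_mult,clpd_mult abundance multipliers (positive)
#' @return object of class `"nk_subject"` (a named list)
#' @export
virtual_subject <- function(age = REF_AGE, weight = REF_WEIGHT, sex = "male",
                            bsa = REF_BSA, scr = REF_SCR,
                            kidney_weight = KW_REF_CAL,
                            hematocrit = REF_HCT,
                            fu_plasma = FU_PLASMA_CAL,
                            renal_blood_flow = REF_RBF,
                            ptcpgk = PTCPGK_REF,
                            oatp_mult = 1, pgp_mult = 1, clpd_mult = 1) {
  sex <- match.arg(sex, c("male", "female"))
  vals <- c(age = age, weight = weight, bsa = bsa, scr = scr,
            kidney_weight = kidney_weight, hematocrit = hematocrit,
            fu_plasma = fu_plasma, renal_blood_flow = renal_blood_flow,
            ptcpgk = ptcpgk, oatp_mult = oatp_mult, pgp_mult = pgp_mult,
            clpd_mult = clpd_mult)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all subject quantities must be positive and finite")
  if (hematocrit >= 1) stop("hematocrit must lie in (0, 1)")
  if (fu_plasma > 1) stop("fu_plasma must lie in (0, 1]")
  gfr_abs <- gfr_from_scr(age, weight, sex, scr)
  s <- list(age = age, sex = sex, weight = weight, bsa = bsa, scr = scr,
            gfr_abs = gfr_abs, gfr_norm = gfr_abs * 1.73 / bsa,
            kidney_weight = kidney_weight, hematocrit = hematocrit,
            fu_plasma = fu_plasma, renal_blood_flow = renal_blood_flow,
            ptcpgk = ptcpgk, oatp_mult = oatp_mult, pgp_mult = pgp_mult,
            clpd_mult = clpd_mult)
  class(s) <- "nk_subject"
  s
}

#' Healthy population representative
#'
#' The simulated population representative of the healthy-volunteer
#' population: age 20 years, 81 kg, BSA 1.98 m^2, male. Serum creatinine
#' defaults to 76.5 µmol/l (normalized GFR 136.4 ml/min/1.73 m^2).
#'
#' @param scr serum creatinine, µmol/l
#' @param ... further overrides passed to [virtual_subject()]
#' @return an `"nk_subject"`
#' @export
reference_subject <- function(scr = REF_SCR, ...) {
  virtual_subject(scr = scr, ...)
}

#' @export
print.nk_subject <- function(x, ...) {
  cat(sprintf(
    "<virtual subject> %s, %g y, %g kg, BSA %.2f m2\n  SCr %.1f umol/l -> GFR %.1f ml/min (%.1f ml/min/1.73 m2)\n  kidney %.0f g, fu_plasma %.3f, RBF %.0f ml/min, PTCPGK %.1f M/g\n",
    x$sex, x$age, x$weight, x$bsa, x$scr, x$gfr_abs, x$gfr_norm,
    x$kidney_weight, x$fu_plasma, x$renal_blood_flow, x$ptcpgk))
  invisible(x)
}
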