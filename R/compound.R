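#' Digoxin compound parameters
#'
#' All drug-specific constants of the kidney and systemic models. Kinetic
#' constants follow the final mechanistic kidney model parameterization:
#' passive diffusion clearance 0.01 µl/min/million cells on both membranes
#' of every tubular segment, OATP4C1 intrinsic clearance 4.14
#' µl/min/million proximal tubule cells (REF 1), P-gp Km 177 µM and Vmax
#' 434 pmol/min/million cells (REF 1.51), fraction unbound in kidney cells
#' 0.51 and in urine 1. The plasma unbound fraction is the calibrated
#' effective value for which filtration-only renal clearance of the
#' healthy representative equals 98.8 ml/min. Systemic disposition is a
#' two-compartment model with a lumped non-renal clearance of 91 ml/min.
#'
#' @param ... overrides for any listed field
#' @return object of class `"nk_compound"`
#' @examples
#' digoxin_compound()
#' digoxin_compound(oatp_clint = 1.85)
#' @export
digoxin_compound <- function(...) {
  p <- list(
    name = "digoxin",
    mw = DIGOXIN_MW,                 # g/mol
    fu_plasma = FU_PLASMA_CAL,       # calibrated; see vignette
    blood_plasma_ratio = BLOOD_PLASMA_RATIO,
    fu_urine = 1,
    fu_kidney_cell = 0.51,
    cl_pd = 0.01,                    # ul/min/million cells, each membrane
    oatp_clint = 4.14,               # ul/min/million PTC
    oatp_ref = 1,
    pgp_km = 177,                    # uM
    pgp_vmax = 434,                  # pmol/min/million cells
    pgp_ref = 1.51,
    cl_nonrenal = 91,                # ml/min
    v_central = 45000,               # ml
    v_peripheral = 455000,           # ml  (Vss ~ 500 l)
    q_intercomp = 800)               # ml/min
  ov <- list(...)
  if (length(ov)) {
    unknown <- setdiff(names(ov), names(p))
    if (length(unknown))
      stop("unknown compound fields: ", paste(unknown, collapse = ", "))
    p <- modifyList(p, ov)
  }
  num <- p[!(names(p) %in% "name")]
  if (any(!is.finite(unlist(num))) || any(unlist(num) < 0))
    stop("compound parameters must be nonnegative and finite")
  for (f in c("fu_plasma", "fu_urine", "fu_kidney_cell"))
    if (p[[f]] <= 0 || p[[f]] > 1) stop(f, " must lie in (0, 1]")
  class(p) <- "nk_compound"
  p
}

#' @export
print.nk_compound <- function(x, ...) {
  cat(sprintf(
    "<compound> %s\n  fu_plasma %.3f, fu_cell %.2f, fu_urine %g, B:P %.2f\n  CL_PD %g ul/min/M cells; OATP4C1 CLint %g ul/min/M PTC (REF %g)\n  P-gp Km %g uM, Vmax %g pmol/min/M cells (REF %g)\n  CL_nonrenal %g ml/min; V1 %g l, V2 %g l, Q %g ml/min\n",
    x$name, x$fu_plasma, x$fu_kidney_cell, x$fu_urine, x$blood_plasma_ratio,
    x$cl_pd, x$oatp_clint, x$oatp_ref, x$pgp_km, x$pgp_vmax, x$pgp_ref,
    x$cl_nonrenal, x$v_central / 1000, x$v_peripheral / 1000, x$q_intercomp))
  invisible(x)
}
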