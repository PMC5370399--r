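# In vitro-in vivo extrapolation helpers for transporter kinetics.

#' Intrinsic clearance from linear-range uptake
#'
#' `CL_int = (dX/dt) / C`, valid when the substrate concentration is well
#' below Km so uptake is linear in concentration. The result carries the
#' same cellular (or protein) basis as the rate.
#'
#' @param rate uptake rate dX/dt, pmol/min per mg protein or per million
#'   cells
#' @param conc initial substrate concentration, µM
#' @param warn_linear if `TRUE`, warn that the linear-range assumption is
#'   being applied
#' @return intrinsic clearance, µl/min per the same basis as `rate`
#' @examples
#' clint_from_uptake(10, 1)  # 10 ul/min/million cells
#' @export
clint_from_uptake <- function(rate, conc, warn_linear = FALSE) {
  if (any(conc <= 0)) stop("substrate concentration must be positive")
  if (any(rate < 0)) stop("uptake rate must be nonnegative")
  if (warn_linear)
    warning("assumes C << Km (linear-range uptake)")
  rate / conc
}

#' Normalize per-mg-protein clearance to proximal tubule cells
#'
#' Divides a per-mg-protein intrinsic clearance by the assay cellularity
#' (13 million MDCK cells per mg protein by default), interpreting the
#' result per million proximal tubule cells under the equal
#' expression/activity assumption.
#'
#' @param clint_per_mg µl/min/mg protein
#' @param cells_per_mg million cells per mg protein (default 13)
#' @return µl/min/million proximal tubule cells
#' @export
normalize_to_ptc <- function(clint_per_mg, cells_per_mg = 13) {
  if (any(cells_per_mg <= 0)) stop("cellularity must be positive")
  clint_per_mg / cells_per_mg
}

#' Kidney relative expression factor for P-gp from mRNA ratios
#'
#' Chains a kidney:intestine mRNA expression ratio with the
#' intestine:Caco-2 relative expression factor (2.04) to obtain the
#' kidney:Caco-2 REF. Assumes tissue-level mRNA is representative of
#' cellular expression.
#'
#' @param kidney_to_intestine_mrna positive ratio
#' @param intestine_to_caco2_ref positive ratio (default 2.04)
#' @return unitless relative expression factor
#' @examples
#' pgp_ref_kidney(0.740)  # ~1.51, the final model value
#' @export
pgp_ref_kidney <- function(kidney_to_intestine_mrna,
                           intestine_to_caco2_ref = 2.04) {
  if (any(kidney_to_intestine_mrna <= 0) || any(intestine_to_caco2_ref <= 0))
    stop("ratios must be positive")
  kidney_to_intestine_mrna * intestine_to_caco2_ref
}

#' Read a table of in vitro uptake measurements
#'
#' Expects columns `system`, `rate`, `units`, `conc` and returns the table
#' with a `clint` column appended (rate/conc, per the row's own basis).
#'
#' @param path CSV file path
#' @return data.frame
#' @export
read_uptake_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("system", "rate", "units", "conc")
  if (!all(need %in% names(df)))
    stop("uptake table must have columns: ", paste(need, collapse = ", "))
  df$clint <- clint_from_uptake(df$rate, df$conc)
  df
}
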