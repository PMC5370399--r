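#' Nephron geometry for a subject
#'
#' Builds the segment-level structure the kidney model runs on: cell
#' numbers, per-segment filtrate flows, and the distal surface-area
#' factors applied to passive diffusion clearance.
#'
#' Cellularity: the three proximal tubule subsegments split
#' `ptcpgk * kidney_weight` equally; loop of Henle, distal tubule and the
#' two collecting ducts are tied to total proximal cellularity by fixed
#' ratios (0.3, 0.2, 0.1, 0.1), so a change in PTCPGK rescales every
#' tubular segment. Water handling: proximal and early-distal exit flows
#' are fixed fractions of GFR (glomerulotubular balance); flows are floored
#' at an absolute urine flow of 1 ml/min, reflecting the loss of urinary
#' concentrating capacity as GFR falls.
#'
#' @param subject an `"nk_subject"` (see [virtual_subject()])
#' @param ptcpgk_mult multiplier on proximal tubule cells per gram
#'   (scenario device; scales all segments)
#' @param water_exit_frac fraction of filtered water remaining at each
#'   segment exit (named, length 7)
#' @param kappa_distal surface-area factor on distal passive diffusion
#'   (calibrated so the representative fraction reabsorbed is 0.12)
#' @return object of class `"nk_geometry"`: a list with `segments`,
#'   `cells` (million), `sa_factor`, `q_exit` (ml/min), `urine_flow`,
#'   `gfr_abs`, `ptcpgk_eff`
#' @export
nephron_geometry <- function(subject, ptcpgk_mult = 1,
                             water_exit_frac = WATER_EXIT_FRAC,
                             kappa_distal = KAPPA_DISTAL) {
  stopifnot(inherits(subject, "nk_subject"), ptcpgk_mult > 0,
            length(water_exit_frac) == 7, all(water_exit_frac > 0),
            all(diff(water_exit_frac) < 0), kappa_distal > 0)
  gfr <- subject$gfr_abs
  ptc_total <- subject$ptcpgk * ptcpgk_mult * subject$kidney_weight
  cells <- c(ptc_total * CELL_SPLIT_PT, ptc_total * CELL_RATIO_DISTAL)
  names(cells) <- SEGMENTS
  q_exit <- pmax(water_exit_frac * gfr, URINE_FLOW_MIN)
  q_exit <- pmin(cummin(q_exit), gfr)   # nonincreasing, never above GFR
  names(q_exit) <- SEGMENTS
  g <- list(segments = SEGMENTS, cells = cells,
            sa_factor = c(1, 1, 1, rep(kappa_distal, 4)),
            q_exit = q_exit, urine_flow = unname(q_exit["MCD"]),
            gfr_abs = gfr, ptcpgk_eff = subject$ptcpgk * ptcpgk_mult)
  class(g) <- "nk_geometry"
  g
}

#' @export
print.nk_geometry <- function(x, ...) {
  cat("<nephron geometry> GFR", round(x$gfr_abs, 1), "ml/min; urine flow",
      round(x$urine_flow, 2), "ml/min\n")
  print(data.frame(segment = x$segments, cells_million = round(x$cells, 0),
                   sa_factor = x$sa_factor, q_exit = round(x$q_exit, 2),
                   row.names = NULL))
  invisible(x)
}
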