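# Frozen model constants. Calibrated quantities are tuned once (see the
# methods vignette, "Calibration") and never adjusted at run time.

# molecular weight of digoxin, g/mol; converts pmol <-> ng
DIGOXIN_MW <- 780.94

# Cockcroft-Gault multiplier for serum creatinine in umol/l
# (classic 72 mg/dl divisor combined with 88.4 umol/l per mg/dl)
CG_K <- 88.4 / 72

# physiological ceiling on absolute GFR (ml/min); the hyperfiltration
# threshold. Caps the Cockcroft-Gault estimate at low serum creatinine.
GFR_MAX <- 180

# reference (healthy representative) renal physiology
REF_AGE <- 20
REF_WEIGHT <- 81
REF_BSA <- 1.98
REF_SCR <- 76.5
REF_HCT <- 0.45
REF_RBF <- 1100          # renal blood flow, ml/min, both kidneys
BLOOD_PLASMA_RATIO <- 1.0
PTCPGK_REF <- 60         # million proximal tubule cells / g kidney

# calibrated constants (frozen; see vignette)
FU_PLASMA_CAL  <- 98.8 / 156  # unbound fraction in plasma; fu*GFR(ref) = 98.8
KW_REF_CAL     <- 380.40      # reference kidney weight (both kidneys), g
KAPPA_DISTAL   <- 8.6078      # distal surface-area factor on CL_PD

# nephron geometry defaults
SEGMENTS <- c("PT1", "PT2", "PT3", "LoH", "DT", "CCD", "MCD")
# fraction of filtered water remaining at each segment exit
WATER_EXIT_FRAC <- c(PT1 = 0.71, PT2 = 0.49, PT3 = 0.34,
                     LoH = 0.25, DT = 0.11, CCD = 0.033, MCD = 0.0064)
URINE_FLOW_MIN <- 1.0    # ml/min absolute floor on distal flows
# cell split: PT1:PT2:PT3 equal thirds of PTCPGK x kidney weight;
# distal cellularity tied to total PT cells by fixed ratios
CELL_SPLIT_PT <- c(1, 1, 1) / 3
CELL_RATIO_DISTAL <- c(LoH = 0.3, DT = 0.2, CCD = 0.1, MCD = 0.1)

# population condition constants (fixed study conditions, not tuning knobs)
POP_LABELS <- c("healthy", "geriatric", "moderate_RI", "severe_RI")
POP_KW_FACTOR   <- c(healthy = 1.00, geriatric = 0.90,
                     moderate_RI = 0.80, severe_RI = 0.55)
POP_FU_FACTOR   <- c(healthy = 1.00, geriatric = 1.00,
                     moderate_RI = 1.05, severe_RI = 1.10)
POP_HCT         <- c(healthy = 0.45, geriatric = 0.42,
                     moderate_RI = 0.40, severe_RI = 0.35)
POP_RBF_FACTOR  <- POP_KW_FACTOR
# healthy/geriatric sample serum creatinine (lognormal medians, umol/l)
POP_SCR_MEDIAN <- list(healthy   = c(male = 66, female = 56),
                       geriatric = c(male = 74, female = 61))
# renal impairment populations sample normalized GFR uniformly in band
POP_GFR_BAND <- list(moderate_RI = c(30, 60), severe_RI = c(15, 30))
# between-subject variability (lognormal CV)
BSV_CV_CLINT <- 0.30
BSV_CV_CLPD  <- 0.30
BSV_CV_PGP   <- 0.30
BSV_CV_SCR   <- 0.15
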