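# Shared stoichiometric constants.
#
# Biomass is the standard ash-free yeast composition CH1.8O0.5N0.2
# (24.6 g per C-mol); its degree of reduction (NH3 as N source) is
# 4 + 1.8 - 2*0.5 - 3*0.2 = 4.2. All per-C-mol masses in g/C-mol.

#' Per-C-mole masses of substrate, products and biomass
#'
#' Grams per C-mole used throughout for C-mole carbon balancing:
#' glucose 30.03, ethanol 23.03, glycerol 30.70, acetate 30.03,
#' pyruvate 29.35, succinate 29.52, lactate 30.03, and biomass 24.6
#' (ash-free CH1.8O0.5N0.2, the standard yeast elemental composition).
#'
#' @format Named numeric vector, g/C-mol.
#' @export
cmol_mass <- c(
  glucose   = 30.03,
  ethanol   = 23.03,
  glycerol  = 30.70,
  acetate   = 30.03,
  pyruvate  = 29.35,
  succinate = 29.52,
  lactate   = 30.03,
  biomass   = 24.6
)

# Degrees of reduction per C-mol (NH3 N source), used for the
# electron-balanced O2 demand during growth on ethanol.
GAMMA_ETHANOL <- 6.0
GAMMA_BIOMASS <- 4.2

# Theoretical maximum ethanol yield on glucose, g/g
# (2 * 46.07 / 180.16 for C6H12O6 -> 2 EtOH + 2 CO2).
ETHANOL_YIELD_MAX <- 0.511

# Column layout of a culture time series (the CSV dialect shared by the
# simulator, the extractor and user-supplied data).
CULTURE_COLUMNS <- c(
  "time_h", "dw_gL", "od600", "glucose_gL", "ethanol_gL", "glycerol_gL",
  "acetate_gL", "pyruvate_gL", "succinate_gL", "lactate_gL",
  "co2_cum_mol_per_L", "o2_cum_mol_per_L"
)

PRODUCT_COLUMNS <- c(
  ethanol = "ethanol_gL", glycerol = "glycerol_gL", acetate = "acetate_gL",
  pyruvate = "pyruvate_gL", succinate = "succinate_gL", lactate = "lactate_gL"
)
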