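# VFA stoichiometry and metabolic-hydrogen balance.
#
# Fermentation of hexose to the volatile fatty acids releases (acetate,
# butyrate) or consumes (propionate, valerate) reducing equivalents
# ("metabolic hydrogen", [2H]); methanogenesis is the major sink. The
# classical stoichiometric bookkeeping used here infers fermented hexose
# and the [2H] balance from the molar VFA yields:
#
#   FOM            = 0.5 Ac + 0.5 Pr + But + Val        (mmol hexose)
#   [2H] produced  = 2 Ac + Pr + 4 But + 3 Val          (mmol)
#   [2H] incorporated = 2 Pr + 2 But + 4 Val + 4 CH4    (mmol)
#   [2H] recovery  = 100 * incorporated / produced      (%)
#
# Branched-chain acids (isobutyrate, isovalerate) arise from amino-acid
# fermentation, not hexose, and are carried for reporting but excluded
# from the formulas.

#' Construct a VFA profile
#'
#' Per-sample amounts of the six measured volatile fatty acids. In
#' `"outflow"` mode amounts are daily molar outflows (mmol/d, Rusitec
#' overflow); in `"batch"` mode concentrations (mM) are converted to
#' amounts (mmol) using the vessel liquid volume.
#'
#' @param acetate,propionate,butyrate,valerate straight-chain acids,
#'   mmol/d (outflow) or mM (batch).
#' @param isobutyrate,isovalerate branched-chain acids; reported in the
#'   totals but excluded from the stoichiometric formulas.
#' @param mode `"outflow"` (default) or `"batch"`.
#' @param volume_l vessel liquid volume used in batch mode (default
#'   0.05 L, i.e. 50 mL of inoculated medium per bottle).
#' @return object of class `vfa_profile`: list of the six amounts (mmol
#'   or mmol/d) plus `mode`.
#' @export
#' @examples
#' v <- vfa_profile(acetate = 15.7, propionate = 9.60,
#'                  butyrate = 5.51, valerate = 1.60)
#' hydrogen_produced(v)
vfa_profile <- function(acetate, propionate, butyrate, valerate,
                        isobutyrate = 0, isovalerate = 0,
                        mode = c("outflow", "batch"), volume_l = 0.05) {
  mode <- match.arg(mode)
  amounts <- c(acetate = acetate, propionate = propionate,
               butyrate = butyrate, valerate = valerate,
               isobutyrate = isobutyrate, isovalerate = isovalerate)
  check_nonnegative(amounts, "VFA amounts")
  if (mode == "batch") {
    check_positive(volume_l, "volume_l")
    amounts <- amounts * volume_l
  }
  structure(c(as.list(amounts), list(mode = mode)), class = "vfa_profile")
}

#' @export
print.vfa_profile <- function(x, ...) {
  cat(sprintf("<vfa_profile mode=%s total=%.3f>\n", x$mode, vfa_total(x)))
  invisible(x)
}

#' Total VFA of a profile (all six acids)
#' @param vfa a [vfa_profile()].
#' @return total amount, mmol or mmol/d.
#' @export
vfa_total <- function(vfa) {
  vfa$acetate + vfa$propionate + vfa$butyrate + vfa$valerate +
    vfa$isobutyrate + vfa$isovalerate
}

#' Molar proportions of a VFA profile
#' @param vfa a [vfa_profile()].
#' @return named numeric vector over the six acids, summing to 1.
#' @export
vfa_proportions <- function(vfa) {
  tot <- vfa_total(vfa)
  check_positive(tot, "total VFA")
  unlist(vfa[c("acetate", "propionate", "butyrate", "valerate",
               "isobutyrate", "isovalerate")]) / tot
}

#' Fermentable organic matter as hexose equivalents
#'
#' FOM = 0.5 Ac + 0.5 Pr + But + Val (mmol hexose). Acetate and
#' propionate each account for half a hexose; butyrate and valerate for
#' a whole one. Iso-acids are excluded.
#'
#' @param vfa a [vfa_profile()].
#' @return fermented hexose, mmol (or mmol/d in outflow mode).
#' @export
compute_fom <- function(vfa) {
  0.5 * vfa$acetate + 0.5 * vfa$propionate + vfa$butyrate + vfa$valerate
}

#' Convert hexose equivalents to mass
#'
#' @param fom_hexose fermented hexose, mmol.
#' @param monomer_mass mass of the polymerised (anhydro) hexose monomer,
#'   mg/mmol; default 162.
#' @return fermentable OM, mg.
#' @export
fom_mass <- function(fom_hexose, monomer_mass = 162) {
  check_nonnegative(fom_hexose, "fom_hexose")
  fom_hexose * monomer_mass
}

#' Metabolic hydrogen produced
#'
#' \[2H\] produced = 2 Ac + Pr + 4 But + 3 Val.
#'
#' @param vfa a [vfa_profile()].
#' @return mmol/d of 2H released by fermentation to VFA.
#' @export
hydrogen_produced <- function(vfa) {
  2 * vfa$acetate + vfa$propionate + 4 * vfa$butyrate + 3 * vfa$valerate
}

#' Metabolic hydrogen incorporated into fermentation products
#'
#' \[2H\] incorporated = 2 Pr + 2 But + 4 Val + `ch4_coefficient` * CH4.
#' Methanogenesis consumes 4 H2 (i.e. four 2H pairs) per CH4, hence the
#' default coefficient of 4; it is exposed for sensitivity analyses.
#'
#' @param vfa a [vfa_profile()].
#' @param methane daily methane production, mmol/d.
#' @param ch4_coefficient reducing-equivalent pairs consumed per mol
#'   CH4 (default 4).
#' @return mmol/d of 2H captured in propionate, butyrate, valerate and
#'   methane.
#' @export
hydrogen_incorporated <- function(vfa, methane, ch4_coefficient = 4) {
  check_nonnegative(methane, "methane")
  2 * vfa$propionate + 2 * vfa$butyrate + 4 * vfa$valerate +
    ch4_coefficient * methane
}

#' Metabolic hydrogen recovery
#'
#' 100 * incorporated / produced (%). Values below 100 indicate 2H lost
#' to unmeasured sinks (microbial biomass, lactate, dissolved H2).
#'
#' @param produced,incorporated mmol/d, e.g. from [hydrogen_produced()]
#'   and [hydrogen_incorporated()].
#' @return recovery, %.
#' @export
hydrogen_recovery <- function(produced, incorporated) {
  check_positive(produced, "produced")
  check_nonnegative(incorporated, "incorporated")
  100 * incorporated / produced
}

#' Methane to total-VFA molar ratio
#'
#' @param methane mmol/d.
#' @param total_vfa total VFA production, mmol/d.
#' @return mol CH4 per mol VFA.
#' @export
ch4_vfa_ratio <- function(methane, total_vfa) {
  check_positive(total_vfa, "total_vfa")
  check_nonnegative(methane, "methane")
  methane / total_vfa
}

#' Intake-weighted organic-matter fraction of a mixed diet
#'
#' @param forage_om_pct,concentrate_om_pct OM contents, % of DM.
#' @param forage_fraction forage share of DM intake (default 0.8 for
#'   the 80:20 diets).
#' @return unitless OM fraction of the whole diet.
#' @export
diet_om_fraction <- function(forage_om_pct, concentrate_om_pct,
                             forage_fraction = 0.8) {
  check_fraction(forage_fraction, "forage_fraction")
  (forage_fraction * forage_om_pct +
     (1 - forage_fraction) * concentrate_om_pct) / 100
}

#' Daily degraded organic matter
#'
#' @param dm_intake DM intake, g/d.
#' @param diet_om_fraction OM fraction of the diet DM (0-1), e.g. from
#'   [diet_om_fraction()].
#' @param om_disappearance fraction of OM disappearing in the vessel
#'   (0-1).
#' @return degraded OM, g/d.
#' @export
degraded_om <- function(dm_intake, diet_om_fraction, om_disappearance) {
  check_nonnegative(dm_intake, "dm_intake")
  check_fraction(diet_om_fraction, "diet_om_fraction")
  check_fraction(om_disappearance, "om_disappearance")
  dm_intake * diet_om_fraction * om_disappearance
}

#' Methane yield per unit degraded OM
#'
#' @param methane mmol/d.
#' @param degraded_om g/d, e.g. from [degraded_om()].
#' @return mmol CH4 per g degraded OM.
#' @export
methane_yield <- function(methane, degraded_om) {
  check_positive(degraded_om, "degraded_om")
  check_nonnegative(methane, "methane")
  methane / degraded_om
}

#' Full metabolic-hydrogen balance for one sample
#'
#' @param vfa a [vfa_profile()].
#' @param methane mmol/d.
#' @param total_vfa total VFA used for the CH4:VFA ratio; defaults to
#'   the profile's six-acid total but can be overridden when an
#'   independently measured total is available.
#' @param ch4_coefficient see [hydrogen_incorporated()].
#' @return one-row data.frame: `h_produced`, `h_incorporated`,
#'   `recovery`, `ch4_vfa_ratio`.
#' @export
hydrogen_balance <- function(vfa, methane, total_vfa = vfa_total(vfa),
                             ch4_coefficient = 4) {
  prod <- hydrogen_produced(vfa)
  inc <- hydrogen_incorporated(vfa, methane, ch4_coefficient)
  data.frame(
    h_produced = prod,
    h_incorporated = inc,
    recovery = hydrogen_recovery(prod, inc),
    ch4_vfa_ratio = ch4_vfa_ratio(methane, total_vfa)
  )
}

#' Fermentation summary for one sample
#'
#' Combines the hexose and methane bookkeeping into the per-sample
#' summary row emitted by the pipeline.
#'
#' @inheritParams hydrogen_balance
#' @param degraded_om g OM degraded per day.
#' @param monomer_mass mg per mmol anhydro-hexose (default 162).
#' @return one-row data.frame: `fom_hexose` (mmol), `fom_mass` (mg),
#'   `methane` (mmol/d), `degraded_om` (g/d), `methane_yield` (mmol/g).
#' @export
fermentation_summary <- function(vfa, methane, degraded_om,
                                 monomer_mass = 162) {
  fom <- compute_fom(vfa)
  data.frame(
    fom_hexose = fom,
    fom_mass = fom_mass(fom, monomer_mass),
    methane = methane,
    degraded_om = degraded_om,
    methane_yield = methane_yield(methane, degraded_om)
  )
}

#' Correct a redox reading to the standard-hydrogen-electrode scale
#'
#' Vessel redox potential is read against an Ag-AgCl reference
#' electrode; Eh = E0 + C converts to the standard hydrogen electrode,
#' with C = +198 mV at 39 degrees C.
#'
#' @param electrode_mv raw platinum-electrode potential E0, mV.
#' @param reference_offset_mv reference-electrode offset C, mV
#'   (default 198).
#' @return corrected Eh, mV.
#' @export
#' @examples
#' correct_redox(-311) # -113
correct_redox <- function(electrode_mv, reference_offset_mv = 198) {
  electrode_mv + reference_offset_mv
}
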