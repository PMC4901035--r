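# Published treatment means from the 2x2 (forage x vitamin E) Rusitec
# experiment and its companion batch-culture dose-response study. These
# tables are the fixture inputs for the reproduction report and the
# default parameter sets of the synthetic-data generator: treatments are
# GRA- / GRA+ (fresh ryegrass, without / with 50 IU/d alpha-tocopheryl
# acetate) and HAY- / HAY+ (ryegrass hay). SED columns are standard
# errors of the difference for the forage x vitamin E interaction (n = 4
# vessels per treatment).

treatments4 <- c("GRA-", "GRA+", "HAY-", "HAY+")

#' Chemical composition of the experimental diet components
#'
#' Percent of DM (except dry matter, % of fresh matter) for the fresh
#' grass, grass hay and the commercial concentrate used in the 80:20
#' forage:concentrate Rusitec diets.
#'
#' @return data.frame with one row per component (`grass`, `hay`,
#'   `concentrate`) and columns `dm_pct_fm`, `om_pct`, `n_pct`, `c_pct`,
#'   `ndf_pct`, `adf_pct`.
#' @export
ref_diet_composition <- function() {
  data.frame(
    component = c("grass", "hay", "concentrate"),
    dm_pct_fm = c(17.5, 84.9, 88.6),
    om_pct    = c(91.2, 91.0, 93.8),
    n_pct     = c(1.83, 1.69, 2.51),
    c_pct     = c(43.8, 43.5, 44.7),
    ndf_pct   = c(50.0, 54.6, 39.3),
    adf_pct   = c(24.0, 28.1, 12.1),
    stringsAsFactors = FALSE
  )
}

#' Reference degradability, gas and hydrogen-balance treatment means
#'
#' Published per-treatment means for feed disappearance, methane
#' emissions and the stoichiometric metabolic-hydrogen summary of the
#' Rusitec experiment, with SEDs where the generator needs them.
#'
#' @return data.frame keyed by `treatment` (GRA-, GRA+, HAY-, HAY+).
#' @export
ref_fermentation_means <- function() {
  data.frame(
    treatment           = treatments4,
    om_disappearance    = c(57.4, 63.5, 60.6, 63.7),
    ndf_disappearance   = c(44.1, 52.5, 52.8, 55.1),
    total_gas_l_d       = c(1.72, 1.71, 1.82, 2.03),
    methane_mmol_d      = c(5.10, 5.01, 6.04, 7.59),
    methane_per_deg_om  = c(0.87, 0.77, 0.96, 1.15),
    h_produced          = c(58.2, 64.0, 67.8, 67.9),
    h_incorporated      = c(50.5, 52.9, 60.8, 66.0),
    h_recovery          = c(87.3, 82.7, 89.6, 97.4),
    ch4_vfa             = c(0.165, 0.149, 0.172, 0.214),
    sed_methane_mmol_d  = 0.792,
    sed_om_disappearance = 3.34,
    stringsAsFactors = FALSE
  )
}

#' Reference daily outflows and nitrogen-partitioning treatment means
#'
#' Published per-treatment daily VFA outflows (mmol/d), N flows (mg/d)
#' and the derived degradability / efficiency-of-synthesis rows from the
#' Rusitec experiment, plus interaction SEDs used by the vessel
#' simulator. `total_vfa` is the printed total, which slightly exceeds
#' the sum of the six printed acids because it was computed per vessel
#' before rounding.
#'
#' @return data.frame keyed by `treatment`.
#' @export
ref_outflow_means <- function() {
  data.frame(
    treatment     = treatments4,
    total_vfa     = c(31.2, 33.8, 35.1, 35.5),
    acetate       = c(14.2, 15.7, 15.7, 16.8),
    propionate    = c(8.02, 8.93, 9.60, 9.96),
    butyrate      = c(4.50, 4.94, 5.51, 5.04),
    isobutyrate   = c(0.39, 0.41, 0.39, 0.41),
    valerate      = c(1.28, 1.27, 1.60, 1.42),
    isovalerate   = c(1.07, 1.28, 1.13, 1.22),
    ammonia_n     = c(58.8, 58.3, 48.8, 46.5),
    nan           = c(140, 152, 122, 115),
    nanm_n        = c(39.9, 54.8, 36.9, 28.6),
    microbial_n   = c(100.5, 97.7, 84.9, 86.3),
    apparent_deg  = c(36.5, 31.0, 41.8, 45.1),
    true_deg      = c(82.0, 75.2, 82.4, 86.4),
    microbial_from_ammonia = c(36.0, 36.3, 45.7, 44.8),
    eff_nan       = c(0.72, 0.64, 0.70, 0.75),
    eff_intake    = c(0.45, 0.44, 0.41, 0.41),
    eff_true_deg  = c(0.55, 0.59, 0.49, 0.48),
    emps          = c(17.0, 14.9, 13.6, 13.2),
    sed_acetate   = 1.247, sed_propionate = 0.801, sed_butyrate = 0.483,
    sed_isobutyrate = 0.036, sed_valerate = 0.067, sed_isovalerate = 0.086,
    sed_ammonia_n = 3.86, sed_nan = 6.92, sed_microbial_n = 4.71,
    stringsAsFactors = FALSE
  )
}

#' Reference batch-culture gas-kinetics and protozoal-activity parameters
#'
#' Control-bottle scale of the vitamin E dose-response batch cultures:
#' asymptotic gas pool, fractional rate on the 9-point sampling grid, and
#' the protozoal bacterial-degradation slope. The published rate column
#' carries the fractional rate scaled by 1000; here it is a first-order
#' rate in 1/h.
#'
#' @return list with `gp_asymptote_ml`, `gp_rate_per_h`, `grid_h`,
#'   `protozoal_slope_pct_h`, `sed_protozoal_slope`.
#' @export
ref_batch_culture <- function() {
  list(
    gp_asymptote_ml       = 116,
    gp_rate_per_h         = 0.0645,
    grid_h                = c(2, 4, 6, 9, 12, 24, 48, 72, 96),
    protozoal_slope_pct_h = 9.95,
    sed_protozoal_slope   = 0.404
  )
}

#' Reference bacterial diversity treatment means
#'
#' Published per-treatment bacterial OTU diversity indices of the
#' Rusitec experiment (samples rarefied to a common depth of 10,572
#' reads; 971 OTUs overall).
#'
#' @return data.frame keyed by `treatment`.
#' @export
ref_diversity_means <- function() {
  data.frame(
    treatment = treatments4,
    richness  = c(632, 616, 688, 635),
    shannon   = c(4.68, 4.53, 5.07, 4.60),
    evenness  = c(0.77, 0.71, 0.78, 0.71),
    simpson   = c(0.97, 0.96, 0.98, 0.96),
    chao      = c(848, 802, 879, 905),
    goods     = c(0.71, 0.70, 0.73, 0.68),
    stringsAsFactors = FALSE
  )
}

#' Daily feed input of the Rusitec vessels
#'
#' 11.25 g DM/d at an 80:20 forage:concentrate ratio.
#'
#' @return list with `dm_intake_g_d` and `forage_fraction`.
#' @export
ref_feeding <- function() {
  list(dm_intake_g_d = 11.25, forage_fraction = 0.8)
}

#' Headline forage contrasts recomputed from the reference means
#'
#' Forage-effect contrasts (HAY vs GRA means, averaged over the vitamin E
#' levels) for the study's headline quantities: methane production,
#' microbial N outflow (microbial protein synthesis), NDF disappearance
#' and bacterial OTU richness. Percent contrasts are expressed relative
#' to the smaller group so each reads as the "+x%" gain quoted for the
#' favoured forage; richness is an absolute OTU difference.
#'
#' @return data.frame with columns `quantity`, `value`, `units`.
#' @export
headline_contrasts <- function() {
  fm <- ref_fermentation_means()
  om <- ref_outflow_means()
  dv <- ref_diversity_means()
  gra <- fm$treatment %in% c("GRA-", "GRA+")
  hay <- !gra
  pct <- function(num, den) 100 * (num - den) / den
  data.frame(
    quantity = c("methane_pct", "microbial_n_pct", "ndf_pct", "richness_otus"),
    value = c(
      pct(mean(fm$methane_mmol_d[hay]), mean(fm$methane_mmol_d[gra])),
      pct(mean(om$microbial_n[gra]), mean(om$microbial_n[hay])),
      pct(mean(fm$ndf_disappearance[hay]), mean(fm$ndf_disappearance[gra])),
      mean(dv$richness[hay]) - mean(dv$richness[gra])
    ),
    units = c("%", "%", "%", "OTUs"),
    stringsAsFactors = FALSE
  )
}
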