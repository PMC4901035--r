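# Synthetic-data generator. Emulates the study design end to end —
# 2x2 factorial (forage x vitamin E), 4 vessels per treatment, 2
# sampling time points, 4 inoculum animals — so that every analysis
# stage has inputs with the statistical structure it assumes, without
# any raw-data download. Every generator is a pure function of
# (config, seed).

#' Build a simulation configuration
#'
#' Defaults mirror the published treatment means of the Rusitec
#' experiment (fermentation, N flows, enrichment targets) and the
#' batch-culture scale (gas kinetics, protozoal release); vessel-level
#' noise reproduces the published SEDs, with per-vessel SD =
#' SED * sqrt(2) (SEDs were reported for differences of 4-vessel means).
#'
#' @param n_per_treatment vessels per treatment (default 4).
#' @param noise_sd_scale multiplier on all noise SDs; 0 gives
#'   noise-free output equal to the treatment means (default 1).
#' @param ammonia_enrichment 15N atom % excess of the labelled ammonia
#'   pool (default 0.5; the tracer ratios are scale-invariant).
#' @param gas overrides for the gas-curve generator: list with any of
#'   `A_ml`, `c_per_h`, `sigma_ml`, `grid_h`, `headspace_ml`,
#'   `ambient_kpa`, `n_bottles`, `n_blanks`, `blank_a_ml`,
#'   `blank_c_per_h`.
#' @param otu overrides for the OTU-table generator: list with any of
#'   `n_samples`, `n_otus`, `concentration`, `effect_fraction`,
#'   `fold_change`, `depth_range`.
#' @param release overrides for the 14C release assay: list with any
#'   of `slope_pct_h`, `intercept_pct`, `sigma_pct`, `times_h`,
#'   `n_tubes`.
#' @return nested list of class `simulation_config`.
#' @export
simulation_config <- function(n_per_treatment = 4, noise_sd_scale = 1,
                              ammonia_enrichment = 0.5,
                              gas = list(), otu = list(), release = list()) {
  check_nonnegative(noise_sd_scale, "noise_sd_scale")
  check_positive(n_per_treatment, "n_per_treatment")
  bc <- ref_batch_culture()
  om <- ref_outflow_means()
  fm <- ref_fermentation_means()
  gas_defaults <- list(
    A_ml = bc$gp_asymptote_ml, c_per_h = bc$gp_rate_per_h,
    sigma_ml = 1, grid_h = bc$grid_h,
    headspace_ml = 70, ambient_kpa = 101.325,
    n_bottles = 4, n_blanks = 4,
    blank_a_ml = 8, blank_c_per_h = 0.04
  )
  otu_defaults <- list(
    n_samples = 32, n_otus = 971, concentration = 50,
    effect_fraction = 0.1, fold_change = 4,
    depth_range = c(10000, 15000)
  )
  release_defaults <- list(
    slope_pct_h = bc$protozoal_slope_pct_h, intercept_pct = 2,
    sigma_pct = 0.3, times_h = 0:4, n_tubes = 4
  )
  cfg <- list(
    n_per_treatment = n_per_treatment,
    noise_sd_scale = noise_sd_scale,
    ammonia_enrichment = ammonia_enrichment,
    fermentation = fm,
    outflow = om,
    gas = modifyList(gas_defaults, gas),
    otu = modifyList(otu_defaults, otu),
    release = modifyList(release_defaults, release)
  )
  stopifnot(cfg$otu$depth_range[1] <= cfg$otu$depth_range[2],
            cfg$otu$fold_change > 0)
  structure(cfg, class = "simulation_config")
}

# Per-vessel SD from a published SED. SEDs were reported for
# differences of two means of 4 vessels (SED = s * sqrt(2/4)), so the
# vessel-level SD is SED * sqrt(2), whatever number of vessels is
# simulated.
sed_to_sd <- function(sed) sed * sqrt(2)

#' Simulate per-vessel fermentation, N-flow and enrichment tables
#'
#' Vessel-level draws are treatment mean + Normal noise (SD derived
#' from the published SEDs), truncated at zero for amounts. 15N
#' enrichments are generated backwards from the vessel's microbial
#' fraction and ammonia-derived share so that the tracer formulas
#' recover them exactly: bacterial = (share/100) * ammonia enrichment,
#' digesta NAN = fraction * bacterial.
#'
#' @param config a [simulation_config()].
#' @param seed RNG seed.
#' @return data.frame with one row per vessel: treatment, vessel id,
#'   the six VFA outflows (mmol/d), methane (mmol/d), NAN and ammonia-N
#'   outflows (mg/d), OM disappearance (fraction), the three 15N
#'   enrichments, and the generating `microbial_fraction_true` /
#'   `microbial_from_ammonia_true`.
#' @export
simulate_vessels <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_per_treatment
  s <- config$noise_sd_scale
  om <- config$outflow
  fm <- config$fermentation
  acids <- c("acetate", "propionate", "butyrate", "isobutyrate",
             "valerate", "isovalerate")
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(om)), function(i) {
      draw <- function(mean, sed) {
        pmax(rnorm(n, mean, s * sed_to_sd(sed)), 0)
      }
      vals <- lapply(acids, function(a) draw(om[[a]][i], om[[paste0("sed_", a)]][i]))
      names(vals) <- acids
      frac <- pmin(draw(om$microbial_n[i] / om$nan[i], 0.033), 1)
      share <- pmin(draw(om$microbial_from_ammonia[i], 2.47), 100)
      amm_e <- config$ammonia_enrichment
      bact_e <- share / 100 * amm_e
      data.frame(
        treatment = om$treatment[i],
        vessel = paste0(om$treatment[i], "_v", seq_len(n)),
        as.data.frame(vals),
        methane_mmol_d = draw(fm$methane_mmol_d[i], fm$sed_methane_mmol_d[i]),
        nan_mg_d = draw(om$nan[i], om$sed_nan),
        ammonia_mg_d = draw(om$ammonia_n[i], om$sed_ammonia_n),
        om_disappearance = pmin(draw(fm$om_disappearance[i] / 100,
                                     fm$sed_om_disappearance[i] / 100), 1),
        digesta_nan_enrichment = frac * bact_e,
        bacterial_enrichment = bact_e,
        ammonia_enrichment = amm_e,
        microbial_fraction_true = frac,
        microbial_from_ammonia_true = share,
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate pressure-transducer gas curves with blanks
#'
#' Cumulative volumes follow the single-pool exponential model plus a
#' small blank baseline and Normal noise; blank bottles carry the
#' baseline only. Volumes are inverted to vented incremental pressure
#' readings with the same ideal-gas convention used by
#' [pressure_to_volume()], so generation and analysis round-trip.
#'
#' @param config a [simulation_config()].
#' @param seed RNG seed.
#' @return list: `pressures` (data.frame bottle_id, is_blank, time_h,
#'   pressure_kpa), `truth` (data.frame bottle_id, A, c), plus the
#'   `headspace_ml` and `ambient_kpa` used.
#' @export
simulate_gas_curves <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  g <- config$gas
  check_positive(c(g$A_ml, g$c_per_h), "France parameters")
  s <- config$noise_sd_scale
  tt <- g$grid_h
  blank_curve <- g$blank_a_ml * (1 - exp(-g$blank_c_per_h * tt))
  to_pressures <- function(vol_cum) {
    diff(c(0, vol_cum)) * g$ambient_kpa / g$headspace_ml
  }
  with_seed(seed, {
    make <- function(id, is_blank) {
      mu <- if (is_blank) blank_curve
      else g$A_ml * (1 - exp(-g$c_per_h * tt)) + blank_curve
      vol <- pmax(mu + rnorm(length(tt), 0, s * g$sigma_ml), 0)
      data.frame(bottle_id = id, is_blank = is_blank, time_h = tt,
                 pressure_kpa = to_pressures(vol),
                 stringsAsFactors = FALSE)
    }
    press <- rbind(
      do.call(rbind, lapply(seq_len(g$n_bottles),
                            function(i) make(sprintf("bottle_%02d", i), FALSE))),
      do.call(rbind, lapply(seq_len(g$n_blanks),
                            function(i) make(sprintf("blank_%02d", i), TRUE)))
    )
    list(pressures = press,
         truth = data.frame(
           bottle_id = sprintf("bottle_%02d", seq_len(g$n_bottles)),
           A = g$A_ml, c = g$c_per_h, stringsAsFactors = FALSE),
         headspace_ml = g$headspace_ml, ambient_kpa = g$ambient_kpa)
  })
}

#' Simulate a Dirichlet-multinomial OTU table with metadata
#'
#' Base OTU proportions follow a long-tailed (gamma-generated) rank
#' abundance curve; a designated fraction of OTUs has its proportion
#' multiplied by `fold_change` in HAY samples (the treatment effect).
#' Per-sample compositions are Dirichlet draws around the group
#' proportions (concentration parameter controls overdispersion) and
#' counts are multinomial at a depth uniform in `depth_range`.
#' Metadata mirrors the study design: forage, vitamin E, time point and
#' inoculum animal.
#'
#' @param config a [simulation_config()].
#' @param seed RNG seed.
#' @return list: `counts` (samples x OTUs integer matrix), `metadata`
#'   (data.frame sample_id, forage, vitamin_e, time_point,
#'   inoculum_animal), `effect_otus` (character vector of the perturbed
#'   OTU ids).
#' @export
simulate_otu_table <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  o <- config$otu
  n_eff <- round(o$effect_fraction * o$n_otus)
  if (o$n_otus < n_eff) {
    stop_rusitecr("effect set larger than the OTU set",
                  "rusitecr_validation_error")
  }
  with_seed(seed, {
    base <- sort(rgamma(o$n_otus, shape = 0.5), decreasing = TRUE)
    base <- base / sum(base)
    eff_idx <- if (n_eff > 0) sample.int(o$n_otus, n_eff) else integer(0)
    p_hay <- base
    p_hay[eff_idx] <- p_hay[eff_idx] * o$fold_change
    p_hay <- p_hay / sum(p_hay)
    groups <- list(GRA = base, HAY = p_hay)
    meta <- data.frame(
      sample_id = sprintf("sample_%02d", seq_len(o$n_samples)),
      forage = rep(c("GRA", "HAY"), length.out = o$n_samples),
      vitamin_e = rep(c("-", "-", "+", "+"), length.out = o$n_samples),
      time_point = rep(c("4h", "24h"), each = 4, length.out = o$n_samples),
      inoculum_animal = paste0("cow", rep(1:4, each = 8,
                                          length.out = o$n_samples)),
      stringsAsFactors = FALSE
    )
    counts <- t(vapply(seq_len(o$n_samples), function(i) {
      p <- groups[[meta$forage[i]]]
      lambda <- rgamma(o$n_otus, shape = o$concentration * p, rate = 1)
      if (sum(lambda) == 0) lambda <- p
      depth <- round(runif(1, o$depth_range[1], o$depth_range[2]))
      as.integer(rmultinom(1, depth, lambda / sum(lambda)))
    }, integer(o$n_otus)))
    rownames(counts) <- meta$sample_id
    colnames(counts) <- sprintf("OTU_%04d", seq_len(o$n_otus))
    list(counts = counts, metadata = meta,
         effect_otus = colnames(counts)[sort(eff_idx)])
  })
}

#' Simulate 14C bacterial-release assay tubes
#'
#' Percent of labelled inoculum released = intercept + slope * t +
#' Normal noise, clipped to \[0, 100\].
#'
#' @param config a [simulation_config()].
#' @param seed RNG seed.
#' @return data.frame: tube_id, time_h, released_pct.
#' @export
simulate_release_assay <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  r <- config$release
  check_nonnegative(r$slope_pct_h, "slope")
  s <- config$noise_sd_scale
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(r$n_tubes), function(i) {
      y <- r$intercept_pct + r$slope_pct_h * r$times_h +
        rnorm(length(r$times_h), 0, s * r$sigma_pct)
      data.frame(tube_id = sprintf("tube_%02d", i), time_h = r$times_h,
                 released_pct = pmin(pmax(y, 0), 100),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}
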