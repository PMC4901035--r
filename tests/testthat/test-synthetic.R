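# Synthetic-data generators: determinism, noise-free round trips,
# statistical fidelity to the configured treatment structure.

test_that("generators are pure functions of (config, seed)", {
  cfg <- simulation_config(otu = list(n_samples = 8, n_otus = 40,
                                      depth_range = c(500, 800)))
  expect_identical(simulate_vessels(cfg, seed = 2),
                   simulate_vessels(cfg, seed = 2))
  expect_identical(simulate_gas_curves(cfg, seed = 2),
                   simulate_gas_curves(cfg, seed = 2))
  expect_identical(simulate_otu_table(cfg, seed = 2),
                   simulate_otu_table(cfg, seed = 2))
  expect_identical(simulate_release_assay(cfg, seed = 2),
                   simulate_release_assay(cfg, seed = 2))
  expect_false(identical(simulate_vessels(cfg, seed = 2),
                         simulate_vessels(cfg, seed = 3)))
})

test_that("noise-free vessels equal their treatment means", {
  cfg <- simulation_config(noise_sd_scale = 0)
  v <- simulate_vessels(cfg, seed = 1)
  om <- ref_outflow_means()
  fm <- ref_fermentation_means()
  expect_equal(nrow(v), 16)
  for (tr in om$treatment) {
    rows <- v[v$treatment == tr, ]
    expect_equal(rows$acetate, rep(om$acetate[om$treatment == tr], 4))
    expect_equal(rows$methane_mmol_d,
                 rep(fm$methane_mmol_d[fm$treatment == tr], 4))
    expect_equal(rows$nan_mg_d, rep(om$nan[om$treatment == tr], 4))
  }
})

test_that("noisy vessel means converge to the configured means", {
  cfg <- simulation_config(n_per_treatment = 1000)
  v <- simulate_vessels(cfg, seed = 6)
  om <- ref_outflow_means()
  gra <- v[v$treatment == "GRA-", ]
  n <- nrow(gra)
  for (col in c("acetate", "propionate", "butyrate")) {
    sed <- om[[paste0("sed_", col)]][1]
    sd_v <- sed * sqrt(2)
    expect_lt(abs(mean(gra[[col]]) - om[[col]][1]), 3 * sd_v / sqrt(n))
  }
})

test_that("noise-free gas curves round-trip through the analysis stage", {
  cfg <- simulation_config(noise_sd_scale = 0,
                           gas = list(n_bottles = 2, n_blanks = 2))
  sim <- simulate_gas_curves(cfg, seed = 1)
  by_bottle <- split(sim$pressures, sim$pressures$bottle_id)
  curves <- lapply(by_bottle, function(b) {
    pressure_to_volume(pressure_series(b$bottle_id[1], b$time_h,
                                       b$pressure_kpa,
                                       sim$headspace_ml, sim$ambient_kpa))
  })
  blanks <- curves[vapply(by_bottle, function(b) b$is_blank[1], logical(1))]
  samples <- curves[vapply(by_bottle, function(b) !b$is_blank[1], logical(1))]
  for (cu in samples) {
    fit <- fit_france(blank_correct(cu, blanks))
    expect_equal(fit$A, cfg$gas$A_ml, tolerance = 1e-6)
    expect_equal(fit$c, cfg$gas$c_per_h, tolerance = 1e-6)
  }
  # blank-only bottles are flat after correction
  for (bl in blanks) {
    corrected <- blank_correct(bl, blanks)
    expect_true(all(abs(corrected$volume_ml) < 1e-9))
  }
})

test_that("asymptote estimation stays unbiased under measurement noise", {
  cfg <- simulation_config(gas = list(n_bottles = 1, n_blanks = 0,
                                      blank_a_ml = 0))
  a_hat <- vapply(1:60, function(s) {
    sim <- simulate_gas_curves(cfg, seed = 100 + s)
    b <- sim$pressures
    fit <- fit_france(pressure_to_volume(
      pressure_series(b$bottle_id[1], b$time_h, b$pressure_kpa,
                      sim$headspace_ml, sim$ambient_kpa)))
    fit$A
  }, numeric(1))
  expect_lt(abs(mean(a_hat) - cfg$gas$A_ml) / cfg$gas$A_ml, 0.02)
})

test_that("OTU tables follow the configured design and depth range", {
  cfg <- simulation_config(otu = list(n_samples = 16, n_otus = 50,
                                      effect_fraction = 0.2, fold_change = 4,
                                      depth_range = c(1000, 1500)))
  sim <- simulate_otu_table(cfg, seed = 12)
  expect_equal(dim(sim$counts), c(16, 50))
  expect_true(all(rowSums(sim$counts) >= 1000 &
                    rowSums(sim$counts) <= 1500))
  expect_true(all(sim$counts >= 0))
  expect_equal(length(sim$effect_otus), 10)
  expect_equal(nrow(sim$metadata), 16)
  expect_setequal(unique(sim$metadata$forage), c("GRA", "HAY"))
  # effect OTUs are enriched in the HAY group
  hay <- sim$metadata$forage == "HAY"
  rel <- sweep(sim$counts, 1, rowSums(sim$counts), "/")
  eff_share <- rowSums(rel[, sim$effect_otus, drop = FALSE])
  expect_gt(mean(eff_share[hay]), mean(eff_share[!hay]))
})

test_that("release assay is noise-free exact and clipped to [0, 100]", {
  cfg0 <- simulation_config(noise_sd_scale = 0)
  tube <- simulate_release_assay(cfg0, seed = 1)
  one <- tube[tube$tube_id == "tube_01", ]
  expect_equal(release_rate(one$time_h, one$released_pct)$slope,
               cfg0$release$slope_pct_h, tolerance = 1e-12)
  cfg_hi <- simulation_config(release = list(intercept_pct = 99,
                                             slope_pct_h = 30))
  hi <- simulate_release_assay(cfg_hi, seed = 2)
  expect_true(all(hi$released_pct <= 100 & hi$released_pct >= 0))
})
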