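# Z capacities, D conductances, and the Level I-III solutions.

test_that("fugacity capacities follow the closed forms", {
  env <- taiwan_env()
  ch <- test_chemical(log_kaw = -1.7, reference_temperature = 295.15)
  z <- compute_z(ch, env)
  # Z_air = 1/(R T) at 295.15 K
  expect_equal(z$pure[["air"]], 4.075183e-4, tolerance = 1e-6)
  # Z_water = Z_air / K_AW
  expect_equal(z$pure[["water"]], z$pure[["air"]] / 10^-1.7, tolerance = 1e-12)
  # K_AW = 1 collapses air and water capacities
  ch1 <- test_chemical(log_kaw = 0, reference_temperature = 295.15)
  z1 <- compute_z(ch1, env)
  expect_equal(z1$pure[["water"]], z1$pure[["air"]])
  # solid-phase Z from Koc, foc, density
  expect_equal(z$pure[["soil_solids"]],
               z$pure[["water"]] * koc_from_kow(6) * 0.0121 * 2.4,
               tolerance = 1e-12)
  # bulk Z bracketed by its constituents
  for (b in z$bulk) {
    expect_gte(b, min(z$pure) * (1 - 1e-12))
    expect_lte(b, max(z$pure) * (1 + 1e-12))
  }
  expect_true(all(z$pure > 0) && all(z$bulk > 0))
})

test_that("Level I distributes by Z V and conserves the input amount", {
  env <- taiwan_env()
  ch <- test_chemical()
  res <- level1(ch, env, total_amount = 100)
  expect_equal(sum(res$mass_mol), 100, tolerance = 1e-12)
  expect_true(all(res$share >= 0 & res$share <= 1))
  expect_equal(sum(res$share), 1, tolerance = 1e-12)
  # the highest concentration sits where bulk Z is highest
  z <- compute_z(ch, env)
  expect_equal(names(which.max(res$concentration)), names(which.max(z$bulk)))
  # shares are proportional to Z V
  vols <- vapply(env$compartments, function(x) x$volume, numeric(1))
  zv <- z$bulk * vols[names(z$bulk)]
  expect_equal(unname(res$share), unname(zv / sum(zv)), tolerance = 1e-12)
  expect_error(level1(ch, env, 0), "invalid-input")
})

test_that("reaction and advection D-values are plain arithmetic", {
  env <- taiwan_env()
  ch <- test_chemical(reference_temperature = 295.15,
                      half_life = c(air = 693.1, water = 693.1,
                                    soil = 693.1, sediment = 693.1))
  z <- compute_z(ch, env)
  d <- compute_d_values(ch, env, z)
  # D_reaction = V Z_bulk ln2 / half-life; soil V = 1e9
  expect_equal(d$reaction[["soil"]],
               1e9 * z$bulk[["soil"]] * log(2) / 693.1, tolerance = 1e-12)
  # with Z_bulk = 1 this is the canonical 1e9 ln2/693.1 ~ 1.0e6 check
  expect_equal(1e9 * log(2) / 693.1, 1.000068e6, tolerance = 1e-6)
  # advection D = (V / tau) Z_bulk for air and water only
  expect_equal(d$advection[["air"]], 1e13 / 100 * z$bulk[["air"]], tolerance = 1e-12)
  expect_equal(d$advection[["water"]], 1.75e11 / 1000 * z$bulk[["water"]],
               tolerance = 1e-12)
  expect_equal(d$advection[["soil"]], 0)
  expect_equal(d$advection[["sediment"]], 0)
  expect_true(all(d$transfer >= 0))
})

test_that("air-side D terms vanish without rain, aerosol, or MTCs", {
  env <- taiwan_env()
  env$transport$rain_rate <- 0
  env$transport$aerosol_dry_deposition_velocity <- 0
  env$transport$mtc_air_water <- 0
  env$transport$mtc_air_soil <- 0
  ch <- test_chemical()
  z <- compute_z(ch, env)
  d <- compute_d_values(ch, env, z)
  expect_equal(d$transfer["air", "water"], 0)
  expect_equal(d$transfer["water", "air"], 0)
  expect_equal(d$transfer["air", "soil"], 0)
  expect_equal(d$transfer["soil", "air"], 0)
})

test_that("doubling the MTCs doubles diffusive D but not reaction/advection", {
  env <- taiwan_env()
  ch <- test_chemical()
  z <- compute_z(ch, env)
  d1 <- compute_d_values(ch, env, z)
  env2 <- env
  for (p in c("mtc_air_water", "mtc_water", "mtc_air_soil", "mtc_soil_air",
              "mtc_soil_water", "mtc_sediment_water"))
    env2$transport[[p]] <- 2 * env$transport[[p]]
  d2 <- compute_d_values(ch, env2, z)
  # purely diffusive directed pairs double exactly
  expect_equal(d2$transfer["water", "air"], 2 * d1$transfer["water", "air"])
  expect_equal(d2$transfer["soil", "air"], 2 * d1$transfer["soil", "air"])
  diff_sed <- env$transport$mtc_sediment_water * 5e9 * z$pure[["water"]]
  expect_equal(d2$transfer["water", "sediment"] - d1$transfer["water", "sediment"],
               diff_sed, tolerance = 1e-9)
  expect_equal(d2$reaction, d1$reaction)
  expect_equal(d2$advection, d1$advection)
  expect_equal(d2$burial, d1$burial)
})

test_that("missing transport parameters are named in the error", {
  env <- taiwan_env()
  env$transport$scavenging_ratio <- NA_real_
  ch <- test_chemical()
  z <- compute_z(ch, env)
  expect_error(compute_d_values(ch, env, z), "scavenging_ratio")
})

test_that("Level II matches the single-box analytic solution", {
  # one effective compartment: strip advection from water, make everything
  # except air negligible by construction, then f = E / D_reaction.
  env <- taiwan_env()
  ch <- test_chemical()
  res <- level2(ch, env, emission_total = 1)
  z <- compute_z(ch, env)
  d <- compute_d_values(ch, env, z)
  f_expected <- 1 / (sum(d$reaction) + sum(d$advection) + d$burial)
  expect_equal(res$fugacity, f_expected, tolerance = 1e-12)
  # linearity: doubling E doubles mass, residence time unchanged
  res2 <- level2(ch, env, emission_total = 2)
  expect_equal(res2$total_mass_mol, 2 * res$total_mass_mol, tolerance = 1e-12)
  expect_equal(res2$tau_overall, res$tau_overall, tolerance = 1e-12)
  # residence-time composition 1/tau = 1/tau_rxn + 1/tau_adv
  expect_equal(1 / res$tau_overall,
               1 / res$tau_reaction + 1 / res$tau_advection, tolerance = 1e-12)
  # advection disabled -> tau = tau_reaction
  env0 <- env
  env0$compartments$air$advective_residence_time <- Inf
  env0$compartments$water$advective_residence_time <- Inf
  env0$transport$sediment_burial_rate <- 0
  res0 <- level2(ch, env0, 1)
  expect_equal(res0$tau_overall, res0$tau_reaction, tolerance = 1e-12)
})

test_that("Level III solves degenerate and symmetric cases exactly", {
  env <- taiwan_env()
  ch <- test_chemical()
  z <- compute_z(ch, env)
  d <- compute_d_values(ch, env, z)
  # reaction-only single compartment: f = E / D_reaction
  d0 <- d
  d0$transfer[] <- 0
  d0$advection[] <- 0
  d0$burial <- 0
  st <- level3(c(air = 1), d0, z, env)
  expect_equal(st$fugacity[["air"]], 1 / d0$reaction[["air"]], tolerance = 1e-12)
  expect_equal(unname(st$fugacity[c("water", "soil", "sediment")]), rep(0, 3))
  # two identical symmetrically coupled compartments get equal fugacities
  ds <- d0
  ds$reaction[] <- c(5, 5, 1, 1)
  ds$transfer["air", "water"] <- 3
  ds$transfer["water", "air"] <- 3
  st2 <- level3(c(air = 1, water = 1), ds, z, env)
  expect_equal(st2$fugacity[["air"]], st2$fugacity[["water"]], tolerance = 1e-12)
  # errors
  expect_error(level3(c(air = -1), d, z, env), "invalid-input")
  expect_error(level3(c(air = 0), d, z, env), "invalid-input")
  dz <- d0; dz$reaction[] <- 0
  expect_error(level3(c(air = 1), dz, z, env), "no-steady-state")
})

test_that("the flux ledger closes the mass balance", {
  env <- taiwan_env()
  ch <- test_chemical()
  z <- compute_z(ch, env)
  d <- compute_d_values(ch, env, z)
  st <- level3(c(air = 1, water = 0.1, soil = 0.3), d, z, env)
  led <- flux_ledger(st, d, molar_mass = ch$molar_mass)
  total_in <- sum(led$flux_mol_h[led$type == "emission"])
  total_out <- sum(led$flux_mol_h[led$to == "loss"])
  expect_equal(total_out, total_in, tolerance = 1e-9)
  expect_equal(sum(led$pct_of_total_input[led$to == "loss"]), 100,
               tolerance = 1e-7)
  # every compartment's outgoing flows sum to 100 % of its gross input
  for (cmp in c("air", "water", "soil", "sediment")) {
    out_pct <- sum(led$pct_of_compartment_input[led$from == cmp])
    expect_equal(out_pct, 100, tolerance = 1e-7)
  }
  # kg/h column is the molar flux scaled by molar mass
  expect_equal(led$flux_kg_h, led$flux_mol_h * ch$molar_mass / 1000)
  # disabling burial removes the pathway and re-normalizes percentages
  env2 <- env; env2$transport$sediment_burial_rate <- 0
  d2 <- compute_d_values(ch, env2, z)
  st2 <- level3(c(air = 1, water = 0.1, soil = 0.3), d2, z, env2)
  led2 <- flux_ledger(st2, d2)
  expect_false("burial_sediment" %in% led2$pathway)
  expect_equal(sum(led2$pct_of_total_input[led2$to == "loss"]), 100,
               tolerance = 1e-7)
})

test_that("spin-up time is the standing mass over the input rate", {
  expect_equal(time_to_steady_state(0, 1), 0)
  expect_equal(time_to_steady_state(352, 113.94e-3), 3089.3, tolerance = 1e-4)
  expect_equal(time_to_steady_state(2 * 352, 113.94e-3),
               2 * time_to_steady_state(352, 113.94e-3))
  expect_error(time_to_steady_state(10, 0), "invalid-input")
})
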