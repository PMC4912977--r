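# Fugacity engine: Z capacities, D conductances, Level I/II/III solutions,
# and the steady-state flux ledger.
#
# Internal unit system: mol, Pa, m3, hours. Z in mol/(m3 Pa); D in
# mol/(Pa h); fugacity in Pa. kg and field reporting units appear only at
# the reporting boundary (see concentration_table / flux_ledger).

#' Fugacity capacities for a chemical in an environment
#'
#' Pure-phase capacities: `Z_air = 1/(R T)`; `Z_water = Z_air / KAW`;
#' solid phases (soil solids, sediment solids, suspended solids)
#' `Z = Z_water * Koc * foc * rho/1000` with `Koc = 0.41 Kow`; aerosol
#' `Z = Z_air * KOA * foc_aerosol` (octanol-air sorption convention, the
#' air compartment's `foc` acting as the organic-matter fraction of the
#' particles). Bulk capacities are the volume-fraction-weighted sums over
#' each compartment's sub-phases.
#'
#' The chemical is first re-expressed at the environment temperature via
#' [chemical_at_temperature()].
#'
#' @param chem A [chemical_properties()] record.
#' @param env A [fate_environment()].
#' @return An object of class `zset` with elements `pure` (named vector:
#'   air, water, aerosol, soil_solids, sediment_solids, suspended_solids)
#'   and `bulk` (named vector over the four compartments), mol/(m3 Pa).
#' @export
compute_z <- function(chem, env) {
  stopifnot(inherits(chem, "chem_properties"), inherits(env, "fate_environment"))
  chem <- chemical_at_temperature(chem, env$temperature)
  t <- env$temperature
  kaw <- 10^chem$log_kaw
  if (!is.finite(kaw) || kaw <= 0)
    stop("invalid-property: K_AW must be positive")
  cp <- env$compartments
  z_air <- 1 / (R_GAS * t)
  z_water <- z_air / kaw
  koc <- koc_from_kow(chem$log_kow)
  z_solid <- function(comp) z_water * koc * comp$foc * comp$solids_density / 1000
  pure <- c(
    air = z_air,
    water = z_water,
    aerosol = z_air * 10^chem$log_koa * cp$air$foc,
    soil_solids = z_solid(cp$soil),
    sediment_solids = z_solid(cp$sediment),
    suspended_solids = z_solid(cp$water)
  )
  frac <- function(comp, phase) {
    f <- comp$subphase_volume_fractions
    if (phase %in% names(f)) unname(f[[phase]]) else 0
  }
  v_q <- frac(cp$air, "solids")
  v_s <- frac(cp$water, "solids")
  bulk <- c(
    air = (1 - v_q) * z_air + v_q * pure[["aerosol"]],
    water = (1 - v_s) * z_water + v_s * pure[["suspended_solids"]],
    soil = frac(cp$soil, "air") * z_air + frac(cp$soil, "water") * z_water +
      frac(cp$soil, "solids") * pure[["soil_solids"]],
    sediment = frac(cp$sediment, "water") * z_water +
      frac(cp$sediment, "air") * z_air +
      frac(cp$sediment, "solids") * pure[["sediment_solids"]]
  )
  structure(list(pure = pure, bulk = bulk, temperature = t), class = "zset")
}

#' Intermedia transport and loss D-values
#'
#' Builds the directed conductances (mol/(Pa h)) of the four-compartment
#' mass balance from the two-film/deposition constructions:
#' \itemize{
#'   \item air-water: series two-film diffusion both ways; rain dissolution
#'     and wet/dry aerosol deposition air-to-water only;
#'   \item air-soil: diffusion through an air boundary layer in series with
#'     parallel air- and water-phase soil diffusion, both ways; rain and
#'     aerosol deposition air-to-soil only;
#'   \item water-sediment: diffusion both ways; suspended-solids deposition
#'     water-to-sediment; resuspension sediment-to-water;
#'   \item soil-water: water runoff plus solids erosion;
#'   \item losses: reaction `V Z_bulk ln2 / half_life` per compartment;
#'     advection `(V / tau) Z_bulk` for air and water; sediment burial
#'     `U_burial A Z_sediment_solids`.
#' }
#'
#' @param chem A [chemical_properties()] record.
#' @param env A [fate_environment()].
#' @param z A [compute_z()] result for the same chemical and environment.
#' @return An object of class `dmatrix`: `transfer` (4 x 4 matrix, entry
#'   \[from, to\]), `reaction` and `advection` (named vectors), `burial`
#'   (scalar).
#' @export
compute_d_values <- function(chem, env, z) {
  stopifnot(inherits(z, "zset"))
  chem <- chemical_at_temperature(chem, env$temperature)
  cp <- env$compartments
  tp <- env$transport
  needed <- names(formals(transport_parameters))
  missing <- needed[!vapply(needed, function(p) is.finite(tp[[p]]), logical(1))]
  if (length(missing))
    stop("configuration error: transport parameter(s) missing or non-finite: ",
         paste(missing, collapse = ", "))
  zp <- z$pure
  a_w <- cp$water$area; a_s <- cp$soil$area; a_sed <- cp$sediment$area
  v_q <- {
    f <- cp$air$subphase_volume_fractions
    if ("solids" %in% names(f)) f[["solids"]] else 0
  }

  series <- function(d1, d2) if (d1 <= 0 || d2 <= 0) 0 else 1 / (1 / d1 + 1 / d2)

  # air <-> water
  d_vol <- series(tp$mtc_air_water * a_w * zp[["air"]],
                  tp$mtc_water * a_w * zp[["water"]])
  dep_terms <- function(area) {
    rain_dissolution <- tp$rain_rate * area * zp[["water"]]
    wet_particles <- tp$rain_rate * tp$scavenging_ratio * v_q * area * zp[["aerosol"]]
    dry_particles <- tp$aerosol_dry_deposition_velocity * v_q * area * zp[["aerosol"]]
    rain_dissolution + wet_particles + dry_particles
  }
  d_aw <- d_vol + dep_terms(a_w)
  d_wa <- d_vol

  # air <-> soil
  d_boundary <- tp$mtc_air_soil * a_s * zp[["air"]]
  d_soil_path <- tp$mtc_soil_air * a_s * zp[["air"]] +
    tp$mtc_soil_water * a_s * zp[["water"]]
  d_diff_soil <- series(d_boundary, d_soil_path)
  d_as <- d_diff_soil + dep_terms(a_s)
  d_sa <- d_diff_soil

  # water <-> sediment
  d_diff_sed <- tp$mtc_sediment_water * a_sed * zp[["water"]]
  d_ws <- d_diff_sed + tp$sediment_deposition_rate * a_sed * zp[["suspended_solids"]]
  d_sw <- d_diff_sed + tp$sediment_resuspension_rate * a_sed * zp[["sediment_solids"]]

  # soil -> water
  d_soil_water <- tp$soil_water_runoff_rate * a_s * zp[["water"]] +
    tp$soil_solids_runoff_rate * a_s * zp[["soil_solids"]]

  transfer <- matrix(0, 4, 4, dimnames = list(COMPARTMENTS, COMPARTMENTS))
  transfer["air", "water"] <- d_aw
  transfer["water", "air"] <- d_wa
  transfer["air", "soil"] <- d_as
  transfer["soil", "air"] <- d_sa
  transfer["water", "sediment"] <- d_ws
  transfer["sediment", "water"] <- d_sw
  transfer["soil", "water"] <- d_soil_water

  vols <- vapply(cp, function(x) x$volume, numeric(1))
  reaction <- vols * z$bulk * log(2) / chem$half_life[COMPARTMENTS]
  names(reaction) <- COMPARTMENTS
  adv_tau <- vapply(cp, function(x) x$advective_residence_time, numeric(1))
  advection <- ifelse(is.na(adv_tau), 0, vols / adv_tau * z$bulk)
  names(advection) <- COMPARTMENTS
  burial <- tp$sediment_burial_rate * a_sed * zp[["sediment_solids"]]

  structure(list(transfer = transfer, reaction = reaction,
                 advection = advection, burial = unname(burial)),
            class = "dmatrix")
}

.total_loss_d <- function(d) sum(d$reaction) + sum(d$advection) + d$burial

.outgoing_d <- function(d) {
  loss <- d$reaction + d$advection
  loss[["sediment"]] <- loss[["sediment"]] + d$burial
  rowSums(d$transfer) + loss
}

#' Level I: closed-system equilibrium distribution
#'
#' A fixed chemical amount distributes over the compartments at a single
#' common fugacity `f = total / sum(Z_bulk V)`; compartment i holds the
#' share `Z_i V_i / sum(Z_j V_j)`.
#'
#' @param chem A [chemical_properties()] record.
#' @param env A [fate_environment()].
#' @param total_amount Total amount in the system, mol (> 0).
#' @return List: `fugacity` (Pa), `mass_mol`, `mass_kg`, `share` (fractions
#'   summing to 1), `concentration` (bulk, mol/m3), per compartment.
#' @export
level1 <- function(chem, env, total_amount) {
  if (!is.finite(total_amount) || total_amount <= 0)
    stop("invalid-input: total_amount must be > 0")
  z <- compute_z(chem, env)
  vols <- vapply(env$compartments, function(x) x$volume, numeric(1))[COMPARTMENTS]
  zv <- z$bulk * vols
  if (sum(zv) <= 0) stop("invalid-input: empty environment (sum Z V = 0)")
  f <- total_amount / sum(zv)
  mass <- zv * f
  list(fugacity = f, mass_mol = mass,
       mass_kg = mass * chem$molar_mass / 1000,
       share = mass / total_amount,
       concentration = z$bulk * f)
}

#' Level II: equilibrium steady state with degradation and advection
#'
#' Chemical enters at a constant rate and the whole system stays at one
#' fugacity: `f = E / (sum D_reaction + sum D_advection + D_burial)`.
#' Residence times satisfy `1/tau = 1/tau_reaction + 1/tau_advection`
#' (burial counted with the advective, non-reactive removals).
#'
#' @param chem A [chemical_properties()] record.
#' @param env A [fate_environment()].
#' @param emission_total Total input rate, mol/h (> 0).
#' @return List: `fugacity`, `mass_mol` and `mass_kg` per compartment,
#'   `total_mass_mol`, loss rates per mechanism, and residence times
#'   `tau_overall`, `tau_reaction`, `tau_advection` (hours).
#' @export
level2 <- function(chem, env, emission_total) {
  if (!is.finite(emission_total) || emission_total <= 0)
    stop("invalid-input: emission_total must be > 0")
  z <- compute_z(chem, env)
  d <- compute_d_values(chem, env, z)
  d_rxn <- sum(d$reaction)
  d_adv <- sum(d$advection) + d$burial
  if (d_rxn + d_adv <= 0)
    stop("no-steady-state: all loss D-values are zero")
  f <- emission_total / (d_rxn + d_adv)
  vols <- vapply(env$compartments, function(x) x$volume, numeric(1))[COMPARTMENTS]
  mass <- z$bulk * vols * f
  m_tot <- sum(mass)
  list(fugacity = f,
       mass_mol = mass,
       mass_kg = mass * chem$molar_mass / 1000,
       total_mass_mol = m_tot,
       loss_reaction = d_rxn * f,
       loss_advection = d_adv * f,
       tau_overall = m_tot / emission_total,
       tau_reaction = if (d_rxn > 0) m_tot / (d_rxn * f) else Inf,
       tau_advection = if (d_adv > 0) m_tot / (d_adv * f) else Inf)
}

#' Level III: non-equilibrium steady state
#'
#' Solves the four-compartment linear balance: for each compartment,
#' emission plus incoming intermedia flows equals fugacity times the sum of
#' outgoing intermedia and loss conductances. Fugacities may differ between
#' compartments; the departure from a common value measures how far the
#' system is from equilibrium.
#'
#' @param emissions Named vector of emission rates, mol/h, per compartment
#'   (missing names taken as 0); all >= 0 and not all zero.
#' @param d A [compute_d_values()] result.
#' @param z The matching [compute_z()] result.
#' @param env The matching [fate_environment()].
#' @return An object of class `steady_state`: `fugacity` (Pa), `mass_mol`,
#'   `concentration` (bulk mol/m3), `total_input_mol_h`, `residual`
#'   (largest relative per-compartment balance error), `d`, `z`, `env`.
#' @export
level3 <- function(emissions, d, z, env) {
  stopifnot(inherits(d, "dmatrix"), inherits(z, "zset"))
  e <- stats::setNames(numeric(4), COMPARTMENTS)
  e[names(emissions)] <- emissions
  if (any(e < 0)) stop("invalid-input: emissions must be >= 0")
  if (all(e == 0)) stop("invalid-input: at least one emission must be positive")
  if (.total_loss_d(d) <= 0)
    stop("no-steady-state: system has no loss pathway")

  out <- .outgoing_d(d)
  a <- diag(out) - t(d$transfer)
  dimnames(a) <- list(COMPARTMENTS, COMPARTMENTS)
  f <- tryCatch(solve(a, e),
                error = function(err) stop("no-steady-state: singular balance matrix (",
                                           conditionMessage(err), ")"))
  if (any(f < -1e-12 * max(abs(f))))
    stop("no-steady-state: negative fugacity in solution")
  f <- pmax(f, 0)
  # per-compartment balance error relative to the gross flux magnitude
  # through that compartment (backward error of the linear balance)
  scale <- as.vector(abs(a) %*% abs(f)) + e
  residual <- max(abs(a %*% f - e)[scale > 0] / scale[scale > 0])
  if (residual > 1e-9)
    warning(sprintf("level3: balance residual %.3g exceeds 1e-9 relative", residual))
  vols <- vapply(env$compartments, function(x) x$volume, numeric(1))[COMPARTMENTS]
  mass <- z$bulk * vols * f
  structure(list(fugacity = f, mass_mol = mass,
                 concentration = z$bulk * f,
                 total_input_mol_h = sum(e),
                 emissions = e,
                 residual = residual,
                 d = d, z = z, env = env),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat("<steady_state> fugacity (Pa):\n")
  print(signif(x$fugacity, 4))
  cat("mass (mol):\n")
  print(signif(x$mass_mol, 4))
  cat(sprintf("input %.4g mol/h | residual %.2g\n", x$total_input_mol_h, x$residual))
  invisible(x)
}

#' Steady-state flux ledger
#'
#' Itemizes every pathway flux at steady state: emissions, the seven
#' intermedia transfers, per-compartment reaction, air and water advection,
#' and sediment burial. Each flow is reported in mol/h (and kg/h when a
#' molar mass is available) together with two explicitly labelled
#' percentage bases: share of total system input, and share of the source
#' compartment's gross input (emission + incoming transfers).
#'
#' @param state A [level3()] result.
#' @param d The [compute_d_values()] result used in the solve (defaults to
#'   the one stored on `state`).
#' @param molar_mass Optional molar mass, g/mol, for kg/h reporting.
#' @return A data.frame with columns `pathway`, `type`, `from`, `to`,
#'   `flux_mol_h`, `flux_kg_h`, `pct_of_total_input`,
#'   `pct_of_compartment_input`.
#' @export
flux_ledger <- function(state, d = state$d, molar_mass = NA_real_) {
  stopifnot(inherits(state, "steady_state"))
  f <- state$fugacity
  rows <- list()
  add <- function(pathway, type, from, to, flux) {
    rows[[length(rows) + 1L]] <<- data.frame(
      pathway = pathway, type = type, from = from, to = to,
      flux_mol_h = flux, stringsAsFactors = FALSE)
  }
  for (i in COMPARTMENTS)
    if (state$emissions[[i]] > 0)
      add(paste0("emission_", i), "emission", "source", i, state$emissions[[i]])
  for (i in COMPARTMENTS) for (j in COMPARTMENTS)
    if (d$transfer[i, j] > 0)
      add(paste0(i, "_to_", j), "transfer", i, j, d$transfer[i, j] * f[[i]])
  for (i in COMPARTMENTS)
    if (d$reaction[[i]] > 0)
      add(paste0("reaction_", i), "reaction", i, "loss", d$reaction[[i]] * f[[i]])
  for (i in c("air", "water"))
    if (d$advection[[i]] > 0)
      add(paste0("advection_", i), "advection", i, "loss", d$advection[[i]] * f[[i]])
  if (d$burial > 0)
    add("burial_sediment", "burial", "sediment", "loss", d$burial * f[["sediment"]])
  ledger <- do.call(rbind, rows)

  total_in <- state$total_input_mol_h
  gross_in <- state$emissions
  for (i in COMPARTMENTS)
    gross_in[[i]] <- gross_in[[i]] + sum(d$transfer[, i] * f)
  ledger$flux_kg_h <- ledger$flux_mol_h * molar_mass / 1000
  ledger$pct_of_total_input <- 100 * ledger$flux_mol_h / total_in
  ledger$pct_of_compartment_input <- ifelse(
    ledger$from %in% COMPARTMENTS,
    100 * ledger$flux_mol_h / gross_in[ledger$from],
    NA_real_)
  ledger[, c("pathway", "type", "from", "to", "flux_mol_h", "flux_kg_h",
             "pct_of_total_input", "pct_of_compartment_input")]
}

#' Time to approach steady state
#'
#' The spin-up estimator: total standing mass divided by the total input
#' rate.
#'
#' @param total_mass Standing mass, kg (>= 0).
#' @param input_rate Input rate, kg/h (> 0).
#' @return Hours.
#' @export
time_to_steady_state <- function(total_mass, input_rate) {
  if (!is.finite(input_rate) || input_rate <= 0)
    stop("invalid-input: input_rate must be > 0")
  if (any(total_mass < 0)) stop("invalid-input: total_mass must be >= 0")
  total_mass / input_rate
}
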