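# Physicochemical property handling: partition-coefficient triangle,
# Koc from Kow, and temperature adjustment of half-lives and K values.

#' Ideal gas constant, J/(mol K)
#' @keywords internal
R_GAS <- 8.314

COMPARTMENTS <- c("air", "water", "soil", "sediment")

#' Create a chemical property record
#'
#' Holds one compound's physicochemical inputs at a stated reference
#' temperature: molar mass, the log10 partition coefficients (KOW, KAW and
#' optionally KOA), degradation half-lives per compartment, per-compartment
#' activation energies for the Arrhenius half-life correction, and
#' phase-change enthalpies for the van't Hoff partition-coefficient
#' correction.
#'
#' If `log_koa` is omitted it is closed from the triangle relation
#' `log KOA = log KOW - log KAW` (see [triangle_close()]). If supplied and it
#' departs from the triangle value by more than 0.5 log units, a consistency
#' warning is raised (the value is kept).
#'
#' @param name Compound label.
#' @param molar_mass Molar mass, g/mol (> 0).
#' @param log_kow log10 octanol-water partition coefficient.
#' @param log_kaw log10 air-water partition coefficient (dimensionless
#'   Henry's law constant).
#' @param half_life Named numeric vector of degradation half-lives in hours
#'   for `air`, `water`, `soil`, `sediment`, valid at
#'   `reference_temperature`. All > 0.
#' @param log_koa Optional log10 octanol-air partition coefficient.
#' @param activation_energy Named vector, J/mol, per compartment; defaults
#'   10000 for air and 30000 for water, soil, sediment.
#' @param phase_change_enthalpy Named vector, J/mol, for `kaw`, `koa`, `kow`;
#'   default 0 (no temperature correction of partitioning).
#' @param reference_temperature Kelvin; default 298.15.
#' @param vapor_pressure Optional vapor pressure, Pa.
#' @param solubility Optional aqueous solubility, g/m3.
#' @return An object of class `chem_properties`.
#' @export
#' @examples
#' chemical_properties("BDE-47", 485.79, log_kow = 6.6, log_kaw = -1.7,
#'   half_life = c(air = 170, water = 5500, soil = 5500, sediment = 22000))
chemical_properties <- function(name, molar_mass, log_kow, log_kaw,
                                half_life,
                                log_koa = NULL,
                                activation_energy = c(air = 10000, water = 30000,
                                                      soil = 30000, sediment = 30000),
                                phase_change_enthalpy = c(kaw = 0, koa = 0, kow = 0),
                                reference_temperature = 298.15,
                                vapor_pressure = NA_real_,
                                solubility = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(molar_mass) || molar_mass <= 0)
    stop("invalid-property: molar_mass must be a positive finite number")
  if (!is.finite(log_kow) || !is.finite(log_kaw))
    stop("invalid-property: log_kow and log_kaw must be finite")
  half_life <- .named_by_compartment(half_life, "half_life")
  if (any(!is.finite(half_life)) || any(half_life <= 0))
    stop("invalid-property: all half-lives must be positive and finite")
  activation_energy <- .named_by_compartment(activation_energy, "activation_energy")
  if (any(activation_energy < 0))
    stop("invalid-property: activation energies must be non-negative")
  if (!is.finite(reference_temperature) || reference_temperature <= 0)
    stop("invalid-input: reference_temperature must be > 0 K")
  dh <- c(kaw = 0, koa = 0, kow = 0)
  dh[names(phase_change_enthalpy)] <- phase_change_enthalpy
  triangle <- triangle_close(log_kow, log_kaw)
  if (is.null(log_koa) || is.na(log_koa)) {
    log_koa <- triangle
  } else if (abs(log_koa - triangle) > 0.5) {
    warning(sprintf(
      "chemical '%s': supplied log_koa (%.2f) departs from log_kow - log_kaw (%.2f) by > 0.5",
      name, log_koa, triangle))
  }
  structure(list(
    name = name,
    molar_mass = molar_mass,
    reference_temperature = reference_temperature,
    log_kow = log_kow,
    log_kaw = log_kaw,
    log_koa = log_koa,
    vapor_pressure = vapor_pressure,
    solubility = solubility,
    half_life = half_life,
    activation_energy = activation_energy,
    phase_change_enthalpy = dh
  ), class = "chem_properties")
}

.named_by_compartment <- function(x, what) {
  if (is.null(names(x))) {
    if (length(x) != 4L)
      stop("invalid-property: ", what, " must be named or length 4 (air, water, soil, sediment)")
    names(x) <- COMPARTMENTS
  }
  missing <- setdiff(COMPARTMENTS, names(x))
  if (length(missing))
    stop("invalid-property: ", what, " missing compartment(s): ",
         paste(missing, collapse = ", "))
  x[COMPARTMENTS]
}

#' Close the partition-coefficient triangle
#'
#' `log KOA = log KOW - log KAW`: octanol-air follows from octanol-water and
#' air-water partitioning when octanol is the common reference phase.
#'
#' @param log_kow,log_kaw log10 partition coefficients (finite).
#' @return log10 KOA.
#' @export
#' @examples
#' triangle_close(6.6, -1.7)  # 8.3
triangle_close <- function(log_kow, log_kaw) {
  if (any(!is.finite(log_kow)) || any(!is.finite(log_kaw)))
    stop("invalid-property: inputs to triangle_close must be finite")
  log_kow - log_kaw
}

#' Organic carbon-water partition coefficient from KOW
#'
#' Karickhoff relation `Koc = 0.41 Kow` (L/kg), the convention used inside
#' the EQC model family for sorption to soil, sediment, and suspended solids.
#'
#' @param log_kow log10 octanol-water partition coefficient.
#' @return Koc (linear scale, L/kg).
#' @export
koc_from_kow <- function(log_kow) {
  if (any(!is.finite(log_kow)))
    stop("invalid-property: log_kow must be finite")
  0.41 * 10^log_kow
}

#' Arrhenius temperature adjustment of a degradation half-life
#'
#' `hl(T) = hl_ref * exp((Ea/R) (1/T - 1/T_ref))`. With positive activation
#' energy, degradation slows (half-life lengthens) as temperature falls.
#'
#' @param hl_ref Half-life at `t_ref`, hours (> 0).
#' @param ea Activation energy, J/mol (>= 0).
#' @param t_ref,t Reference and target temperatures, K (> 0).
#' @return Half-life at `t`, hours.
#' @export
adjust_half_life <- function(hl_ref, ea, t_ref, t) {
  if (any(!is.finite(hl_ref)) || any(hl_ref <= 0))
    stop("invalid-input: half-life must be positive")
  if (any(!is.finite(ea)) || any(ea < 0))
    stop("invalid-input: activation energy must be non-negative")
  if (any(!is.finite(c(t_ref, t))) || any(c(t_ref, t) <= 0))
    stop("invalid-input: temperatures must be positive")
  hl_ref * exp((ea / R_GAS) * (1 / t - 1 / t_ref))
}

#' Van't Hoff temperature adjustment of a partition coefficient
#'
#' `K(T) = K_ref * exp(-(dH/R) (1/T - 1/T_ref))`, applied and returned on the
#' log10 scale. A zero enthalpy leaves the coefficient unchanged.
#'
#' @param log_k_ref log10 partition coefficient at `t_ref`.
#' @param enthalpy Phase-change enthalpy, J/mol.
#' @param t_ref,t Reference and target temperatures, K (> 0).
#' @return log10 partition coefficient at `t`.
#' @export
adjust_partition <- function(log_k_ref, enthalpy, t_ref, t) {
  if (any(!is.finite(c(t_ref, t))) || any(c(t_ref, t) <= 0))
    stop("invalid-input: temperatures must be positive")
  log_k_ref + (-(enthalpy / R_GAS) * (1 / t - 1 / t_ref)) / log(10)
}

#' Re-express a chemical's properties at a new temperature
#'
#' Applies [adjust_half_life()] per compartment (with the record's activation
#' energies) and [adjust_partition()] per partition coefficient (with the
#' record's phase-change enthalpies), and resets the reference temperature.
#' Calling it at the record's own reference temperature is the identity.
#'
#' @param chem A [chemical_properties()] record.
#' @param temperature Target temperature, K.
#' @return A `chem_properties` record valid at `temperature`.
#' @export
chemical_at_temperature <- function(chem, temperature) {
  stopifnot(inherits(chem, "chem_properties"))
  if (!is.finite(temperature) || temperature <= 0)
    stop("invalid-input: temperature must be positive")
  t0 <- chem$reference_temperature
  if (identical(temperature, t0)) return(chem)
  chem$half_life <- adjust_half_life(chem$half_life, chem$activation_energy,
                                     t0, temperature)
  dh <- chem$phase_change_enthalpy
  chem$log_kaw <- adjust_partition(chem$log_kaw, dh[["kaw"]], t0, temperature)
  chem$log_kow <- adjust_partition(chem$log_kow, dh[["kow"]], t0, temperature)
  chem$log_koa <- adjust_partition(chem$log_koa, dh[["koa"]], t0, temperature)
  chem$reference_temperature <- temperature
  chem
}

#' @export
print.chem_properties <- function(x, ...) {
  cat(sprintf("<chem_properties> %s (M = %.2f g/mol, ref %.2f K)\n",
              x$name, x$molar_mass, x$reference_temperature))
  cat(sprintf("  log KOW %.2f | log KAW %.2f | log KOA %.2f\n",
              x$log_kow, x$log_kaw, x$log_koa))
  cat("  half-life (h):",
      paste(sprintf("%s %.4g", names(x$half_life), x$half_life), collapse = ", "),
      "\n")
  invisible(x)
}

# --- delimited-table I/O ----------------------------------------------------

.CHEM_COLS <- c("name", "molar_mass", "reference_temperature",
                "log_kow", "log_kaw", "log_koa",
                "vapor_pressure", "solubility",
                "half_life_air", "half_life_water", "half_life_soil",
                "half_life_sediment",
                "ea_air", "ea_water", "ea_soil", "ea_sediment",
                "dh_kaw", "dh_koa", "dh_kow")

#' Read a chemical property table
#'
#' One row per compound; header-named columns `name`, `molar_mass`,
#' `reference_temperature`, `log_kow`, `log_kaw`, `log_koa`,
#' `vapor_pressure`, `solubility`, `half_life_<compartment>`,
#' `ea_<compartment>`, `dh_{kaw,koa,kow}`. Lines starting with `#` are
#' comments.
#'
#' @param path CSV file path.
#' @return A named list of [chemical_properties()] records.
#' @export
read_chemical_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  chems <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    chemical_properties(
      name = r$name, molar_mass = r$molar_mass,
      log_kow = r$log_kow, log_kaw = r$log_kaw,
      log_koa = if ("log_koa" %in% names(r)) r$log_koa else NULL,
      half_life = c(air = r$half_life_air, water = r$half_life_water,
                    soil = r$half_life_soil, sediment = r$half_life_sediment),
      activation_energy = c(air = r$ea_air, water = r$ea_water,
                            soil = r$ea_soil, sediment = r$ea_sediment),
      phase_change_enthalpy = c(kaw = r$dh_kaw, koa = r$dh_koa, kow = r$dh_kow),
      reference_temperature = r$reference_temperature,
      vapor_pressure = if ("vapor_pressure" %in% names(r)) r$vapor_pressure else NA_real_,
      solubility = if ("solubility" %in% names(r)) r$solubility else NA_real_)
  })
  names(chems) <- df$name
  chems
}

#' Write a chemical property table
#'
#' Inverse of [read_chemical_table()]; numeric values keep full precision so
#' a read/write round trip is loss-free well past 6 significant digits.
#'
#' @param chems A list of [chemical_properties()] records.
#' @param path Output CSV file path.
#' @export
write_chemical_table <- function(chems, path) {
  if (inherits(chems, "chem_properties")) chems <- list(chems)
  rows <- lapply(chems, function(ch) {
    data.frame(
      name = ch$name, molar_mass = ch$molar_mass,
      reference_temperature = ch$reference_temperature,
      log_kow = ch$log_kow, log_kaw = ch$log_kaw, log_koa = ch$log_koa,
      vapor_pressure = ch$vapor_pressure, solubility = ch$solubility,
      half_life_air = ch$half_life[["air"]],
      half_life_water = ch$half_life[["water"]],
      half_life_soil = ch$half_life[["soil"]],
      half_life_sediment = ch$half_life[["sediment"]],
      ea_air = ch$activation_energy[["air"]],
      ea_water = ch$activation_energy[["water"]],
      ea_soil = ch$activation_energy[["soil"]],
      ea_sediment = ch$activation_energy[["sediment"]],
      dh_kaw = ch$phase_change_enthalpy[["kaw"]],
      dh_koa = ch$phase_change_enthalpy[["koa"]],
      dh_kow = ch$phase_change_enthalpy[["kow"]],
      stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

#' The three bundled PBDE congeners
#'
#' BDE-47, BDE-99, and BDE-209 with the log10 partition coefficients of the
#' Taiwan case study and degradation half-lives reconstructed from the
#' sources that study builds on (EQC-class air half-lives from the Danish
#' per-capita PBDE model; water = soil = 5500 h identical across congeners;
#' sediment = 4 x soil). See the bundled
#' `extdata/pbde_properties_reconstructed.csv` and the methods vignette for
#' provenance.
#'
#' @return Named list of three [chemical_properties()] records.
#' @export
pbde_congeners <- function() {
  read_chemical_table(system.file("extdata", "pbde_properties_reconstructed.csv",
                                  package = "pbdefate", mustWork = TRUE))
}
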