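# Seeded generator of physically plausible chemicals, environments, and
# emission scenarios, for property testing of the engine without any
# external data.

#' Specification of the synthetic sampling ranges
#'
#' Ranges bracket the hydrophobic semivolatile neighborhood of the bundled
#' PBDEs: log KOW 4-11, log KAW -6-0 (uniform), half-lives 10-1e6 h and
#' emission magnitudes (log-uniform), molar mass 200-1000 g/mol, and
#' multiplicative geometry scale factors applied to the Taiwan domain.
#'
#' @param log_kow,log_kaw Length-2 ranges (uniform sampling).
#' @param half_life_hours,emission_kg_h Length-2 positive ranges
#'   (log-uniform sampling).
#' @param molar_mass Length-2 range, g/mol.
#' @param geometry_scale Length-2 positive range of area/depth multipliers
#'   (log-uniform).
#' @param foc Length-2 range of organic-carbon fractions for soil and
#'   sediment.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(log_kow = c(4, 11),
                           log_kaw = c(-6, 0),
                           half_life_hours = c(10, 1e6),
                           emission_kg_h = c(1e-4, 1),
                           molar_mass = c(200, 1000),
                           geometry_scale = c(0.2, 5),
                           foc = c(0.002, 0.05)) {
  for (r in list(log_kow, log_kaw, half_life_hours, emission_kg_h,
                 molar_mass, geometry_scale, foc))
    if (length(r) != 2L || !all(is.finite(r)) || r[1] >= r[2])
      stop("invalid-input: every range must be a finite, increasing pair")
  if (half_life_hours[1] <= 0 || emission_kg_h[1] <= 0 || geometry_scale[1] <= 0)
    stop("invalid-input: log-uniform ranges must be positive")
  structure(list(log_kow = log_kow, log_kaw = log_kaw,
                 half_life_hours = half_life_hours,
                 emission_kg_h = emission_kg_h,
                 molar_mass = molar_mass,
                 geometry_scale = geometry_scale,
                 foc = foc),
            class = "synthetic_spec")
}

# Run code under a local RNG stream: one integer seed determines the draw
# and the caller's global RNG state is untouched.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.runif_log <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))

#' Draw a random chemical
#'
#' Partition coefficients uniform in their log ranges, half-lives
#' log-uniform per compartment, log KOA closed from the triangle relation,
#' default activation energies. The same seed always yields the same
#' chemical.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return A [chemical_properties()] record.
#' @export
random_chemical <- function(spec = synthetic_spec(), seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .with_seed(seed, {
    lkow <- stats::runif(1, spec$log_kow[1], spec$log_kow[2])
    lkaw <- stats::runif(1, spec$log_kaw[1], spec$log_kaw[2])
    hl <- .runif_log(4, spec$half_life_hours)
    chemical_properties(
      name = sprintf("synthetic-%d", as.integer(seed)),
      molar_mass = stats::runif(1, spec$molar_mass[1], spec$molar_mass[2]),
      log_kow = lkow, log_kaw = lkaw,
      log_koa = triangle_close(lkow, lkaw),
      half_life = stats::setNames(hl, COMPARTMENTS))
  })
}

#' Draw a random environment and emission scenario
#'
#' The Taiwan domain geometry is rescaled by log-uniform factors (areas and
#' depths independently), soil/sediment organic carbon redrawn, air/water
#' advective residence times drawn log-uniformly in 50-5000 h, and a single
#' compound's emissions drawn with a log-uniform magnitude split across
#' air/water/soil by a uniform simplex draw. Sediment never receives direct
#' emissions; reaction losses are always positive, so every generated
#' scenario admits a steady state.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @param congener Name used in the scenario table.
#' @return List with elements `env` ([fate_environment()]), `scenario`
#'   ([emission_scenario()]), and `chem` (the matching random chemical).
#' @export
random_scenario <- function(spec = synthetic_spec(), seed,
                            congener = sprintf("synthetic-%d", as.integer(seed))) {
  stopifnot(inherits(spec, "synthetic_spec"))
  chem <- random_chemical(spec, seed)
  chem$name <- congener
  .with_seed(seed + 1L, {
    base <- build_taiwan_environment(quiet = TRUE)
    cp <- base$compartments
    area_scale <- .runif_log(1, spec$geometry_scale)
    for (nm in COMPARTMENTS) {
      depth_scale <- .runif_log(1, spec$geometry_scale)
      cp[[nm]]$area <- cp[[nm]]$area * area_scale
      cp[[nm]]$depth <- cp[[nm]]$depth * depth_scale
      cp[[nm]]$volume <- cp[[nm]]$area * cp[[nm]]$depth
    }
    cp$soil$foc <- stats::runif(1, spec$foc[1], spec$foc[2])
    cp$sediment$foc <- stats::runif(1, spec$foc[1], spec$foc[2])
    cp$air$advective_residence_time <- .runif_log(1, c(50, 5000))
    cp$water$advective_residence_time <- .runif_log(1, c(50, 5000))
    env <- fate_environment(cp, base$transport, temperature = base$temperature)

    magnitude <- .runif_log(1, spec$emission_kg_h)
    split <- stats::runif(3)
    split <- split / sum(split)
    scenario <- emission_scenario(data.frame(
      congener = congener,
      compartment = EMISSION_MODES,
      kg_per_hour = magnitude * split,
      stringsAsFactors = FALSE))
    list(env = env, scenario = scenario, chem = chem)
  })
}
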