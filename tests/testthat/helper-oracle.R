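# Shared fixtures and the dynamic-integration oracle.

taiwan_env <- function() build_taiwan_environment(quiet = TRUE)

# A small, well-behaved reference chemical for unit tests.
test_chemical <- function(...) {
  args <- utils::modifyList(list(
    name = "test", molar_mass = 500, log_kow = 6, log_kaw = -2,
    half_life = c(air = 200, water = 5000, soil = 5000, sediment = 20000)),
    list(...))
  do.call(chemical_properties, args)
}

# Solve one synthetic scenario with the engine; returns pieces for checks.
solve_synthetic <- function(seed, spec = synthetic_spec()) {
  sc <- random_scenario(spec, seed)
  chem <- chemical_at_temperature(sc$chem, sc$env$temperature)
  e_kg <- stats::setNames(sc$scenario$rates$kg_per_hour,
                          sc$scenario$rates$compartment)
  e_mol <- to_molar(e_kg, chem$molar_mass)
  z <- compute_z(chem, sc$env)
  d <- compute_d_values(chem, sc$env, z)
  state <- level3(e_mol, d, z, sc$env)
  list(scenario = sc, chem = chem, z = z, d = d, state = state,
       emissions_mol = e_mol)
}

# Independent oracle: brute-force time integration of the dynamic mass
# balance dM/dt = E + inflow(f) - outflow(f), f = M / (Z V), run until the
# transient has died out. Shares the Z/D inputs with the algebraic solve but
# not the solution path.
ode_steady_fugacity <- function(d, z, env, emissions_mol) {
  vols <- vapply(env$compartments, function(x) x$volume, numeric(1))
  comps <- c("air", "water", "soil", "sediment")
  vols <- vols[comps]
  zv <- z$bulk[comps] * vols
  e <- stats::setNames(numeric(4), comps)
  e[names(emissions_mol)] <- emissions_mol
  loss <- d$reaction + d$advection
  loss[["sediment"]] <- loss[["sediment"]] + d$burial
  outgoing <- rowSums(d$transfer) + loss
  rhs <- function(t, m, p) {
    f <- m / zv
    list(as.vector(e + t(d$transfer) %*% f - outgoing * f))
  }
  t_end <- 200 * max(zv / outgoing)
  out <- deSolve::lsoda(y = stats::setNames(numeric(4), comps),
                        times = c(0, t_end / 2, t_end), func = rhs,
                        rtol = 1e-11, atol = 1e-12 * max(e) * max(zv / outgoing))
  m_half <- out[2, comps]
  m_end <- out[3, comps]
  stopifnot(max(abs(m_end - m_half)) <= 1e-6 * max(m_end))  # converged
  m_end / zv
}
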