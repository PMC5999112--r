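# Shared fixtures for the suite. Everything is generated in code; the
# scenario configurations come from make_fixture().

# memoised reduced-scale sweep shared by the acceptance tests: the full
# default TI grid at 4 fields x 50 flights per condition
.sweep_cache <- new.env(parent = emptyenv())

reduced_sweep <- function() {
  if (!is.null(.sweep_cache$sweep)) return(.sweep_cache$sweep)
  cfg <- default_config()
  cfg$experiment$n_fields <- 4
  cfg$experiment$n_flights_per_field <- 50
  cfg$seed$master <- 20180613
  .sweep_cache$sweep <- run_experiment(cfg)
  .sweep_cache$sweep
}

# a small single-puff field from the chord fixture: one frozen-size puff
# (rho = 0.2 m) advected along y = 0 at U = 1 m/s in laminar wind
chord_field <- function(horizon = 12) {
  cfg <- make_fixture("single_puff_chord")
  m <- resolve_models(cfg, ti = 0)
  simulate_field(m$wind, m$plume, horizon, dt = cfg$experiment$dt,
                 prune_x = 30, seed = 1)
}

# deterministic laminar corridor field (continuous detection along y = 0)
straight_field <- function(horizon = 80) {
  cfg <- make_fixture("zero_turbulence_straight_shot")
  m <- resolve_models(cfg, ti = 0)
  list(cfg = cfg, models = m,
       field = simulate_field(m$wind, m$plume, horizon,
                              dt = cfg$experiment$dt, prune_x = 30, seed = 1))
}
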