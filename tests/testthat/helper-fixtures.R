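# Session-level cache for expensive shared fixtures (surrogate I-V tables
# take tens of seconds to generate; every test that needs them shares one
# computation).
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# full-resolution surrogate tables at the shipped defaults
fixture_ivs <- function() {
  cached("ivs", surrogate_iv_tables())
}

# coarse, fast tables: enough structure for circuit-level tests
fixture_ivs_coarse <- function() {
  cached("ivs_coarse", surrogate_iv_tables(
    bias_grid = seq(0, 1, by = 0.1), delta_grid = c(0, 0.1, 0.2, 0.25),
    energy_step = 0.004
  ))
}

fixture_hb <- function(species = "CT1C") {
  cached(
    paste0("hb_", species),
    surrogate_hamiltonian(surrogate_spec(species))
  )
}
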