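# Shared simulation runs, computed once per test session and reused by the
# module property tests and the acceptance suite.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

# Scaled evolutionary bootstrapping runs: 1D defaults with a quarter-size
# habitat (L = 204.8), all-defector start, 20 000 generations.
evo_run <- function(seed) {
  cached(paste0("evo", seed), {
    p <- sim_params(dim = 1, L = 204.8, T = 20000, seed = seed)
    run_simulation(p, record_every = 500)
  })
}

evo_params <- function(seed = 1) sim_params(dim = 1, L = 204.8, T = 20000, seed = seed)

# Quasi-steady-state run: same scaled habitat and duration, but initialized
# at the reference trait level 0.05 with mutation on, so mutation-selection
# balance (and with it the steady-state multilevel sign structure) is reached
# within a few thousand generations.
steady_run <- function() {
  cached("steady", {
    run_simulation(steady_params(), init_phi = 0.05, record_every = 500)
  })
}

steady_params <- function() sim_params(dim = 1, L = 204.8, T = 20000, seed = 4)

steady_mls <- function() {
  cached("steadymls", {
    mls_intervals(steady_run(), steady_params())
  })
}

# Fixed-trait (phi = 0.05, mu = 0) run at the full 1D defaults for the
# colony-formation diagnostics; 2400 generations.
fixedphi_run <- function() {
  cached("fixedphi", {
    p <- fixedphi_params()
    run_simulation(p, record_every = 2500)
  })
}

fixedphi_params <- function() sim_params(dim = 1, mu = 0, T = 2400, seed = 11)

# Short default-parameter run on a small habitat used for the exact-identity
# checks (evolution enabled, altruistic start so colonies exist).
identity_run <- function() {
  cached("identity", {
    p <- identity_params()
    run_simulation(p, record_every = 1)
  })
}

identity_params <- function() sim_params(dim = 1, L = 25.6, T = 400, seed = 7)

identity_run_altruist <- function() {
  cached("identity_alt", {
    run_simulation(identity_params(), init_phi = 0.05, record_every = 1)
  })
}
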