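# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Full-size default operating point (15 Gabor filters).
default_net <- function() cached("default_net", default_network())

# Three-filter network on a coarse raster: same operating point, cheap runs.
small_net <- function() cached("small_net", {
  spec <- gabor_bank_spec(
    image_side = 12, orientations = 0,
    locations = rbind(c(0.3, 0.3), c(0.5, 0.5), c(0.7, 0.7))
  )
  ei_network(gsm_model(build_gabor_bank(spec)))
})

# One long Hamiltonian run of the default network at unit contrast,
# shared by the balance and spectral-property tests.
balance_traj <- function() cached("balance_traj", {
  simulate(default_net(), protocol = simulation_protocol(
    t_pre = 1, t_post = 3, z_gen = 1, seed = 42
  ))
})
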