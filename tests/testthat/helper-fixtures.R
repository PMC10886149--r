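# Shared fixtures.  All inputs are built in code; heavy fits used by
# several acceptance checks are computed once per session and cached.

ref_params <- function(...) release_parameters(...)

small_design <- function(S = 30, WS = 0.464, E = 10, P = 0, V = 0.011,
                         horizon = 30, events = list(), ...) {
  experiment_design(release_state(P = P, S = S, WS = WS, E = E, V = V),
                    events = events, horizon = horizon, ...)
}

# noiseless measurements from a single design (generator-is-truth oracle)
noiseless_data <- function(design, params, times, variant = "two_substrate",
                           id = "exp1") {
  traj <- simulate_release(design, params, variant, times = times)
  measurement_set(rep(id, length(times)), times,
                  trajectory_glucose(traj, times))
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# The synthetic calibration campaign: 24 designs, reference truth
# parameters, sigma = 0.2 g/L, master seed 7.
ds1_synthetic <- function() {
  cached("ds1", simulate_dataset1(params = ref_params(), sigma = 0.2, seed = 7))
}

# One global+local fit per variant on the shared synthetic campaign.
ds1_fit <- function(variant) {
  cached(paste0("fit_", variant), {
    ds <- ds1_synthetic()
    fit_global(ds$designs, ds$data, variant = variant, seed = 7)
  })
}
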