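# Shared lazily-computed gating runs (the full wild-type opening ramp and
# the N-terminus deletion at half tension), reused across test files so the
# expensive solves happen once per session.

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(name, fun) {
  if (!exists(name, envir = .run_cache)) assign(name, fun(), envir = .run_cache)
  get(name, envir = .run_cache)
}

wt_full_run <- function() cached_run("wt_full", function() {
  sys <- assemble_system(build_idealized(idealized_params("gating")),
                         bilayer_patch(), vdw_law(), solver_config())
  list(sys = sys, traj = solve_quasistatic(sys))
})

wt_half_state <- function() {
  run <- wt_full_run()
  # increment 15 of 30 equal steps to 0.6 is exactly sigma* = 0.3
  st <- run$traj$states[[16L]]
  stopifnot(abs(st$sigma - 0.3) < 1e-12)
  st
}

dn_half_run <- function() cached_run("dn_half", function() {
  cfg <- solver_config(sigma_max = 0.3, n_increments = 15)
  sys <- assemble_system(build_idealized(idealized_params("gating"),
                                         has_nterm = FALSE),
                         bilayer_patch(), vdw_law(), cfg)
  list(sys = sys, traj = solve_quasistatic(sys))
})

# synthetic converged state at given nodal positions (for metric unit tests)
synthetic_state <- function(sys, positions, sigma = 0) {
  structure(list(sigma = sigma, d = numeric(sys$n_red),
                 positions = positions,
                 rim_radius = sys$rim_R0, thickness = sys$patch$rest_thickness,
                 stretch = 1, thinning_percent = 0,
                 converged = TRUE, iterations = 0L, residual = 0),
            class = "system_state")
}
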