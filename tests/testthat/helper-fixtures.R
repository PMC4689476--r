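# shared fixtures, computed lazily once per test session
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# the baseline synapse: physiological groups (B = 2e-9, tau = 15), open
# pinned edge, six bumps, 64^2 disk, 40 dimensional minutes
baseline_run_64 <- function() {
  fixture("baseline64", function() {
    run_simulation(params = physical_params(),
                   grid = make_grid(64, "disk"),
                   bc = boundary_condition("open_pinned"),
                   ic = initial_condition(seed = 1),
                   solver = solver_config(dt_init = 0.1),
                   B = 2e-9, tau = 15)
  })
}

# 3x3 (tau, B) sweep on a 48^2 disk (32^2 is too coarse for the low-tau
# diffusion/kinetics competition); also supplies the cluster-size scaling
sweep_48 <- function() {
  fixture("sweep48", function() {
    phase_diagram(tau_values = c(0.03, 1, 15),
                  B_values = c(2e-9, 2e-8, 2e-7),
                  params = physical_params(),
                  grid = make_grid(48, "disk"),
                  bc = boundary_condition("open_pinned"),
                  ic = initial_condition(seed = 1),
                  solver = solver_config(dt_init = 0.1))
  })
}

# closed-boundary run integrated far past pattern formation: volume
# conservation and late-time arrest
closed_run_small <- function() {
  fixture("closed_small", function() {
    run_simulation(params = physical_params(),
                   grid = make_grid(32, "disk"),
                   bc = boundary_condition("closed_free"),
                   ic = initial_condition(seed = 2),
                   solver = solver_config(dt_init = 0.1, t_end = 1e6,
                                          snapshot_every = 1e5),
                   B = 2e-9, tau = 15)
  })
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}

round_sig <- function(x, digits = 1) signif(x, digits)
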