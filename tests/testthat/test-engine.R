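test_that("initial condition realises the documented bump statistics", {
  g <- make_grid(48, "disk")
  ic <- initial_condition(seed = 3)
  st <- make_initial_state(ic, g)
  expect_equal(st$t, 0)
  hi <- st$h[g$interior]
  expect_gte(min(hi), 0.5)
  expect_true(max(hi) >= 0.575 && max(hi) <= 0.6)
  expect_equal(unique(as.vector(st$C1)), 0.01)
  expect_equal(unique(as.vector(st$C2)), 0.01)
  # no bumps: flat film at the base height
  flat <- make_initial_state(initial_condition(n_bumps = 0), g)
  expect_equal(unique(as.vector(flat$h)), 0.5)
  # determinism: same seed, bit-identical fields
  st2 <- make_initial_state(ic, g)
  expect_identical(st$h, st2$h)
  # different seeds differ
  st3 <- make_initial_state(initial_condition(seed = 4), g)
  expect_false(identical(st$h, st3$h))
  # under-resolved bumps are refused
  expect_error(make_initial_state(initial_condition(width = 0.01),
                                  make_grid(16, "disk")), "under-resolved")
})

test_that("a flat state at the kinetic fixed point is a steady state", {
  g <- make_grid(32, "disk")
  bc <- boundary_condition("closed_free")
  gr <- dimensionless_groups(physical_params())
  k1 <- kinetics_config(gr, 1)
  k2 <- kinetics_config(gr, 2)
  h0 <- 1   # long-bond height: LFA-saturated flat membrane
  st <- structure(list(
    t = 0,
    h = matrix(h0, g$nx, g$ny),
    C1 = matrix(kinetics_fixed_point(h0, k1), g$nx, g$ny),
    C2 = matrix(kinetics_fixed_point(h0, k2), g$nx, g$ny)
  ), class = "smac_state")
  sv <- solver_config(dt_init = 1, dt_max = 1)
  st1 <- step_state(st, gr, g, bc, sv)
  expect_equal(max(abs(st1$h[g$interior] - st$h[g$interior])), 0,
               tolerance = 1e-12)
  expect_equal(max(abs(st1$C1[g$interior] - st$C1[g$interior])), 0,
               tolerance = 1e-12)
  expect_equal(max(abs(st1$C2[g$interior] - st$C2[g$interior])), 0,
               tolerance = 1e-12)
})

test_that("per-step and whole-run volume conservation under the closed edge", {
  run <- closed_run_small()
  g <- run_grid(run)
  # per-step: advance the final state once more
  st <- run$final_state
  vol0 <- field_integral(st$h, g)
  st1 <- step_state(st, run$config$groups, g, run$config$bc,
                    run$config$solver)
  expect_rel_equal(field_integral(st1$h, g), vol0, 1e-10)
  # whole run: first vs last snapshot
  s <- run$series
  sn <- run$snapshots
  v_start <- field_integral(sn[[1]]$h, g)
  v_end <- field_integral(sn[[length(sn)]]$h, g)
  expect_rel_equal(v_end, v_start, 1e-8)
  # the membrane actually deformed along the way
  expect_gt(max(s$hmax) - min(s$hmin), 0.05)
})

test_that("closed-edge pattern arrests at late times", {
  run <- closed_run_small()
  sn <- run$snapshots
  n <- length(sn)
  win <- function(f, k) max(abs(sn[[k]][[f]] - sn[[k - 1]][[f]])) /
    max(abs(sn[[k]][[f]]))
  # membrane and the pattern-defining LFA field change < 1% over the last
  # 10% of the run, versus order-one changes in the first window
  expect_lt(win("h", n), 0.01)
  expect_lt(win("C2", n), 0.01)
  expect_gt(win("h", 2), 0.1)
  expect_gt(win("C2", 2), 0.5)
  # residual TCR creep (pure slow transport where kinetics has shut off)
  # is bounded and far below the formation-phase dynamics
  expect_lt(win("C1", n), 0.05)
  expect_gt(win("C1", 2) / win("C1", n), 10)
})

test_that("stepping is deterministic and restartable bit-identically", {
  g <- make_grid(32, "disk")
  bc <- boundary_condition("open_pinned")
  gr <- dimensionless_groups(physical_params())
  gr$B <- 2e-9; gr$tau <- 15
  sv <- solver_config(dt_init = 0.1, dt_max = 100)
  ic <- initial_condition(seed = 5)
  adv <- function(st, nst) {
    for (i in seq_len(nst)) st <- step_state(st, gr, g, bc, sv)
    st
  }
  a <- adv(make_initial_state(ic, g), 30L)
  b <- adv(make_initial_state(ic, g), 30L)
  expect_identical(a$h, b$h)
  expect_identical(a$C1, b$C1)
  expect_identical(a$C2, b$C2)
  expect_identical(attr(a, "dt"), attr(b, "dt"))
  # interrupted vs uninterrupted trajectories agree bit-for-bit
  mid <- adv(make_initial_state(ic, g), 15L)
  resumed <- adv(mid, 15L)
  expect_identical(resumed$h, a$h)
  expect_identical(resumed$C1, a$C1)
})

test_that("run archives round-trip and restarts reproduce the trajectory", {
  run <- closed_run_small()
  dir <- withr::local_tempdir()
  write_run_archive(run, file.path(dir, "arch"))
  back <- read_run_archive(file.path(dir, "arch"))
  expect_identical(back$final_state$h, run$final_state$h)
  expect_identical(back$series, run$series)
  expect_true(file.exists(file.path(dir, "arch", "series.csv")))
  expect_true(file.exists(file.path(dir, "arch", "config.json")))
  ser <- utils::read.csv(file.path(dir, "arch", "series.csv"))
  expect_named(ser, c("t_dimensionless", "t_minutes", "N1", "N2"))
  # restart from the second-to-last snapshot reproduces the final state
  k <- length(run$snapshots) - 1L
  cont <- restart_run(run, from = k)
  expect_identical(cont$final_state$h, run$final_state$h)
  expect_identical(cont$final_state$C1, run$final_state$C1)
  expect_identical(cont$final_state$C2, run$final_state$C2)
  # corrupt archives raise load errors
  expect_error(read_run_archive(file.path(dir, "nothere")), "no run archive")
  writeLines("junk", file.path(dir, "arch", "run.rds"))
  expect_error(read_run_archive(file.path(dir, "arch")), "corrupt")
})

test_that("time-step underflow reports a stiffness failure", {
  g <- make_grid(32, "disk")
  bc <- boundary_condition("open_pinned")
  gr <- dimensionless_groups(physical_params())
  st <- make_initial_state(initial_condition(seed = 1), g)
  # an inadmissible state (height below the floor) can never be accepted
  st$h[g$interior][10] <- 5e-4
  sv <- solver_config(dt_init = 1, dt_max = 1, dt_underflow = 1e-3)
  expect_error(step_state(st, gr, g, bc, sv), "stiffness")
})
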