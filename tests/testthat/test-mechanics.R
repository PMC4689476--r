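test_that("pressure operator: spring terms and flat-film degeneracies", {
  g <- make_grid(32)
  cfg <- mechanics_config(B = 2e-9)
  ones <- matrix(1, g$nx, g$ny)
  zero <- matrix(0, g$nx, g$ny)
  # h at the short-bond length with only species 1 bound: no restoring force
  p <- pressure_field(ones * cfg$lam1, ones * 0.7, zero, cfg, g)
  expect_equal(max(abs(p)), 0, tolerance = 1e-12)
  # h = l2 with C1 = C0: pure species-1 spring, p = 1 - lam1 = 2/3
  p2 <- pressure_field(ones, ones, zero, cfg, g)
  expect_equal(p2[5, 9], 2 / 3, tolerance = 1e-12)
  # dimensional check: kappa C0 (l2 - l1) = 7.2 Pa
  params <- physical_params()
  expect_equal(dimensionalize(params, p2[5, 9], "pressure"), 7.2,
               tolerance = 1e-12)
})

test_that("pressure of a sinusoidal bump matches the analytic biharmonic", {
  g <- make_grid(128)
  cfg <- mechanics_config(B = 2e-7)
  X <- matrix(g$x, g$nx, g$ny)
  a <- 0.01; k <- 2 * pi * 3
  h <- cfg$lam1 + a * sin(k * X)
  zero <- matrix(0, g$nx, g$ny)
  p <- pressure_field(h, zero, zero, cfg, g)
  expect_equal(p, a * cfg$B * k^4 * sin(k * X),
               tolerance = 2 * (k * g$dx)^2)
})

test_that("pressure operator is linear in the densities at fixed h", {
  g <- make_grid(32)
  cfg <- mechanics_config(B = 2e-8)
  set.seed(21)
  h <- matrix(0.5 + 0.1 * runif(g$nx * g$ny), g$nx, g$ny)
  C1a <- matrix(runif(g$nx * g$ny), g$nx, g$ny)
  C1b <- matrix(runif(g$nx * g$ny), g$nx, g$ny)
  C2 <- matrix(runif(g$nx * g$ny), g$nx, g$ny)
  zero <- matrix(0, g$nx, g$ny)
  pa <- pressure_field(h, C1a, C2, cfg, g)
  pb <- pressure_field(h, C1b, zero, cfg, g)
  pc <- pressure_field(h, C1a + C1b, C2, cfg, g)
  p0 <- pressure_field(h, zero, zero, cfg, g)
  expect_equal(pc, pa + pb - p0, tolerance = 1e-10)
})

test_that("height RHS vanishes for uniform pressure and conserves volume", {
  g <- make_grid(32, "disk")
  bc <- boundary_condition("closed_free")
  cfg <- mechanics_config(B = 2e-9)
  set.seed(9)
  h <- matrix(0.5 + 0.1 * runif(g$nx * g$ny), g$nx, g$ny)
  ones <- matrix(1, g$nx, g$ny)
  expect_equal(max(abs(height_rhs(h, ones * 0.3, cfg, g, bc))), 0,
               tolerance = 1e-13)
  p <- matrix(rnorm(g$nx * g$ny), g$nx, g$ny)
  r <- height_rhs(h, p, cfg, g, bc)
  expect_lt(abs(field_integral(r, g)) / field_integral(abs(r), g), 1e-12)
  h[which(g$interior)[20]] <- -0.1
  expect_error(height_rhs(h, p, cfg, g, bc), "positiv")
})

test_that("dispersion rate: algebraic structure", {
  cfg <- mechanics_config(B = 2e-9)
  k <- 2 * pi * 5
  # pure bending limit
  expect_equal(dispersion_rate(k, 0.5, 0, 0, cfg),
               -(cfg$eps^2 / 12) * 0.5^3 * cfg$B * k^6, tolerance = 1e-12)
  # monotone decreasing in k, always non-positive
  ks <- 2 * pi * (1:30)
  om <- vapply(ks, dispersion_rate, numeric(1), h0 = 0.5, C1 = 0.4, C2 = 0.2,
               cfg = cfg)
  expect_true(all(om <= 0))
  expect_true(all(diff(om) < 0))
})

test_that("simulated decay of a small sinusoid matches the dispersion rate", {
  # quasi-1-D periodic film, frozen densities; oracle is the closed-form
  # linearisation, the solver runs the full nonlinear machinery
  n <- 256L
  g <- make_grid(n, ny = 16L)
  groups <- dimensionless_groups(physical_params())
  groups$B <- 2e-8
  cfg <- as_mechanics_config(groups)
  h0 <- 0.5; C1f <- 0.5; C2f <- 0.25
  for (m in c(4, 8)) {
    k <- 2 * pi * m
    om <- dispersion_rate(k, h0, C1f, C2f, cfg)
    X <- matrix(g$x, g$nx, g$ny)
    a0 <- 1e-4
    st <- structure(list(t = 0, h = h0 + a0 * sin(k * X),
                         C1 = matrix(C1f, g$nx, g$ny),
                         C2 = matrix(C2f, g$nx, g$ny)),
                    class = "smac_state")
    dt <- 0.1 / abs(om)
    sv <- solver_config(dt_init = dt, dt_max = dt, theta = 0.5,
                        freeze_C = TRUE, scheme = "full")
    nsteps <- 10L
    amp <- function(s) 2 * mean(s$h[, 1] * sin(k * g$x))
    a_start <- amp(st)
    for (i in seq_len(nsteps)) st <- step_state(st, groups, g, NULL, sv)
    a_end <- amp(st)
    rate <- log(a_end / a_start) / (nsteps * dt)
    expect_rel_equal(rate, om, 0.01)
  }
})

test_that("uniform film with uniform bound springs relaxes to equilibrium", {
  # closed film: a perturbed membrane with fixed uniform C1 relaxes to a
  # flat state conserving volume, with pressure gradients dying away
  g <- make_grid(32, "disk")
  bc <- boundary_condition("closed_free")
  groups <- dimensionless_groups(physical_params())
  groups$B <- 2e-7
  st <- make_initial_state(initial_condition(seed = 4, C_init = 0.5), g)
  st$C2[] <- 0
  sv <- solver_config(dt_init = 0.1, dt_max = 1e5, freeze_C = TRUE)
  vol0 <- field_integral(st$h, g)
  cfg <- as_mechanics_config(groups)
  grad_norm <- function(s) {
    p <- pressure_field(s$h, s$C1, s$C2, cfg, g, bc)
    pv <- as.vector(p); nb <- g$nbr
    gx <- (pv[nb[, 1]] - pv[nb[, 2]]); gy <- (pv[nb[, 3]] - pv[nb[, 4]])
    gx[is.na(gx)] <- 0; gy[is.na(gy)] <- 0
    inner <- g$intv & g$intv[g$nbr[, 1]] & g$intv[g$nbr[, 2]] &
      g$intv[g$nbr[, 3]] & g$intv[g$nbr[, 4]]
    inner[is.na(inner)] <- FALSE
    max(abs(c(gx[inner], gy[inner]))) / (2 * g$dx)
  }
  g0 <- grad_norm(st)
  for (i in 1:3000) {
    st <- step_state(st, groups, g, bc, sv)
    if (st$t > 4e7) break
  }
  vol1 <- field_integral(st$h, g)
  expect_rel_equal(vol1, vol0, 1e-8)
  hr <- range(st$h[g$interior])
  expect_lt(diff(hr) / mean(hr), 1e-4)
  expect_lt(grad_norm(st), 1e-8 * g0)
})
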