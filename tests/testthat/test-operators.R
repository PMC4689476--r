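test_that("laplacian and biharmonic reproduce analytic eigenfunctions", {
  for (n in c(64L, 128L)) {
    g <- make_grid(n)
    X <- matrix(g$x, g$nx, g$ny)
    f <- sin(2 * pi * X)
    lf <- op_laplacian(f, g)
    err_l <- max(abs(lf + (2 * pi)^2 * f)) / (2 * pi)^2
    bf <- op_biharmonic(f, g)
    err_b <- max(abs(bf - (2 * pi)^4 * f)) / (2 * pi)^4
    expect_lt(err_l, 2 * (2 * pi * g$dx)^2)
    expect_lt(err_b, 4 * (2 * pi * g$dx)^2)
    if (n == 128L) {
      # empirical second-order convergence: error drops ~4x on refinement
      expect_lt(err_l / .prev_err_l, 0.3)
      expect_lt(err_b / .prev_err_b, 0.3)
    }
    .prev_err_l <- err_l; .prev_err_b <- err_b
  }
})

test_that("laplacian of a quadratic is constant; constants map to zero", {
  g <- make_grid(32, "disk")
  X <- matrix(g$x, g$nx, g$ny)
  lf <- op_laplacian(X^2, g, boundary_condition("open_pinned"))
  inner <- g$interior & (X - 0.5)^2 +
    matrix((g$y - 0.5)^2, g$nx, g$ny, byrow = TRUE) < 0.4^2
  expect_equal(max(abs(lf[inner] - 2)), 0, tolerance = 1e-8)
  gp <- make_grid(32)
  cz <- op_laplacian(matrix(3, gp$nx, gp$ny), gp)
  expect_equal(max(abs(cz)), 0)
  expect_equal(max(abs(op_biharmonic(matrix(3, gp$nx, gp$ny), gp))), 0)
})

test_that("biharmonic equals laplacian composed twice on periodic grids", {
  g <- make_grid(32)
  set.seed(7)
  f <- matrix(rnorm(g$nx * g$ny), g$nx, g$ny)
  expect_equal(op_biharmonic(f, g), op_laplacian(op_laplacian(f, g), g),
               tolerance = 1e-12)
})

test_that("operators are linear and translation invariant", {
  g <- make_grid(32)
  set.seed(11)
  f1 <- matrix(rnorm(g$nx * g$ny), g$nx, g$ny)
  f2 <- matrix(rnorm(g$nx * g$ny), g$nx, g$ny)
  for (op in list(op_laplacian, op_biharmonic)) {
    expect_equal(op(2 * f1 - 3 * f2, g), 2 * op(f1, g) - 3 * op(f2, g),
                 tolerance = 1e-10)
  }
  # translation invariance on the periodic grid
  sh <- function(m) m[c(5:g$nx, 1:4), c(9:g$ny, 1:8)]
  expect_equal(op_laplacian(sh(f1), g), sh(op_laplacian(f1, g)),
               tolerance = 1e-12)
})

test_that("flux divergence reduces to the laplacian and telescopes to zero", {
  g <- make_grid(32)
  set.seed(3)
  f <- matrix(rnorm(g$nx * g$ny), g$nx, g$ny)
  ones <- matrix(1, g$nx, g$ny)
  expect_equal(op_div_flux(ones, f, g), op_laplacian(f, g), tolerance = 1e-11)
  expect_equal(max(abs(op_div_flux(ones, matrix(2, g$nx, g$ny), g))), 0)
  # periodic: total flux divergence telescopes to zero
  coef <- matrix(runif(g$nx * g$ny, 0.5, 1.5), g$nx, g$ny)
  expect_lt(abs(field_integral(op_div_flux(coef, f, g), g)) /
              field_integral(abs(op_div_flux(coef, f, g)), g), 1e-12)
  # disk with no-flux boundary: interior sum vanishes
  gd <- make_grid(32, "disk")
  bc <- boundary_condition("closed_free")
  fd <- matrix(rnorm(gd$nx * gd$ny), gd$nx, gd$ny)
  cd <- matrix(runif(gd$nx * gd$ny, 0.5, 1.5), gd$nx, gd$ny)
  res <- op_div_flux(cd, fd, gd, bc)
  expect_lt(abs(field_integral(res, gd)) / field_integral(abs(res), gd), 1e-12)
  expect_error(op_div_flux(-ones, f, g), "positivity")
})

test_that("advection vanishes for uniform fields and moves a step correctly", {
  g <- make_grid(64, ny = 16)
  ones <- matrix(1, g$nx, g$ny)
  X <- matrix(g$x, g$nx, g$ny)
  expect_equal(max(abs(op_advect(ones, ones * 2, X, g))), 0)
  expect_equal(max(abs(op_advect(ones, X, ones, g))), 0)

  # piecewise-linear pressure (periodic tent), step-profile C: for x < 0.5
  # the pressure falls toward the centre so the step advects right at the
  # characteristic speed u_factor * |dp/dx|
  slope <- 1.5
  p <- slope * abs(X - 0.5)
  C <- ifelse(X < 0.3, 1, 0)
  uf <- 0.8
  speed <- uf * slope
  dt <- 0.25 * g$dx / speed
  nsteps <- 40L
  for (i in seq_len(nsteps)) {
    C <- C + dt * op_advect(ones * uf, p, C, g)
  }
  xfront <- g$x[max(which(C[, 1] > 0.5))]
  expected <- 0.3 + speed * dt * nsteps
  expect_lt(abs(xfront - expected), 3 * g$dx)
})

test_that("sliding divergence conserves mass and vanishes on flat fields", {
  g <- make_grid(32)
  set.seed(5)
  h <- matrix(0.5 + 0.2 * runif(g$nx * g$ny), g$nx, g$ny)
  C <- matrix(runif(g$nx * g$ny, 0, 1), g$nx, g$ny)
  res <- op_slide_div(C, h, 1 / 3, g)
  expect_lt(abs(field_integral(res, g)) /
              max(field_integral(abs(res), g), 1e-300), 1e-12)
  flat <- matrix(0.5, g$nx, g$ny)
  expect_equal(max(abs(op_slide_div(C, flat, 1 / 3, g))), 0)
})

test_that("shape mismatches and invalid grids raise errors", {
  g <- make_grid(32)
  expect_error(op_laplacian(matrix(0, 8, 8), g), "shape")
  expect_error(make_grid(8), "at least 16")
  expect_error(make_grid(32, "disk", ny = 16), "ny")
})

test_that("disk mask geometry is sane", {
  g <- make_grid(48, "disk")
  # area of the unit-diameter disk
  expect_equal(sum(g$interior) * g$dx^2, pi / 4, tolerance = 0.01)
  # every ring node has at least one interior neighbour
  expect_true(length(g$boundary_ring) > 0)
  for (k in g$boundary_ring[seq(1, length(g$boundary_ring), by = 7)]) {
    nb <- g$nbr[k, ]
    expect_true(any(g$intv[nb[!is.na(nb)]]))
  }
})
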