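test_that("bound totals: zero, linear, and the 1-micron disk worked count", {
  g <- make_grid(256)
  p <- physical_params()
  zero <- matrix(0, g$nx, g$ny)
  st0 <- list(C1 = zero, C2 = zero)
  expect_equal(bound_totals(st0, g, p)$N1, 0)
  # full-occupancy TCR disk of diameter 1 micron = 0.1 L
  X <- matrix(g$x, g$nx, g$ny)
  Y <- matrix(g$y, g$nx, g$ny, byrow = TRUE)
  C1 <- ifelse((X - 0.5)^2 + (Y - 0.5)^2 <= 0.05^2, 1, 0)
  st <- list(C1 = C1, C2 = zero)
  N1 <- bound_totals(st, g, p)$N1
  expect_equal(round(N1 / 10) * 10, 160)
  # linearity
  st2 <- list(C1 = 2 * C1, C2 = zero)
  expect_equal(bound_totals(st2, g, p)$N1, 2 * N1, tolerance = 1e-12)
})

test_that("cluster segmentation finds constructed blobs with correct geometry", {
  g <- make_grid(96)
  X <- matrix(g$x, g$nx, g$ny)
  Y <- matrix(g$y, g$nx, g$ny, byrow = TRUE)
  blob <- function(cx, cy, s) exp(-(((X - cx)^2 + (Y - cy)^2) / (2 * s^2)))
  C <- 0.9 * blob(0.25, 0.25, 0.03) + 0.8 * blob(0.7, 0.3, 0.04) +
    0.7 * blob(0.4, 0.75, 0.05)
  cl <- find_clusters(C, g, ctot = 1, threshold_frac = 0.3)
  expect_equal(nrow(cl), 3)
  cl <- cl[order(cl$centroid_x + 2 * cl$centroid_y), ]
  cents <- cbind(cl$centroid_x, cl$centroid_y)
  truth <- rbind(c(0.25, 0.25), c(0.7, 0.3), c(0.4, 0.75))
  truth <- truth[order(truth[, 1] + 2 * truth[, 2]), ]
  expect_true(all(sqrt(rowSums((cents - truth)^2)) < 1.5 * g$dx))

  # single blob whose half-max radius matches the threshold: equivalent
  # diameter within 10% of 2r. For a Gaussian a*exp(-r^2/(2s^2)) cut at
  # a/2 the radius is s*sqrt(2 ln 2)
  a <- 0.8; s <- 0.06
  C1 <- a * blob(0.5, 0.5, s)
  r_half <- s * sqrt(2 * log(2))
  cl1 <- find_clusters(C1, g, ctot = 1, threshold_frac = a / 2)
  expect_equal(nrow(cl1), 1)
  expect_lt(abs(cl1$diameter - 2 * r_half) / (2 * r_half), 0.1)

  # uniform sub-threshold field: nothing found
  expect_equal(nrow(find_clusters(matrix(0.2, g$nx, g$ny), g, 1)), 0)
  # threshold monotonicity: higher cut never increases clustered area
  areas <- vapply(c(0.2, 0.35, 0.5, 0.65),
                  function(th) sum(find_clusters(C, g, 1, th)$area), numeric(1))
  expect_true(all(diff(areas) <= 1e-12))
})

test_that("tiny components are discarded and 8-connectivity joins diagonals", {
  g <- make_grid(32)
  C <- matrix(0, g$nx, g$ny)
  C[5, 5] <- 1                      # single pixel: below min size
  C[10:13, 10:13] <- 1              # 16-pixel block
  C[14, 14] <- 1                    # diagonal touch joins the block
  cl <- find_clusters(C, g, 1)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_pixels, 17L)
})

test_that("pattern classification matches constructed archetypes", {
  g <- make_grid(64, "disk")
  p <- physical_params()
  gr <- dimensionless_groups(p)
  X <- matrix(g$x, g$nx, g$ny)
  Y <- matrix(g$y, g$nx, g$ny, byrow = TRUE)
  R <- sqrt((X - 0.5)^2 + (Y - 0.5)^2)
  zero <- matrix(0, g$nx, g$ny)
  # concentric bulls-eye: TCR disk + LFA annulus
  C1 <- ifelse(R < 0.15, 0.8, 0.01)
  C2 <- ifelse(R > 0.2 & R < 0.35, 1.5, 0.01)
  st <- list(C1 = C1, C2 = C2, h = matrix(0.5, g$nx, g$ny))
  rep <- classify_pattern(st, g, p, gr)
  expect_equal(rep$regime, "bullseye")
  expect_gte(rep$lfa_ring_coverage, 0.6)
  # uniform low fields: no pattern
  st0 <- list(C1 = matrix(0.05, g$nx, g$ny), C2 = matrix(0.05, g$nx, g$ny))
  expect_equal(classify_pattern(st0, g, p, gr)$regime, "no_pattern")
  # several dispersed TCR islands, no central cluster: kinetic clusters
  blobs <- ifelse((R > 0.25 & R < 0.32) &
                    (abs(sin(6 * atan2(Y - 0.5, X - 0.5))) > 0.7), 0.8, 0.01)
  std <- list(C1 = blobs, C2 = zero + 0.01)
  repd <- classify_pattern(std, g, p, gr)
  expect_equal(repd$regime, "kinetic_clusters")
  expect_gte(repd$n_clusters_1, 3)
})

test_that("cluster-size scaling regression recovers exact power laws", {
  B <- c(2e-9, 2e-8, 2e-7)
  d <- tibble::tibble(B = B, mean_diam = 0.05 * (B / 2e-9)^0.25)
  fit <- cluster_size_scaling(d)
  expect_equal(fit$slope, 0.25, tolerance = 1e-12)
  flat <- tibble::tibble(B = B, mean_diam = rep(0.07, 3))
  expect_equal(cluster_size_scaling(flat)$slope, 0, tolerance = 1e-12)
  expect_error(cluster_size_scaling(tibble::tibble(B = 1e-9,
                                                   mean_diam = 0.1)),
               "at least 2")
})

test_that("phase-diagram plumbing: reduction, dedupe, tidy output", {
  # a 1x1 sweep equals a single run + classify
  p <- physical_params()
  g <- make_grid(32, "disk")
  sv <- solver_config(dt_init = 0.1, dt_max = 200, t_end = 2e3)
  pd <- phase_diagram(15, 2e-9, params = p, grid = g,
                      solver = sv, ic = initial_condition(seed = 1))
  expect_equal(nrow(pd), 1)
  run <- run_simulation(params = p, grid = g,
                        bc = boundary_condition("open_pinned"),
                        ic = initial_condition(seed = 1),
                        solver = sv, B = 2e-9, tau = 15)
  rep <- classify_pattern(run$final_state, g, p, run$config$groups)
  expect_equal(pd$regime, rep$regime)
  expect_equal(pd$n_clusters_1, rep$n_clusters_1)
  expect_warning(
    pd2 <- phase_diagram(c(15, 15), 2e-9, params = p, grid = g, solver = sv,
                         ic = initial_condition(seed = 1)),
    "duplicate")
  expect_equal(nrow(pd2), 1)
  expect_error(phase_diagram(numeric(0), 1e-9), "nonempty")
})
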