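#' Total bound receptors in a state
#'
#' Domain-integrated absolute receptor counts for both species:
#' \eqn{N_i = (\sum C_i\, dx^2)\, C_0 L^2}.
#'
#' @param state An `smac_state` (or snapshot with `C1`, `C2`).
#' @param grid A [make_grid()] object.
#' @param params A [physical_params()] object supplying `C0` and `L`.
#' @return One-row tibble with columns `N1`, `N2` (receptor counts).
#' @export
bound_totals <- function(state, grid, params = physical_params()) {
  scale <- params$C0 * params$L^2
  tibble::tibble(N1 = field_integral(state$C1, grid) * scale,
                 N2 = field_integral(state$C2, grid) * scale)
}

#' Segment micro-clusters in a bound-density field
#'
#' Connected components (8-connectivity) of the super-threshold region
#' `C > threshold_frac * ctot`; components smaller than `min_pixels` are
#' discarded. Cluster diameters are equivalent-circle diameters.
#'
#' @param C Bound-density field matrix (units of C0).
#' @param grid A [make_grid()] object.
#' @param ctot Total density of the species (units of C0).
#' @param threshold_frac Threshold as a fraction of `ctot` (default 0.3).
#' @param min_pixels Minimum component size in pixels (default 4).
#' @param params Optional [physical_params()]; when supplied, a
#'   `diameter_m` column with dimensional diameters is added.
#' @return A tibble with one row per cluster: `label`, `n_pixels`, `area`
#'   (units of L^2), `diameter` (units of L), `centroid_x`, `centroid_y`,
#'   `mean_density` (units of C0), `count` (receptors, only with `params`).
#' @export
find_clusters <- function(C, grid, ctot = 1, threshold_frac = 0.3,
                          min_pixels = 4, params = NULL) {
  check_same_shape(C, grid)
  mask <- C > threshold_frac * ctot & grid$interior
  empty <- tibble::tibble(label = integer(0), n_pixels = integer(0),
                          area = numeric(0), diameter = numeric(0),
                          centroid_x = numeric(0), centroid_y = numeric(0),
                          mean_density = numeric(0))
  if (!any(mask)) return(empty)
  idx <- which(mask)
  pos <- match(seq_len(grid$nx * grid$ny), idx)   # node -> local id
  edges <- integer(0)
  # 8-connectivity: E, N, NE, NW are enough (each undirected pair once)
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  ij <- arrayInd(idx, c(grid$nx, grid$ny))
  for (o in offs) {
    ii <- ij[, 1] + o[1]; jj <- ij[, 2] + o[2]
    if (grid$geometry == "periodic_square") {
      ii <- ((ii - 1L) %% grid$nx) + 1L
      jj <- ((jj - 1L) %% grid$ny) + 1L
      ok <- rep(TRUE, length(ii))
    } else {
      ok <- ii >= 1L & ii <= grid$nx & jj >= 1L & jj <= grid$ny
    }
    nb <- rep(NA_integer_, length(ii))
    nb[ok] <- (jj[ok] - 1L) * grid$nx + ii[ok]
    loc <- pos[nb]
    keep <- !is.na(loc)
    edges <- c(edges, as.vector(rbind(which(keep), loc[keep])))
  }
  el <- matrix(edges, ncol = 2, byrow = TRUE)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  d <- tibble::tibble(node = idx, member = comp[seq_along(idx)],
                      x = grid$x[ij[, 1]], y = grid$y[ij[, 2]],
                      dens = C[idx])
  out <- dplyr::group_by(d, .data$member)
  out <- dplyr::summarise(out,
                          n_pixels = dplyr::n(),
                          centroid_x = mean(.data$x),
                          centroid_y = mean(.data$y),
                          mean_density = mean(.data$dens),
                          .groups = "drop")
  out <- dplyr::filter(out, .data$n_pixels >= min_pixels)
  if (nrow(out) == 0) return(empty)
  out <- dplyr::mutate(out,
                       label = dplyr::row_number(),
                       area = .data$n_pixels * grid$dx^2,
                       diameter = 2 * sqrt(.data$area / pi))
  out <- dplyr::select(out, "label", "n_pixels", "area", "diameter",
                       "centroid_x", "centroid_y", "mean_density")
  if (!is.null(params)) {
    out$diameter_m <- out$diameter * params$L
    out$count <- out$mean_density * out$area * params$C0 * params$L^2
  }
  out
}

#' Classify the late-time synapse pattern
#'
#' Operational decision rules for the pattern regimes seen across the
#' (tau, B) phase diagram, applied to a simulation state (conventionally at
#' 40 dimensional minutes, when a mature synapse pattern has formed):
#' * `no_pattern` — species-1 (TCR) density nowhere exceeds
#'   `no_pattern_frac * ctot1`: the proteins fail to organise.
#' * `bullseye` — a central TCR cluster covers the domain centre and an
#'   LFA-rich annulus spans at least `ring_frac` of angular bins at larger
#'   radius (the cSMAC/pSMAC arrangement).
#' * `kinetic_clusters` — at least `min_dispersed` disjoint TCR clusters
#'   without the bulls-eye arrangement.
#' * `intermediate` — anything else.
#'
#' The thresholds are documented, configurable constants; the regime labels
#' are qualitative and at coarse resolution only their ordering along tau
#' is meaningful.
#'
#' @param state An `smac_state` or snapshot.
#' @param grid A [make_grid()] object.
#' @param params A [physical_params()].
#' @param groups A [dimensionless_groups()] (for the total densities).
#' @param threshold_frac Cluster segmentation threshold (see
#'   [find_clusters()]).
#' @param no_pattern_frac Below this fraction of `ctot1` the TCR field
#'   counts as unpatterned.
#' @param ring_frac Minimum angular coverage of the LFA annulus for the
#'   bulls-eye call.
#' @param min_dispersed Minimum number of TCR clusters for the dispersed
#'   kinetic-cluster call.
#' @param centre_tol Distance from the domain centre (units of L) within
#'   which a TCR cluster pixel counts as central.
#' @return A one-row tibble (class `pattern_report`): `regime`,
#'   `n_clusters_1`, `n_clusters_2`, `mean_diam_1`, `mean_diam_2`,
#'   `tcr_centroid_radius`, `lfa_ring_coverage`, `overlap_index`.
#' @export
classify_pattern <- function(state, grid, params = physical_params(),
                             groups = dimensionless_groups(params),
                             threshold_frac = 0.3, no_pattern_frac = 0.2,
                             ring_frac = 0.6, min_dispersed = 3,
                             centre_tol = 0.08) {
  ctot1 <- groups$c10; ctot2 <- groups$c20
  C1 <- state$C1; C2 <- state$C2
  cl1 <- find_clusters(C1, grid, ctot1, threshold_frac)
  cl2 <- find_clusters(C2, grid, ctot2, threshold_frac)
  X <- matrix(grid$x, grid$nx, grid$ny)
  Y <- matrix(grid$y, grid$nx, grid$ny, byrow = TRUE)
  R <- sqrt((X - 0.5)^2 + (Y - 0.5)^2)
  m1 <- C1[grid$interior]
  w1 <- sum(m1)
  tcr_radius <- if (w1 > 0) sum(R[grid$interior] * m1) / w1 else NA_real_
  overlap <- max(C1[grid$interior] * C2[grid$interior]) / (ctot1 * ctot2)

  # central TCR cluster: any super-threshold pixel of a retained cluster
  # within centre_tol of the domain centre
  mask1 <- C1 > threshold_frac * ctot1 & grid$interior
  central <- any(mask1 & R <= centre_tol)

  # LFA angular ring coverage outside the central region
  mask2 <- C2 > threshold_frac * ctot2 & grid$interior
  r_in <- max(centre_tol, if (central) {
    stats::quantile(R[mask1], 0.9, names = FALSE)
  } else centre_tol)
  ring_pix <- mask2 & R > r_in
  coverage <- 0
  if (any(ring_pix)) {
    ang <- atan2(Y[ring_pix] - 0.5, X[ring_pix] - 0.5)
    bins <- unique(floor((ang + pi) / (2 * pi) * 36))
    coverage <- length(bins) / 36
  }

  regime <- if (max(C1[grid$interior]) < no_pattern_frac * ctot1) {
    "no_pattern"
  } else if (central && coverage >= ring_frac) {
    "bullseye"
  } else if (nrow(cl1) >= min_dispersed) {
    "kinetic_clusters"
  } else {
    "intermediate"
  }
  out <- tibble::tibble(
    regime = regime,
    n_clusters_1 = nrow(cl1),
    n_clusters_2 = nrow(cl2),
    mean_diam_1 = if (nrow(cl1)) mean(cl1$diameter) else NA_real_,
    mean_diam_2 = if (nrow(cl2)) mean(cl2$diameter) else NA_real_,
    tcr_centroid_radius = tcr_radius,
    lfa_ring_coverage = coverage,
    overlap_index = overlap
  )
  class(out) <- c("pattern_report", class(out))
  out
}

#' Scaling exponent of cluster size with the bending group
#'
#' Log-log regression slope of mean cluster diameter against the bending
#' group `B`. The elastic length that sets the micro-cluster scale is
#' \eqn{l_c = (B_m/(C_0\kappa))^{1/4} = B^{1/4} L}, so in the kinetic
#' regime the fitted slope is expected near 1/4.
#'
#' @param data A data frame with columns `B` and `mean_diam` (one row per
#'   sweep point; `NA` or non-positive diameters are dropped).
#' @return One-row tibble with `slope`, `se`, `n_points`.
#' @export
cluster_size_scaling <- function(data) {
  d <- dplyr::filter(data, is.finite(.data$mean_diam), .data$mean_diam > 0)
  if (nrow(d) < 2) {
    stop("need at least 2 sweep points with non-empty cluster sets",
         call. = FALSE)
  }
  fit <- stats::lm(log(mean_diam) ~ log(B), data = d)
  sm <- summary(fit)$coefficients
  tibble::tibble(slope = unname(sm["log(B)", "Estimate"]),
                 se = unname(sm["log(B)", "Std. Error"]),
                 n_points = nrow(d))
}

#' Sweep the (tau, B) phase diagram
#'
#' Runs one simulation per (tau, B) pair, classifies the pattern at the
#' final time, and collects one row per cell. Duplicated pairs are run once
#' with a warning; failed cells are recorded with `regime = NA` and the
#' sweep continues.
#'
#' @param tau_values,B_values Numeric vectors of group values.
#' @param params A [physical_params()].
#' @param grid A [make_grid()] object (a periodic square is the cheap
#'   default for sweeps).
#' @param bc A [boundary_condition()].
#' @param ic An [initial_condition()].
#' @param solver A [solver_config()].
#' @param ... Passed to [classify_pattern()].
#' @return A tibble with columns `tau`, `B`, `regime`, `n_clusters_1`,
#'   `n_clusters_2`, `mean_diam_1`, `mean_diam_2`, `overlap_index`, `error`.
#' @export
phase_diagram <- function(tau_values, B_values,
                          params = physical_params(),
                          grid = make_grid(32),
                          bc = boundary_condition("open_pinned"),
                          ic = initial_condition(),
                          solver = solver_config(),
                          ...) {
  if (!length(tau_values) || !length(B_values)) {
    stop("`tau_values` and `B_values` must be nonempty", call. = FALSE)
  }
  cells <- tidyr::expand_grid(tau = tau_values, B = B_values)
  if (anyDuplicated(cells)) {
    warning("duplicate (tau, B) cells removed from sweep")
    cells <- dplyr::distinct(cells)
  }
  groups0 <- dimensionless_groups(params)
  res <- purrr::pmap(cells, function(tau, B) {
    out <- tryCatch({
      run <- run_simulation(params = params, grid = grid, bc = bc, ic = ic,
                            solver = solver, groups = groups0,
                            B = B, tau = tau)
      rep <- classify_pattern(run$final_state, grid, params,
                              groups = run$config$groups, ...)
      dplyr::mutate(rep, tau = tau, B = B, error = NA_character_)
    }, error = function(e) {
      tibble::tibble(regime = NA_character_, n_clusters_1 = NA_integer_,
                     n_clusters_2 = NA_integer_, mean_diam_1 = NA_real_,
                     mean_diam_2 = NA_real_, tcr_centroid_radius = NA_real_,
                     lfa_ring_coverage = NA_real_, overlap_index = NA_real_,
                     tau = tau, B = B, error = conditionMessage(e))
    })
    out
  })
  out <- dplyr::bind_rows(res)
  dplyr::select(out, "tau", "B", "regime", dplyr::everything())
}
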