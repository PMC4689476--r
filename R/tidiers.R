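#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy a set of physical parameters
#'
#' @param x A [physical_params()] object.
#' @param ... Unused.
#' @return A tibble with columns `name`, `value`, `unit`, `description`.
#' @export
tidy.physical_params <- function(x, ...) {
  info <- list(
    mu = c("Pa s", "cleft fluid viscosity"),
    E = c("Pa", "membrane Young's modulus"),
    b = c("m", "membrane thickness"),
    nu = c("", "membrane Poisson ratio"),
    kappa = c("N/m", "reference bond spring stiffness"),
    C0 = c("1/m^2", "reference receptor density"),
    C10 = c("1/m^2", "total TCR density"),
    C20 = c("1/m^2", "total LFA density"),
    l1 = c("m", "TCR-pMHC bond length"),
    l2 = c("m", "LFA-ICAM bond length"),
    D = c("m^2/s", "reference membrane diffusivity"),
    tau_k = c("s", "kinetic on-time"),
    L = c("m", "contact-zone size"),
    kBT = c("J", "thermal energy"),
    gamma = c("N/m", "membrane tension"),
    sigma_on = c("", "on-rate gate width"),
    sigma_off = c("", "off-rate gate width")
  )
  tibble::tibble(
    name = names(info),
    value = unname(vapply(names(info), function(f) x[[f]], numeric(1))),
    unit = vapply(info, `[`, character(1), 1),
    description = vapply(info, `[`, character(1), 2)
  )
}

#' Tidy the dimensionless groups
#'
#' @param x A [dimensionless_groups()] object.
#' @param ... Unused.
#' @return A tibble with columns `name`, `value`, `description`.
#' @export
tidy.dimensionless_groups <- function(x, ...) {
  info <- c(
    B = "membrane bending / protein spring pressure",
    eps = "aspect ratio l2/L",
    lam1 = "bond length ratio l1/l2",
    Pe = "advection / diffusion (Peclet)",
    M = "sliding mobility / diffusion",
    tau = "hydrodynamic / kinetic time",
    Gamma = "membrane tension / spring pressure",
    c10 = "total TCR density / C0",
    c20 = "total LFA density / C0",
    sigma_on = "on-rate gate width",
    sigma_off = "off-rate gate width"
  )
  tibble::tibble(
    name = names(info),
    value = unname(vapply(names(info), function(f) x[[f]], numeric(1))),
    description = unname(info)
  )
}

#' Tidy the scaling-law predictions
#'
#' @param x A [scaling_predictions()] object.
#' @param ... Unused.
#' @return A tibble with columns `name`, `value`, `unit`, `description`.
#' @export
tidy.scaling_predictions <- function(x, ...) {
  info <- list(
    tau_mu = c("s", "hydrodynamic time mu/(C0 kappa l2)"),
    p0 = c("Pa", "pressure scale C0 kappa l2"),
    Bm = c("J", "membrane bending modulus"),
    l_c = c("m", "micro-cluster length (Bm/(C0 kappa))^(1/4)"),
    tau_c = c("s", "cluster-scale drainage time 12 (l_c/l2)^2 tau_mu"),
    tau_L = c("s", "cell-scale drainage time 12 (L/l2)^2 tau_mu")
  )
  tibble::tibble(
    name = names(info),
    value = unname(vapply(names(info), function(f) x[[f]], numeric(1))),
    unit = vapply(info, `[`, character(1), 1),
    description = vapply(info, `[`, character(1), 2)
  )
}

#' Tidy a simulation run into its time series
#'
#' @param x An `smac_run`.
#' @param ... Unused.
#' @return The per-step tibble of domain totals: `t` (tau_mu units),
#'   `t_minutes`, `N1`, `N2` (receptor counts), `hmin`, `hmax` (l2 units).
#' @export
tidy.smac_run <- function(x, ...) {
  x$series
}

#' One-row summary of a simulation run
#'
#' @param x An `smac_run`.
#' @param ... Unused.
#' @return A tibble with the bound-TCR peak (`N1_peak`, `t_peak_minutes`),
#'   final totals, final height range and step count.
#' @export
glance.smac_run <- function(x, ...) {
  s <- x$series
  i <- which.max(s$N1)
  tibble::tibble(
    t_end_minutes = max(s$t_minutes),
    N1_peak = s$N1[i],
    t_peak_minutes = s$t_minutes[i],
    N1_final = s$N1[nrow(s)],
    N2_final = s$N2[nrow(s)],
    hmin_final = s$hmin[nrow(s)],
    hmax_final = s$hmax[nrow(s)],
    n_steps = x$n_steps
  )
}

#' Field matrix as a tidy coordinate table
#'
#' @param f Field matrix.
#' @param grid A [make_grid()] object.
#' @param name Column name for the values.
#' @return A tibble with `x`, `y` (units of L) and the value column,
#'   interior nodes only.
#' @export
field_tbl <- function(f, grid, name = "value") {
  check_same_shape(f, grid)
  ij <- arrayInd(which(grid$interior), c(grid$nx, grid$ny))
  out <- tibble::tibble(x = grid$x[ij[, 1]], y = grid$y[ij[, 2]],
                        value = f[grid$interior])
  names(out)[3] <- name
  out
}

#' Plot the bound-receptor time series of a run
#'
#' @param object An `smac_run`.
#' @param ... Unused.
#' @return A ggplot: receptor counts for both species against dimensional
#'   time in minutes.
#' @export
autoplot.smac_run <- function(object, ...) {
  d <- tidyr::pivot_longer(object$series, c("N1", "N2"),
                           names_to = "species", values_to = "count")
  d$species <- dplyr::recode(d$species, N1 = "TCR-pMHC", N2 = "LFA-ICAM")
  ggplot2::ggplot(d, ggplot2::aes(.data$t_minutes, .data$count,
                                  colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "bound receptors",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the fields of a snapshot
#'
#' Raster panels of gap height and the two bound densities for one stored
#' snapshot of a run.
#'
#' @param run An `smac_run`.
#' @param snapshot Snapshot index (default: last).
#' @return A ggplot with one facet per field.
#' @export
plot_snapshot <- function(run, snapshot = length(run$snapshots)) {
  grid <- run_grid(run)
  sn <- run$snapshots[[snapshot]]
  d <- dplyr::bind_rows(
    dplyr::mutate(field_tbl(sn$h, grid), field = "h (l2)"),
    dplyr::mutate(field_tbl(sn$C1, grid), field = "C1 TCR (C0)"),
    dplyr::mutate(field_tbl(sn$C2, grid), field = "C2 LFA (C0)")
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~field) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (L)", y = "y (L)",
                  title = paste0("t = ", signif(sn$t, 4), " tau_mu")) +
    ggplot2::theme_minimal()
}

#' Plot a (tau, B) phase-diagram sweep
#'
#' @param data The tibble returned by [phase_diagram()].
#' @return A ggplot tile map of regimes over the sweep grid.
#' @export
plot_phase_diagram <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(factor(.data$tau), factor(.data$B),
                                     fill = .data$regime)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::labs(x = expression(tau), y = "B", fill = "regime") +
    ggplot2::theme_minimal()
}
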