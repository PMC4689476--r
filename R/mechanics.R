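#' Mechanics configuration (dimensionless)
#'
#' Groups entering the membrane pressure: `B` the bending/spring pressure
#' ratio, `Gamma` the tension/spring ratio (0 disables tension), `lam1` the
#' bond-length ratio l1/l2 and `eps` the cleft aspect ratio l2/L.
#'
#' @param B Bending group, > 0.
#' @param Gamma Tension group, >= 0.
#' @param lam1 Bond-length ratio l1/l2 in (0, 1).
#' @param eps Aspect ratio l2/L, > 0.
#' @return An object of class `mechanics_config`.
#' @seealso [as_mechanics_config()] to derive one from [dimensionless_groups()].
#' @export
mechanics_config <- function(B, Gamma = 0, lam1 = 1 / 3, eps = 4.5e-3) {
  if (!(B > 0)) stop("`B` must be positive", call. = FALSE)
  if (Gamma < 0) stop("`Gamma` must be >= 0", call. = FALSE)
  if (!(lam1 > 0 && lam1 < 1)) stop("`lam1` must lie in (0, 1)", call. = FALSE)
  if (!(eps > 0)) stop("`eps` must be positive", call. = FALSE)
  structure(list(B = B, Gamma = Gamma, lam1 = lam1, eps = eps),
            class = "mechanics_config")
}

#' @rdname mechanics_config
#' @param groups A [dimensionless_groups()] object.
#' @export
as_mechanics_config <- function(groups) {
  mechanics_config(B = groups$B, Gamma = groups$Gamma,
                   lam1 = groups$lam1, eps = groups$eps)
}

#' Membrane pressure field (dimensionless)
#'
#' The mechanical response of the membrane in units of the spring pressure
#' scale \eqn{p_0 = C_0 \kappa l_2}:
#' \deqn{p = B \nabla^4 h - \Gamma \epsilon^2 \nabla^2 h
#'       + C_1 (h - \lambda_1) + \lambda_1 C_2 (h - 1),}
#' i.e. bending, optional tension, and the two bond-spring terms. `h` is in
#' units of l2, densities in units of C0; the species-2 spring is softer by
#' the bond-length ratio \eqn{\kappa_2 = \lambda_1 \kappa}.
#'
#' @param h Gap-height field (units of l2).
#' @param C1,C2 Bound densities of species 1 and 2 (units of C0).
#' @param cfg A [mechanics_config()].
#' @param grid A [make_grid()] object.
#' @param bc A [boundary_condition()] (ignored on periodic grids).
#' @return Pressure field matrix (units of p0), zero on exterior nodes.
#' @export
pressure_field <- function(h, C1, C2, cfg, grid, bc = NULL) {
  check_same_shape(h, grid); check_same_shape(C1, grid); check_same_shape(C2, grid)
  p <- cfg$B * op_biharmonic(h, grid, bc, role = "height") +
    C1 * (h - cfg$lam1) + cfg$lam1 * C2 * (h - 1)
  if (cfg$Gamma > 0) {
    p <- p - cfg$Gamma * cfg$eps^2 * op_laplacian(h, grid, bc, role = "height")
  }
  p[!grid$interior] <- 0
  p
}

#' Lubrication drainage rate of the gap height (dimensionless)
#'
#' Thin-film (Poiseuille) evolution of the cleft height in units of l2 per
#' hydrodynamic time \eqn{\tau_\mu}:
#' \deqn{\partial h/\partial t = (\epsilon^2 / 12)\, \nabla\cdot(h^3 \nabla p).}
#'
#' @param h Gap-height field (> 0 on the interior).
#' @param p Pressure field (units of p0).
#' @inheritParams pressure_field
#' @return Rate-of-change field for `h`.
#' @export
height_rhs <- function(h, p, cfg, grid, bc = NULL) {
  check_same_shape(h, grid); check_same_shape(p, grid)
  if (any(h[grid$interior] <= 0)) {
    stop("gap height must stay positive: positivity lost", call. = FALSE)
  }
  hf <- ghost_fill(h, grid, fill_for(grid, bc, "height"))
  coef <- hf^3
  (cfg$eps^2 / 12) * op_div_flux(coef, p, grid, bc,
                                 coef_role = "raw", g_role = "pressure")
}

#' Linear dispersion rate of a height perturbation
#'
#' Closed-form decay rate of a small sinusoidal perturbation
#' \eqn{h = h_0 + a\,e^{ikx}} about a flat film with frozen uniform bound
#' densities, obtained by linearising the pressure and drainage equations:
#' \deqn{\omega(k) = -\frac{\epsilon^2}{12} h_0^3 k^2
#'   \left(B k^4 + \Gamma \epsilon^2 k^2 + C_1 + \lambda_1 C_2\right).}
#' Always non-positive: bending, tension and bond springs all stabilise the
#' flat film. Serves as the independent oracle for the nonlinear solver.
#'
#' @param k Wavenumber in units of 1/L (> 0).
#' @param h0 Base gap height (units of l2, > 0).
#' @param C1,C2 Frozen uniform bound densities (units of C0).
#' @param cfg A [mechanics_config()].
#' @return Decay rate in units of 1/\eqn{\tau_\mu} (<= 0).
#' @export
dispersion_rate <- function(k, h0, C1, C2, cfg) {
  stopifnot(k > 0, h0 > 0)
  -(cfg$eps^2 / 12) * h0^3 * k^2 *
    (cfg$B * k^4 + cfg$Gamma * cfg$eps^2 * k^2 + C1 + cfg$lam1 * C2)
}
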