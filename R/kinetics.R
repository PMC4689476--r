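#' Kinetics configuration for one bond species
#'
#' Dimensionless constants of the height-gated binding/unbinding kinetics
#' and the transport terms of one receptor species. Binding is fastest where
#' the local gap height matches the natural bond length (`h = lam`), with a
#' Gaussian gate of relative width `sigma_on`; unbinding is slower by
#' `off_factor` (bonds break three times slower than they form by default)
#' with a wider gate `sigma_off`, or a constant off-rate when
#' `sigma_off = Inf`.
#'
#' @param groups A [dimensionless_groups()] object.
#' @param species 1 (TCR-pMHC, short bond, `lam = lam1`) or 2 (LFA-ICAM,
#'   long bond, `lam = 1`).
#' @param off_factor On/off rate prefactor ratio (default 3).
#' @return An object of class `kinetics_config` with fields `tau`,
#'   `sigma_on`, `sigma_off`, `off_factor`, `lam`, `ctot`, `Pe`, `M`,
#'   `eps`, `lam1`, `species`.
#' @export
kinetics_config <- function(groups, species, off_factor = 3) {
  species <- match_species(species)
  if (!(groups$tau > 0)) stop("`tau` must be positive", call. = FALSE)
  if (!(groups$sigma_on > 0)) stop("`sigma_on` must be positive", call. = FALSE)
  if (!(off_factor > 0)) stop("`off_factor` must be positive", call. = FALSE)
  structure(list(
    tau = groups$tau,
    sigma_on = groups$sigma_on,
    sigma_off = groups$sigma_off,
    off_factor = off_factor,
    lam = if (species == 1L) groups$lam1 else 1,
    ctot = if (species == 1L) groups$c10 else groups$c20,
    Pe = groups$Pe, M = groups$M, eps = groups$eps, lam1 = groups$lam1,
    species = species
  ), class = "kinetics_config")
}

#' Height-gated binding rate
#'
#' Dimensionless on-rate (per hydrodynamic time \eqn{\tau_\mu}):
#' \deqn{K^{on} = \tau \exp\left[-\left(\frac{\lambda - h}
#'   {\sigma_{on}\lambda}\right)^2\right],}
#' peaked where the gap height matches the natural bond length and even
#' about it. `h` may be a scalar or a field matrix.
#'
#' @param h Gap height (units of l2).
#' @param cfg A [kinetics_config()].
#' @return Rate(s), same shape as `h`.
#' @export
on_rate <- function(h, cfg) {
  cfg$tau * exp(-((cfg$lam - h) / (cfg$sigma_on * cfg$lam))^2)
}

#' Height-gated unbinding rate
#'
#' Dimensionless off-rate, slower than binding by `off_factor` at the
#' natural bond length and gated by the wider width `sigma_off`; with
#' `sigma_off = Inf` the gate is absent and the off-rate is constant.
#'
#' @inheritParams on_rate
#' @return Rate(s), same shape as `h`.
#' @export
off_rate <- function(h, cfg) {
  if (is.infinite(cfg$sigma_off)) {
    out <- h * 0 + cfg$tau / cfg$off_factor
    return(out)
  }
  (cfg$tau / cfg$off_factor) *
    exp(-((cfg$lam - h) / (cfg$sigma_off * cfg$lam))^2)
}

#' Pointwise kinetic equilibrium density
#'
#' The fixed point of the local binding/unbinding dynamics at frozen gap
#' height: \eqn{C_{eq} = c_{tot} K^{on} / (K^{on} + K^{off})}. Independent
#' of `tau` (the rate magnitude cancels). Where the height is so far from
#' the bond length that both rates underflow to zero, returns 0 with
#' attribute `undefined = TRUE`.
#'
#' @param h Scalar gap height (units of l2).
#' @param cfg A [kinetics_config()].
#' @return Equilibrium bound density (units of C0).
#' @export
kinetics_fixed_point <- function(h, cfg) {
  kon <- on_rate(h, cfg)
  koff <- off_rate(h, cfg)
  tot <- kon + koff
  if (all(tot == 0)) {
    out <- h * 0
    attr(out, "undefined") <- TRUE
    return(out)
  }
  out <- ifelse(tot > 0, cfg$ctot * kon / tot, 0)
  out
}

#' Full transport-reaction rate for one bound-receptor species
#'
#' Dimensionless right-hand side of the bound-density evolution:
#' advection of bound complexes by the pressure-driven cleft flow
#' (\eqn{\epsilon^2 \lambda\, h \nabla p \cdot \nabla C}, upwinded),
#' membrane diffusion (\eqn{(\lambda_1/\lambda)\,Pe^{-1} \nabla^2 C}),
#' thermodynamic sliding down height gradients
#' (\eqn{(\epsilon^2/M)(\lambda_1/\lambda)^2
#'   \nabla\cdot(C (h - \lambda)\nabla h)}),
#' and height-gated binding/unbinding
#' (\eqn{(c_{tot} - C) K^{on}(h) - C K^{off}(h)}).
#'
#' @param h Gap-height field (> 0).
#' @param p Pressure field.
#' @param C Bound-density field (in `[0, ctot]`).
#' @param cfg A [kinetics_config()].
#' @param grid A [make_grid()] object.
#' @param bc A [boundary_condition()].
#' @param terms Named logical vector switching individual contributions
#'   (`advection`, `diffusion`, `sliding`, `kinetics`).
#' @return Rate-of-change field for `C`.
#' @export
concentration_rhs <- function(h, p, C, cfg, grid, bc = NULL,
                              terms = c(advection = TRUE, diffusion = TRUE,
                                        sliding = TRUE, kinetics = TRUE)) {
  check_same_shape(h, grid); check_same_shape(p, grid); check_same_shape(C, grid)
  Ci <- C[grid$interior]
  if (any(Ci < -1e-9) || any(Ci > cfg$ctot + 1e-9)) {
    stop("bound density outside [0, ctot]: state invalid", call. = FALSE)
  }
  res <- matrix(0, grid$nx, grid$ny)
  if (isTRUE(terms[["advection"]])) {
    u_factor <- cfg$eps^2 * cfg$lam * h
    res <- res + op_advect(u_factor, p, C, grid, bc)
  }
  if (isTRUE(terms[["diffusion"]])) {
    nu <- (cfg$lam1 / cfg$lam) / cfg$Pe
    res <- res + nu * op_laplacian(C, grid, bc, role = "density")
  }
  if (isTRUE(terms[["sliding"]])) {
    coef <- (cfg$eps^2 / cfg$M) * (cfg$lam1 / cfg$lam)^2
    res <- res + coef * op_slide_div(C, h, cfg$lam, grid, bc)
  }
  if (isTRUE(terms[["kinetics"]])) {
    res <- res + (cfg$ctot - C) * on_rate(h, cfg) - C * off_rate(h, cfg)
  }
  res[!grid$interior] <- 0
  res
}

# exact pointwise integrator of the reaction part over a step:
# dC/dt = ctot*Kon - C*(Kon+Koff) has the closed-form exponential solution
kinetics_exact_update <- function(C, h, cfg, dt) {
  kon <- on_rate(h, cfg)
  koff <- off_rate(h, cfg)
  r <- kon + koff
  Ceq <- ifelse(r > 0, cfg$ctot * kon / r, 0)
  ifelse(r > 0, Ceq + (C - Ceq) * exp(-r * dt), C)
}
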