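#' Physical parameters of the synaptic cleft model
#'
#' Builds the set of dimensional material parameters describing the T-cell /
#' antigen-presenting-surface contact: the fluid in the synaptic cleft, the
#' cell membrane treated as an elastic plate, the two receptor-ligand bond
#' species (short TCR-pMHC bonds, species 1; long LFA-ICAM bonds, species 2),
#' their binding kinetics, and the lateral size of the contact zone.
#'
#' Defaults are the literature values for the T-cell synapse. All quantities
#' are SI; unit conversion happens only at I/O boundaries.
#'
#' @param mu Fluid viscosity of the cleft (Pa s).
#' @param E Membrane Young's modulus (Pa). The default corresponds to a
#'   bending modulus `Bm` of about `4.5e-21` J, the soft (thermal-scale) end
#'   of the plausible range.
#' @param b Membrane thickness (m).
#' @param nu Membrane Poisson ratio (dimensionless, in (0, 1)).
#' @param kappa Reference bond spring stiffness \eqn{\kappa} (N/m). Species
#'   stiffnesses scale inversely with bond length:
#'   \eqn{\kappa_i = (l_1/l_i)\kappa}.
#' @param C0 Reference receptor number density (1/m^2).
#' @param C10,C20 Total (bound + free) densities of species 1 and 2 (1/m^2).
#' @param l1,l2 Natural bond lengths of species 1 and 2 (m), `l1 < l2`.
#' @param D Reference membrane diffusivity (m^2/s); species diffusivities
#'   scale as \eqn{D_i = (l_1/l_i) D}.
#' @param tau_k Kinetic on-time \eqn{\tau_k} (s); the on-rate at the natural
#'   bond length is \eqn{1/\tau_k}.
#' @param L Lateral size of the contact domain (m).
#' @param kBT Thermal energy (J).
#' @param gamma Membrane tension (N/m); 0 disables the tension term.
#' @param sigma_on,sigma_off Relative widths of the Gaussian height gates on
#'   the on- and off-rates (dimensionless); `sigma_off = Inf` selects the
#'   constant-off-rate variant.
#'
#' @return An object of class `physical_params` (a named list).
#' @seealso [dimensionless_groups()], [scaling_predictions()], [tidy.physical_params()]
#' @examples
#' p <- physical_params()
#' bending_modulus(p)
#' tidy(p)
#' @export
physical_params <- function(mu = 4e-2,
                            E = 4.5e-21 * 12 * (1 - 0.5^2) / (8e-9)^3,
                            b = 8e-9,
                            nu = 0.5,
                            kappa = 1.2e-6,
                            C0 = 2e14,
                            C10 = C0,
                            C20 = 2 * C0,
                            l1 = 15e-9,
                            l2 = 45e-9,
                            D = 5e-13,
                            tau_k = NULL,
                            L = 1e-5,
                            kBT = 4.34e-21,
                            gamma = 0,
                            sigma_on = 0.2,
                            sigma_off = 0.6) {
  if (is.null(tau_k)) {
    # default kinetic time: tau = tau_mu / tau_k = 15, the baseline regime
    tau_k <- mu / (C0 * kappa * l2) / 15
  }
  p <- list(mu = mu, E = E, b = b, nu = nu, kappa = kappa, C0 = C0,
            C10 = C10, C20 = C20, l1 = l1, l2 = l2, D = D, tau_k = tau_k,
            L = L, kBT = kBT, gamma = gamma,
            sigma_on = sigma_on, sigma_off = sigma_off)
  validate_physical_params(p)
  structure(p, class = "physical_params")
}

validate_physical_params <- function(p) {
  pos <- c("mu", "E", "b", "kappa", "C0", "C10", "C20", "l1", "l2", "D",
           "tau_k", "L", "kBT", "sigma_on")
  for (f in pos) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("physical parameter `", f, "` must be a single positive finite number",
           call. = FALSE)
    }
  }
  if (!(p$nu > 0 && p$nu < 1)) stop("`nu` must lie in (0, 1)", call. = FALSE)
  if (!(p$l1 < p$l2)) stop("`l1` must be smaller than `l2`", call. = FALSE)
  if (p$gamma < 0) stop("`gamma` must be >= 0", call. = FALSE)
  if (!(p$sigma_off > 0)) stop("`sigma_off` must be positive (Inf allowed)", call. = FALSE)
  invisible(p)
}

#' @export
print.physical_params <- function(x, ...) {
  cat("<physical_params> dimensional parameters of the synaptic cleft model\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Membrane bending modulus
#'
#' \eqn{B_m = E b^3 / (12 (1 - \nu^2))} for a thin elastic plate of Young's
#' modulus `E`, thickness `b` and Poisson ratio `nu`.
#'
#' @param params A [physical_params()] object.
#' @return Bending modulus in joules.
#' @export
bending_modulus <- function(params) {
  validate_physical_params(params)
  params$E * params$b^3 / (12 * (1 - params$nu^2))
}

#' Dimensionless groups governing synapse patterning
#'
#' Nondimensionalising the coupled mechanics/hydrodynamics/kinetics system
#' with lateral lengths scaled by `L`, the gap height by `l2`, pressure by
#' \eqn{p_0 = C_0 \kappa l_2}, time by the hydrodynamic time
#' \eqn{\tau_\mu = \mu / (C_0 \kappa l_2)} and densities by `C0` yields the
#' groups returned here. Two of them organise the whole phase diagram:
#' `B` (membrane bending vs. protein spring pressure) and `tau`
#' (hydrodynamic vs. kinetic time scale).
#'
#' @param params A [physical_params()] object.
#' @return An object of class `dimensionless_groups` with fields
#'   `B`, `eps` (= l2/L), `lam1` (= l1/l2), `Pe`, `M`, `tau`, `Gamma`,
#'   `c10`, `c20`, `sigma_on`, `sigma_off`.
#' @examples
#' g <- dimensionless_groups(physical_params())
#' g$tau    # ~ 15 for the default kinetic time
#' @export
dimensionless_groups <- function(params) {
  validate_physical_params(params)
  Bm <- bending_modulus(params)
  denomB <- params$kappa * params$C0 * params$L^4
  Dmu <- params$D * params$mu
  if (denomB == 0 || Dmu == 0) stop("zero denominator in dimensionless groups", call. = FALSE)
  tau_mu <- params$mu / (params$C0 * params$kappa * params$l2)
  g <- list(
    B = Bm / denomB,
    eps = params$l2 / params$L,
    lam1 = params$l1 / params$l2,
    Pe = params$L^2 * params$C0 * params$kappa * params$l2 / Dmu,
    M = params$kBT * params$C0 * params$l2 / Dmu,
    tau = tau_mu / params$tau_k,
    Gamma = params$gamma / (params$kappa * params$C0 * params$l2^2),
    c10 = params$C10 / params$C0,
    c20 = params$C20 / params$C0,
    sigma_on = params$sigma_on,
    sigma_off = params$sigma_off
  )
  structure(g, class = "dimensionless_groups")
}

#' @export
print.dimensionless_groups <- function(x, ...) {
  cat("<dimensionless_groups>\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Scaling-law predictions for cluster size and drainage times
#'
#' Closed-form characteristic scales of the passive patterning dynamics:
#' the hydrodynamic time \eqn{\tau_\mu = \mu/(C_0\kappa l_2)}, the pressure
#' scale \eqn{p_0 = C_0\kappa l_2}, the micro-cluster length
#' \eqn{l_c = (B_m/(C_0\kappa))^{1/4}} from balancing bending and spring
#' pressure, and the fluid-drainage times on the cluster and cell scales,
#' \eqn{\tau_c = 12 (l_c/l_2)^2 \tau_\mu} and
#' \eqn{\tau_L = 12 (L/l_2)^2 \tau_\mu}.
#'
#' @param params A [physical_params()] object.
#' @return An object of class `scaling_predictions` with fields `tau_mu` (s),
#'   `p0` (Pa), `Bm` (J), `l_c` (m), `tau_c` (s), `tau_L` (s).
#' @examples
#' s <- scaling_predictions(physical_params())
#' s$tau_L / 60   # cell-scale drainage time in minutes, ~ 40
#' @export
scaling_predictions <- function(params) {
  validate_physical_params(params)
  Bm <- bending_modulus(params)
  tau_mu <- params$mu / (params$C0 * params$kappa * params$l2)
  l_c <- (Bm / (params$C0 * params$kappa))^0.25
  s <- list(
    tau_mu = tau_mu,
    p0 = params$C0 * params$kappa * params$l2,
    Bm = Bm,
    l_c = l_c,
    tau_c = 12 * (l_c / params$l2)^2 * tau_mu,
    tau_L = 12 * (params$L / params$l2)^2 * tau_mu
  )
  structure(s, class = "scaling_predictions")
}

#' @export
print.scaling_predictions <- function(x, ...) {
  cat("<scaling_predictions>\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

scale_for <- function(params, kind) {
  switch(kind,
    length_xy = params$L,
    height = params$l2,
    pressure = params$C0 * params$kappa * params$l2,
    time = params$mu / (params$C0 * params$kappa * params$l2),
    density = params$C0,
    stop("unknown scaling kind `", kind, "`; expected one of ",
         "length_xy, height, pressure, time, density", call. = FALSE)
  )
}

#' Convert between dimensional and dimensionless quantities
#'
#' The model's canonical scales: lateral lengths by `L`, gap height by `l2`,
#' pressure by \eqn{C_0\kappa l_2}, time by \eqn{\tau_\mu}, densities by
#' `C0`. `nondimensionalize()` divides by the scale, `dimensionalize()`
#' multiplies; the two are exact inverses.
#'
#' @param params A [physical_params()] object.
#' @param quantity Numeric value(s) to convert.
#' @param kind One of `"length_xy"`, `"height"`, `"pressure"`, `"time"`,
#'   `"density"`.
#' @return Converted numeric value(s).
#' @export
nondimensionalize <- function(params, quantity, kind) {
  validate_physical_params(params)
  quantity / scale_for(params, kind)
}

#' @rdname nondimensionalize
#' @export
dimensionalize <- function(params, quantity, kind) {
  validate_physical_params(params)
  quantity * scale_for(params, kind)
}

#' Per-species bond stiffness and diffusivity
#'
#' Species-level constants derived from the reference values: stiffness and
#' diffusivity are inversely proportional to the bond length,
#' \eqn{\kappa_i = (l_1/l_i)\kappa}, \eqn{D_i = (l_1/l_i) D}, so species 1
#' carries the reference values and species 2 (three times longer bond)
#' gets a third of each.
#'
#' @param params A [physical_params()] object.
#' @param species 1 (TCR-pMHC) or 2 (LFA-ICAM).
#' @return Named list with `kappa_i`, `D_i`, `l_i`, `lam` (= l_i/l2),
#'   `ctot` (= C_{i,0}/C0).
#' @export
species_constants <- function(params, species) {
  species <- match_species(species)
  l_i <- if (species == 1L) params$l1 else params$l2
  ratio <- params$l1 / l_i
  list(kappa_i = ratio * params$kappa,
       D_i = ratio * params$D,
       l_i = l_i,
       lam = l_i / params$l2,
       ctot = (if (species == 1L) params$C10 else params$C20) / params$C0)
}

match_species <- function(species) {
  if (!species %in% c(1, 2)) stop("`species` must be 1 or 2", call. = FALSE)
  as.integer(species)
}
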