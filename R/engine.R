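#' Initial condition: membrane bumps over a uniform film
#'
#' The canonical starting state for synapse simulations: a uniform cleft of
#' height `base_h` (half the long-bond length) decorated with a handful of
#' small Gaussian bumps of differing widths and amplitudes, mimicking
#' incipient membrane contacts, with both bound densities uniform at
#' `C_init`. Bump centres sit on a hexagonal ring of radius 0.3 about the
#' domain centre by default; widths and amplitudes (and optionally centres)
#' are drawn reproducibly from `seed`.
#'
#' @param n_bumps Number of Gaussian bumps (default 6).
#' @param width Characteristic bump width as a fraction of the domain size
#'   `L` (~ 0.1); individual bump widths are drawn within +/- 20% of this.
#' @param amp_range Bump amplitude range in units of l2.
#' @param base_h Uniform background height (units of l2).
#' @param C_init Uniform initial bound density (units of C0).
#' @param seed Integer seed; identical seeds give bit-identical states.
#' @param random_centres If `TRUE`, draw centres uniformly in the domain
#'   (rejecting points within 0.15 of the disk edge) instead of the
#'   hexagonal ring.
#' @return An object of class `initial_condition`.
#' @export
initial_condition <- function(n_bumps = 6, width = 0.1,
                              amp_range = c(0.075, 0.1), base_h = 0.5,
                              C_init = 0.01, seed = 1L,
                              random_centres = FALSE) {
  structure(list(n_bumps = as.integer(n_bumps), width = width,
                 amp_range = amp_range, base_h = base_h, C_init = C_init,
                 seed = as.integer(seed), random_centres = random_centres),
            class = "initial_condition")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Build the initial simulation state
#'
#' Realises an [initial_condition()] on a grid: `h = base_h` plus the
#' Gaussian bumps, `C1 = C2 = C_init` uniformly, `t = 0`.
#'
#' @param ic An [initial_condition()].
#' @param grid A [make_grid()] object.
#' @return An object of class `smac_state` with fields `t`, `h`, `C1`, `C2`.
#' @export
make_initial_state <- function(ic, grid) {
  if (ic$n_bumps > 0 && ic$width < 2 * grid$dx) {
    stop("bump width ", ic$width, " is under-resolved on this grid (dx = ",
         grid$dx, "); refine the grid or widen the bumps", call. = FALSE)
  }
  h <- matrix(ic$base_h, grid$nx, grid$ny)
  if (ic$n_bumps > 0) {
    bumps <- with_seed(ic$seed, {
      k <- ic$n_bumps
      widths <- stats::runif(k, 0.8 * ic$width, 1.2 * ic$width)
      amps <- stats::runif(k, ic$amp_range[1], ic$amp_range[2])
      if (ic$random_centres) {
        cx <- cy <- numeric(k)
        for (b in seq_len(k)) {
          repeat {
            px <- stats::runif(1, 0.15, 0.85); py <- stats::runif(1, 0.15, 0.85)
            if ((px - 0.5)^2 + (py - 0.5)^2 <= 0.35^2 ||
                grid$geometry == "periodic_square") break
          }
          cx[b] <- px; cy[b] <- py
        }
      } else {
        ang <- 2 * pi * (seq_len(k) - 1) / k
        cx <- 0.5 + 0.3 * cos(ang)
        cy <- 0.5 + 0.3 * sin(ang)
      }
      list(cx = cx, cy = cy, widths = widths, amps = amps)
    })
    X <- matrix(grid$x, grid$nx, grid$ny)
    Y <- matrix(grid$y, grid$nx, grid$ny, byrow = TRUE)
    for (b in seq_len(ic$n_bumps)) {
      sig <- bumps$widths[b] / 2
      r2 <- (X - bumps$cx[b])^2 + (Y - bumps$cy[b])^2
      h <- h + bumps$amps[b] * exp(-r2 / (2 * sig^2))
    }
  }
  state <- list(t = 0,
                h = h,
                C1 = matrix(ic$C_init, grid$nx, grid$ny),
                C2 = matrix(ic$C_init, grid$nx, grid$ny))
  structure(state, class = "smac_state")
}

#' @export
print.smac_state <- function(x, ...) {
  cat("<smac_state> t =", signif(x$t, 5), "tau_mu;",
      "h in [", signif(min(x$h), 4), ",", signif(max(x$h), 4), "]\n")
  invisible(x)
}

#' Solver configuration
#'
#' Controls of the semi-implicit integrator. The stiff linear part of the
#' drainage equation (bending-driven flux with lagged mobility `h^3` and
#' frozen densities) is treated implicitly with a theta scheme; receptor
#' diffusion is implicit; advection and sliding are explicit and
#' CFL-limited; the binding/unbinding reaction is integrated exactly
#' pointwise. Steps are accepted only if the gap height stays above `h_min`
#' and densities stay within bounds; otherwise `dt` is halved and the step
#' retried. After `grow_after` consecutive accepts `dt` grows by 1.2x up to
#' `dt_max`.
#'
#' @param dt_init,dt_max Initial and maximal time step (units of
#'   \eqn{\tau_\mu}).
#' @param t_end End time (units of \eqn{\tau_\mu}); `NULL` means 40
#'   dimensional minutes, resolved against the physical parameters at run
#'   time.
#' @param snapshot_every Interval between stored snapshots (units of
#'   \eqn{\tau_\mu}); `NULL` means `t_end / 8`.
#' @param theta Implicitness of the height solve (1 backward Euler,
#'   0.5 trapezoidal).
#' @param h_min Smallest admissible gap height (units of l2).
#' @param dh_max Largest admissible per-step height change (units of l2);
#'   the accuracy throttle of the stabilized scheme.
#' @param dC_max Largest admissible per-step density change as a fraction
#'   of each species' total.
#' @param scheme `"stabilized"` (default: constant-coefficient majorant
#'   implicit, nonlinear rate explicit, factorisation reused) or `"full"`
#'   (lagged-coefficient linearly implicit theta scheme, refactorised every
#'   step; used for verification runs).
#' @param cfl Courant number for the explicit transport terms.
#' @param bound_tol Tolerance for density-bound violations before a step is
#'   rejected.
#' @param grow_after Consecutive accepted steps before `dt` grows.
#' @param dt_underflow Below this `dt` the integrator aborts with a
#'   stiffness failure.
#' @param freeze_C If `TRUE` the density fields are frozen (used for linear
#'   dispersion checks against the closed-form rate).
#' @param terms Named logicals enabling the density transport/reaction
#'   contributions.
#' @param record_every Record the domain time series every this many
#'   accepted steps.
#' @param seed Integer seed recorded with the run.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(dt_init = 0.05, dt_max = 400, t_end = NULL,
                          snapshot_every = NULL, theta = 1, h_min = 1e-3,
                          dh_max = 0.05, dC_max = 0.05, cfl = 0.8,
                          bound_tol = 1e-9,
                          grow_after = 5L, dt_underflow = 1e-12,
                          freeze_C = FALSE,
                          scheme = c("stabilized", "full"),
                          terms = c(advection = TRUE, diffusion = TRUE,
                                    sliding = TRUE, kinetics = TRUE),
                          record_every = 1L, seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(dt_init > 0, dt_max >= dt_init, theta >= 0, theta <= 1,
            h_min > 0, cfl > 0, dh_max > 0)
  structure(list(dt_init = dt_init, dt_max = dt_max, t_end = t_end,
                 snapshot_every = snapshot_every, theta = theta,
                 h_min = h_min, dh_max = dh_max, dC_max = dC_max, cfl = cfl,
                 bound_tol = bound_tol,
                 grow_after = as.integer(grow_after),
                 dt_underflow = dt_underflow, freeze_C = freeze_C,
                 scheme = scheme,
                 terms = terms, record_every = as.integer(record_every),
                 seed = as.integer(seed)),
            class = "solver_config")
}

embed_full <- function(v, grid) {
  out <- matrix(0, grid$nx, grid$ny)
  out[grid$interior] <- v
  out
}

# largest admissible explicit-transport step from the CFL condition
cfl_limit <- function(h, p, grid, bc, groups, solver) {
  if (solver$freeze_C) return(Inf)
  dx <- grid$dx
  vmax <- 0
  if (isTRUE(solver$terms[["advection"]])) {
    pv <- as.vector(ghost_fill(p, grid, fill_for(grid, bc, "pressure")))
    nb <- grid$nbr
    gx <- abs(nbr_vals(pv, nb[, 1]) - nbr_vals(pv, nb[, 2])) / (2 * dx)
    gy <- abs(nbr_vals(pv, nb[, 3]) - nbr_vals(pv, nb[, 4])) / (2 * dx)
    u <- groups$eps^2 * 1 * abs(as.vector(h)) * pmax(gx, gy)  # lam <= 1
    vmax <- max(vmax, max(u[grid$intv]))
  }
  if (isTRUE(solver$terms[["sliding"]])) {
    hv <- as.vector(ghost_fill(h, grid, fill_for(grid, bc, "height")))
    nb <- grid$nbr
    gx <- abs(nbr_vals(hv, nb[, 1]) - nbr_vals(hv, nb[, 2])) / (2 * dx)
    gy <- abs(nbr_vals(hv, nb[, 3]) - nbr_vals(hv, nb[, 4])) / (2 * dx)
    coef <- (groups$eps^2 / groups$M) * max(1, 1 / groups$lam1)^0 # lam1/lam <= 1
    w <- coef * abs(hv - groups$lam1) * pmax(gx, gy)
    vmax <- max(vmax, max(w[grid$intv]))
  }
  if (vmax == 0) return(Inf)
  solver$cfl * dx / vmax
}

# one attempted advance by dt; returns NULL on rejection
attempt_step <- function(state, dt, grid, bc, groups, solver, cons, cfg,
                         kcfg1, kcfg2, p_old) {
  hi <- state$h[grid$interior]
  C1i <- state$C1[grid$interior]
  C2i <- state$C2[grid$interior]
  th <- solver$theta
  n_int <- grid$n_int
  if (solver$scheme == "full") {
    aff <- height_affine(grid, bc, cons, cfg, state$h, C1i, C2i)
    Asys <- Matrix::Diagonal(n_int) - (th * dt) * aff$A
    rhs <- hi + dt * aff$b
    if (th < 1) rhs <- rhs + dt * (1 - th) * as.numeric(aff$A %*% hi)
    hn <- as.numeric(Matrix::solve(Asys, rhs))
  } else {
    # stabilized IMEX: the true nonlinear drainage rate explicitly, a
    # constant-coefficient majorant operator implicitly (factored once and
    # reused); exact for uniform films, first-order accurate otherwise with
    # the per-step height change capped by dh_max
    f_old <- height_rhs(state$h, p_old, cfg, grid, bc)[grid$interior]
    # majorants rounded up to powers of two so factorisations are reused
    mbar <- 2^ceiling(log2(max(state$h[grid$interior])^3))
    cbar <- 2^ceiling(log2(max(C1i + cfg$lam1 * C2i) + 1e-12))
    st <- stabilizer_factor(cons, cfg, grid, mbar, cbar, th, dt)
    rhs <- hi + dt * f_old - (th * dt) * as.numeric(st$Abar %*% hi)
    hn <- as.numeric(Matrix::solve(st$fac, rhs))
    if (max(abs(hn - hi)) > solver$dh_max) return(NULL)
  }
  if (!all(is.finite(hn)) || any(hn <= solver$h_min)) return(NULL)
  h_new <- embed_full(hn, grid)

  C1 <- state$C1; C2 <- state$C2
  if (!solver$freeze_C) {
    upd <- function(C, kcfg) {
      # explicit transport rates, frozen over the step
      s <- matrix(0, grid$nx, grid$ny)
      if (isTRUE(solver$terms[["advection"]])) {
        s <- s + op_advect(kcfg$eps^2 * kcfg$lam * state$h, p_old, C, grid, bc)
      }
      if (isTRUE(solver$terms[["sliding"]])) {
        coef <- (kcfg$eps^2 / kcfg$M) * (kcfg$lam1 / kcfg$lam)^2
        s <- s + coef * op_slide_div(C, state$h, kcfg$lam, grid, bc)
      }
      Cn <- C
      if (isTRUE(solver$terms[["diffusion"]])) {
        nu <- (kcfg$lam1 / kcfg$lam) / kcfg$Pe
        key <- paste0("s", kcfg$species, "_", format(dt, digits = 17))
        fac <- cons$diff_factors[[key]]
        if (is.null(fac)) {
          Ad <- Matrix::Diagonal(n_int) - (dt * nu) * cons$AC
          fac <- Matrix::lu(Ad)
          cons$diff_factors[[key]] <- fac
        }
        rhsC <- Cn[grid$interior] + dt * nu * cons$bC
        Cn <- embed_full(as.numeric(Matrix::solve(fac, rhsC)), grid)
      }
      if (isTRUE(solver$terms[["kinetics"]])) {
        # exponential (ETD) update of dC/dt = ctot*Kon - (Kon+Koff) C + s:
        # exact for frozen rates, and its large-dt limit is the correct
        # kinetics/transport balance rather than the bare kinetic fixed
        # point (plain splitting would erase transport at large dt)
        kon <- on_rate(h_new, kcfg)
        koff <- off_rate(h_new, kcfg)
        r <- kon + koff
        er <- exp(-r * dt)
        phi <- (1 - er) / r
        z <- r == 0
        if (any(z)) phi[z] <- dt
        Cn <- Cn * er + (kcfg$ctot * kon + s) * phi
        Cn[!grid$interior] <- 0
      } else {
        Cn <- Cn + dt * s
        Cn[!grid$interior] <- 0
      }
      Cn
    }
    C1 <- upd(state$C1, kcfg1)
    C2 <- upd(state$C2, kcfg2)
    ok_bounds <- function(C, ctot) {
      ci <- C[grid$interior]
      all(is.finite(ci)) && min(ci) >= -solver$bound_tol &&
        max(ci) <= ctot + solver$bound_tol
    }
    if (!ok_bounds(C1, kcfg1$ctot) || !ok_bounds(C2, kcfg2$ctot)) return(NULL)
    # accuracy throttle: densities must not move more than dC_max of their
    # totals in one step (interfacial dynamics stays resolved)
    if (max(abs(C1[grid$interior] - state$C1[grid$interior])) >
          solver$dC_max * kcfg1$ctot ||
        max(abs(C2[grid$interior] - state$C2[grid$interior])) >
          solver$dC_max * kcfg2$ctot) return(NULL)
    C1 <- pmin(pmax(C1, 0), kcfg1$ctot)
    C2 <- pmin(pmax(C2, 0), kcfg2$ctot)
    C1[!grid$interior] <- 0; C2[!grid$interior] <- 0
  }
  structure(list(t = state$t + dt, h = h_new, C1 = C1, C2 = C2),
            class = "smac_state")
}

#' Advance the coupled state by one accepted time step
#'
#' One semi-implicit step of the coupled height/density system with
#' adaptive step control: the proposed `dt` (capped by the explicit-term
#' CFL limit) is halved until the new state is admissible (gap height above
#' `h_min`, densities within bounds). Carries the adaptive step size and
#' accept streak in attributes `dt` and `streak`.
#'
#' @param state An `smac_state` (optionally with attributes `dt`, `streak`).
#' @param groups A [dimensionless_groups()] object.
#' @param grid A [make_grid()] object.
#' @param bc A [boundary_condition()].
#' @param solver A [solver_config()].
#' @return The advanced `smac_state` with updated `dt`/`streak` attributes.
#' @export
step_state <- function(state, groups, grid, bc, solver) {
  cons <- engine_constants(grid, bc)
  cfg <- as_mechanics_config(groups)
  kcfg1 <- kinetics_config(groups, 1)
  kcfg2 <- kinetics_config(groups, 2)
  dt <- attr(state, "dt") %||% solver$dt_init
  streak <- attr(state, "streak") %||% 0L

  p_now <- pressure_field(state$h, state$C1, state$C2, cfg, grid, bc)
  dt_cap <- cfl_limit(state$h, p_now, grid, bc, groups, solver)

  # quantize the CFL cap so the stabiliser factorisation can be reused
  cap <- if (is.finite(dt_cap)) 2^floor(log2(dt_cap)) else Inf
  repeat {
    dt_use <- min(dt, cap)
    new_state <- attempt_step(state, dt_use, grid, bc, groups, solver,
                              cons, cfg, kcfg1, kcfg2, p_now)
    if (!is.null(new_state)) break
    dt <- dt_use / 2
    streak <- 0L
    if (dt < solver$dt_underflow) {
      stop("time step underflow (dt < ", solver$dt_underflow,
           "): stiffness failure at t = ", state$t, call. = FALSE)
    }
  }
  if (dt_use >= dt) {   # nominal dt was not CFL-capped: count toward growth
    streak <- streak + 1L
    if (streak >= solver$grow_after && dt < solver$dt_max) {
      dt <- min(dt * 1.2, solver$dt_max)
      streak <- 0L
    }
  }
  attr(new_state, "dt") <- dt
  attr(new_state, "streak") <- streak
  attr(new_state, "dt_used") <- dt_use
  new_state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a full synapse patterning simulation
#'
#' Integrates the coupled gap-height / bound-density system from an initial
#' condition to `t_end`, recording the domain time series of bound-receptor
#' totals and height extrema plus periodic full-field snapshots.
#'
#' @param params A [physical_params()] object (used for the dimensionless
#'   groups unless `groups` is given, and for unit conversion of times).
#' @param grid A [make_grid()] object.
#' @param bc A [boundary_condition()].
#' @param ic An [initial_condition()].
#' @param solver A [solver_config()].
#' @param groups Optional [dimensionless_groups()] overriding those derived
#'   from `params`.
#' @param B,tau Optional direct overrides of the two phase-diagram groups.
#' @return An object of class `smac_run`: list with `series` (a tibble with
#'   columns `t`, `t_minutes`, `N1`, `N2`, `hmin`, `hmax`), `snapshots`
#'   (list of states with pressure), `config`, `final_state`.
#' @examples
#' \donttest{
#' run <- run_simulation(grid = make_grid(32, "disk"),
#'                       solver = solver_config(t_end = 2000))
#' tidy(run)
#' }
#' @export
run_simulation <- function(params = physical_params(),
                           grid = make_grid(64, "disk"),
                           bc = boundary_condition("open_pinned"),
                           ic = initial_condition(),
                           solver = solver_config(),
                           groups = NULL, B = NULL, tau = NULL) {
  if (is.null(groups)) groups <- dimensionless_groups(params)
  if (!is.null(B)) groups$B <- B
  if (!is.null(tau)) groups$tau <- tau
  scal <- scaling_predictions(params)
  t_end <- solver$t_end %||% (40 * 60 / scal$tau_mu)
  snap_every <- solver$snapshot_every %||% (t_end / 8)

  state <- make_initial_state(ic, grid)
  cons <- engine_constants(grid, bc)
  cfg <- as_mechanics_config(groups)

  snap_of <- function(state) {
    list(t = state$t, h = state$h, C1 = state$C1, C2 = state$C2,
         p = pressure_field(state$h, state$C1, state$C2, cfg, grid, bc),
         dt = attr(state, "dt") %||% solver$dt_init,
         streak = attr(state, "streak") %||% 0L)
  }

  rec <- list(); snaps <- list()
  add_rec <- function(state) {
    list(t = state$t,
         N1 = field_integral(state$C1, grid) * params$C0 * params$L^2,
         N2 = field_integral(state$C2, grid) * params$C0 * params$L^2,
         hmin = min(state$h[grid$interior]),
         hmax = max(state$h[grid$interior]))
  }
  rec[[1]] <- add_rec(state)
  snaps[[1]] <- snap_of(state)
  next_snap <- snap_every
  nstep <- 0L
  while (state$t < t_end - 1e-9) {
    # never step past t_end
    dt_left <- t_end - state$t
    if ((attr(state, "dt") %||% solver$dt_init) > dt_left) {
      attr(state, "dt") <- dt_left
    }
    state <- step_state(state, groups, grid, bc, solver)
    nstep <- nstep + 1L
    if (nstep %% solver$record_every == 0L) {
      rec[[length(rec) + 1L]] <- add_rec(state)
    }
    if (state$t >= next_snap - 1e-9) {
      snaps[[length(snaps) + 1L]] <- snap_of(state)
      next_snap <- next_snap + snap_every
    }
  }
  if (rec[[length(rec)]]$t < state$t) rec[[length(rec) + 1L]] <- add_rec(state)
  if (snaps[[length(snaps)]]$t < state$t) snaps[[length(snaps) + 1L]] <- snap_of(state)

  series <- tibble::tibble(
    t = vapply(rec, `[[`, numeric(1), "t"),
    t_minutes = vapply(rec, `[[`, numeric(1), "t") * scal$tau_mu / 60,
    N1 = vapply(rec, `[[`, numeric(1), "N1"),
    N2 = vapply(rec, `[[`, numeric(1), "N2"),
    hmin = vapply(rec, `[[`, numeric(1), "hmin"),
    hmax = vapply(rec, `[[`, numeric(1), "hmax")
  )
  structure(list(series = series, snapshots = snaps,
                 config = list(params = params, groups = groups,
                               grid_n = grid$n, geometry = grid$geometry,
                               bc = bc, ic = ic, solver = solver,
                               t_end = t_end, snapshot_every = snap_every),
                 final_state = state, n_steps = nstep),
            class = "smac_run")
}

#' @export
print.smac_run <- function(x, ...) {
  cat("<smac_run> ", x$config$geometry, " n=", x$config$grid_n,
      ", bc=", x$config$bc$variant,
      ", B=", signif(x$config$groups$B, 3),
      ", tau=", signif(x$config$groups$tau, 3),
      ", t_end=", signif(x$config$t_end, 4), " tau_mu (",
      signif(max(x$series$t_minutes), 3), " min), ",
      x$n_steps, " steps\n", sep = "")
  invisible(x)
}

#' Rebuild the grid a run was computed on
#'
#' @param run An `smac_run`.
#' @return The [make_grid()] object matching the run configuration.
#' @export
run_grid <- function(run) {
  make_grid(run$config$grid_n, run$config$geometry)
}

#' Write / read a run archive
#'
#' Persists a run to a directory: the full object as an RDS file, the time
#' series as CSV (columns `t_dimensionless`, `t_minutes`, `N1`, `N2`), and
#' the resolved configuration as JSON for inspection.
#'
#' @param run An `smac_run`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly (for `write_run_archive`); the restored
#'   `smac_run` (for `read_run_archive`).
#' @export
write_run_archive <- function(run, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  saveRDS(run, file.path(path, "run.rds"))
  ser <- run$series
  utils::write.csv(
    data.frame(t_dimensionless = ser$t, t_minutes = ser$t_minutes,
               N1 = ser$N1, N2 = ser$N2),
    file.path(path, "series.csv"), row.names = FALSE)
  cfg <- run$config
  cfg_flat <- list(grid_n = cfg$grid_n, geometry = cfg$geometry,
                   bc = unclass(cfg$bc), ic = unclass(cfg$ic),
                   solver = unclass(cfg$solver),
                   groups = unclass(cfg$groups),
                   params = unclass(cfg$params),
                   t_end = cfg$t_end, snapshot_every = cfg$snapshot_every)
  writeLines(jsonlite::toJSON(cfg_flat, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(path, "config.json"))
  invisible(path)
}

#' @rdname write_run_archive
#' @export
read_run_archive <- function(path) {
  f <- file.path(path, "run.rds")
  if (!file.exists(f)) stop("no run archive at ", path, call. = FALSE)
  run <- tryCatch(readRDS(f), error = function(e)
    stop("corrupt run archive at ", path, ": ", conditionMessage(e),
         call. = FALSE))
  if (!inherits(run, "smac_run")) stop("corrupt run archive at ", path,
                                       call. = FALSE)
  run
}

#' Restart a run from a stored snapshot
#'
#' Reconstructs the state (including the adaptive step size) from snapshot
#' `from` of a run and integrates on to `t_end` with the same
#' configuration. For a deterministic configuration the continued
#' trajectory is bit-identical to the uninterrupted one.
#'
#' @param run An `smac_run`.
#' @param from Snapshot index to restart from.
#' @param t_end New end time (defaults to the original).
#' @return An `smac_run` covering `[t_from, t_end]`.
#' @export
restart_run <- function(run, from = length(run$snapshots), t_end = NULL) {
  snap <- run$snapshots[[from]]
  cfg <- run$config
  grid <- run_grid(run)
  t_end <- t_end %||% cfg$t_end
  state <- structure(list(t = snap$t, h = snap$h, C1 = snap$C1, C2 = snap$C2),
                     class = "smac_state")
  attr(state, "dt") <- snap$dt
  attr(state, "streak") <- snap$streak
  solver <- cfg$solver
  solver$t_end <- t_end
  scal <- scaling_predictions(cfg$params)
  rec <- list(); nstep <- 0L
  add_rec <- function(state) {
    list(t = state$t,
         N1 = field_integral(state$C1, grid) * cfg$params$C0 * cfg$params$L^2,
         N2 = field_integral(state$C2, grid) * cfg$params$C0 * cfg$params$L^2,
         hmin = min(state$h[grid$interior]),
         hmax = max(state$h[grid$interior]))
  }
  rec[[1]] <- add_rec(state)
  while (state$t < t_end - 1e-9) {
    dt_left <- t_end - state$t
    if ((attr(state, "dt") %||% solver$dt_init) > dt_left) {
      attr(state, "dt") <- dt_left
    }
    state <- step_state(state, cfg$groups, grid, cfg$bc, solver)
    nstep <- nstep + 1L
    rec[[length(rec) + 1L]] <- add_rec(state)
  }
  series <- tibble::tibble(
    t = vapply(rec, `[[`, numeric(1), "t"),
    t_minutes = vapply(rec, `[[`, numeric(1), "t") * scal$tau_mu / 60,
    N1 = vapply(rec, `[[`, numeric(1), "N1"),
    N2 = vapply(rec, `[[`, numeric(1), "N2"),
    hmin = vapply(rec, `[[`, numeric(1), "hmin"),
    hmax = vapply(rec, `[[`, numeric(1), "hmax")
  )
  structure(list(series = series, snapshots = list(),
                 config = cfg, final_state = state, n_steps = nstep),
            class = "smac_run")
}
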