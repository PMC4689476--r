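#' Discrete simulation domain
#'
#' Builds a uniform collocated Cartesian grid over the synapse contact zone.
#' Lateral coordinates are in units of the domain size `L`. Two geometries
#' are supported: a periodic square (cheap, used for parameter sweeps and
#' operator tests) and a disk of diameter 1 embedded in a padded square via
#' an interior mask (the physical geometry of the cell contact, used for the
#' bulls-eye simulations). For the disk, exterior nodes act as a ghost ring
#' whose values are set by the active boundary condition.
#'
#' @param n Number of grid points per unit length (so the spacing is
#'   `dx = 1/n`); at least 16.
#' @param geometry `"periodic_square"` or `"disk"`.
#' @param ny Number of points in y for the periodic rectangle (defaults to
#'   `n`; must equal `n` for the disk). A small `ny` gives a cheap
#'   quasi-one-dimensional domain for dispersion tests.
#' @return An object of class `smac_grid`.
#' @examples
#' g <- make_grid(32)
#' gd <- make_grid(32, "disk")
#' sum(gd$interior) * gd$dx^2  # ~ pi/4, the disk area in units of L^2
#' @export
make_grid <- function(n, geometry = c("periodic_square", "disk"), ny = n) {
  geometry <- match.arg(geometry)
  n <- as.integer(n)
  ny <- as.integer(ny)
  if (n < 16L) stop("`n` must be at least 16", call. = FALSE)
  dx <- 1 / n
  if (geometry == "periodic_square") {
    nx_tot <- n
    ny_tot <- ny
    x <- (seq_len(nx_tot) - 0.5) * dx
    y <- (seq_len(ny_tot) - 0.5) * dx
    interior <- matrix(TRUE, nx_tot, ny_tot)
  } else {
    if (ny != n) stop("disk geometry requires `ny == n`", call. = FALSE)
    pad <- 2L
    nx_tot <- n + 2L * pad
    ny_tot <- n + 2L * pad
    x <- (seq_len(nx_tot) - pad - 0.5) * dx
    y <- (seq_len(ny_tot) - pad - 0.5) * dx
    r2 <- outer(x - 0.5, y - 0.5, function(a, b) a^2 + b^2)
    interior <- r2 <= 0.25
  }
  N <- nx_tot * ny_tot
  idx <- matrix(seq_len(N), nx_tot, ny_tot)
  periodic <- geometry == "periodic_square"
  shift_idx <- function(di, dj) {
    if (periodic) {
      ii <- ((seq_len(nx_tot) - 1L + di) %% nx_tot) + 1L
      jj <- ((seq_len(ny_tot) - 1L + dj) %% ny_tot) + 1L
      as.vector(idx[ii, jj])
    } else {
      ii <- seq_len(nx_tot) + di
      jj <- seq_len(ny_tot) + dj
      ok_i <- ii >= 1L & ii <= nx_tot
      ok_j <- jj >= 1L & jj <= ny_tot
      out <- matrix(NA_integer_, nx_tot, ny_tot)
      out[ok_i, ok_j] <- idx[ii[ok_i], jj[ok_j]]
      as.vector(out)
    }
  }
  nbr <- cbind(E = shift_idx(1L, 0L), W = shift_idx(-1L, 0L),
               N = shift_idx(0L, 1L), S = shift_idx(0L, -1L))

  # faces, oriented low -> high index along each axis; each node appears at
  # most once as the "a" side and once as the "b" side per direction
  fx_a <- as.vector(idx[seq_len(nx_tot - 1L), , drop = FALSE])
  fx_b <- as.vector(idx[seq.int(2L, nx_tot), , drop = FALSE])
  fy_a <- as.vector(idx[, seq_len(ny_tot - 1L), drop = FALSE])
  fy_b <- as.vector(idx[, seq.int(2L, ny_tot), drop = FALSE])
  if (periodic) {
    fx_a <- c(fx_a, as.vector(idx[nx_tot, ]))
    fx_b <- c(fx_b, as.vector(idx[1L, ]))
    fy_a <- c(fy_a, as.vector(idx[, ny_tot]))
    fy_b <- c(fy_b, as.vector(idx[, 1L]))
  }

  intv <- as.vector(interior)
  # mirror map: ghost value of an exterior node = mean over its interior
  # 4-neighbours (zero-normal-gradient closure for the free-edge variant)
  mirror_M <- NULL
  boundary_ring <- integer(0)
  if (!periodic) {
    ext_idx <- which(!intv)
    rows <- integer(0); cols <- integer(0); vals <- numeric(0)
    for (d in 1:4) {
      nb <- nbr[ext_idx, d]
      ok <- !is.na(nb) & intv[nb]
      rows <- c(rows, ext_idx[ok]); cols <- c(cols, nb[ok])
      vals <- c(vals, rep(1, sum(ok)))
    }
    cnt <- numeric(N)
    tab <- table(rows)
    cnt[as.integer(names(tab))] <- as.numeric(tab)
    vals <- vals / cnt[rows]
    mirror_M <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(N, N))
    boundary_ring <- sort(unique(rows))
  }

  g <- list(n = n, nx = nx_tot, ny = ny_tot, dx = dx, geometry = geometry,
            x = x, y = y, interior = interior, intv = intv,
            idx_int = which(intv), n_int = sum(intv),
            nbr = nbr,
            faces = list(x = cbind(a = fx_a, b = fx_b),
                         y = cbind(a = fy_a, b = fy_b)),
            mirror_M = mirror_M, boundary_ring = boundary_ring,
            cache = new.env(parent = emptyenv()))
  structure(g, class = "smac_grid")
}

#' @export
print.smac_grid <- function(x, ...) {
  cat("<smac_grid> ", x$geometry, ", ", x$nx, "x", x$ny,
      " nodes (", x$n_int, " interior), dx = ", signif(x$dx, 4), " L\n", sep = "")
  invisible(x)
}

#' Boundary condition for the synapse edge
#'
#' Two physical variants of the contact-zone edge:
#' * `open_pinned` — the membrane is pinned at half the long-bond height
#'   (`h = 0.5` in units of l2), the edge is torque free (zero bending
#'   moment), held at ambient pressure (`p = 0`) so fluid can drain through
#'   the edge, and the bound densities are held at their far-field value.
#' * `closed_free` — no fluid flux through the edge
#'   (\eqn{\nabla p \cdot n = 0}), zero bending moment, zero receptor flux;
#'   the membrane height is free (zero normal gradient). This variant
#'   conserves cleft fluid volume and arrests the late-time pattern.
#'
#' On a periodic-square grid the condition is ignored (periodic wrap).
#'
#' @param variant `"open_pinned"` or `"closed_free"`.
#' @param h_edge Edge gap height in units of l2 (open variant).
#' @param p_edge Edge pressure in units of p0 (open variant).
#' @param C_edge Edge bound density in units of C0 (open variant).
#' @return An object of class `boundary_condition`.
#' @export
boundary_condition <- function(variant = c("open_pinned", "closed_free"),
                               h_edge = 0.5, p_edge = 0, C_edge = 0.01) {
  variant <- match.arg(variant)
  structure(list(variant = variant, h_edge = h_edge, p_edge = p_edge,
                 C_edge = C_edge),
            class = "boundary_condition")
}

#' @export
print.boundary_condition <- function(x, ...) {
  cat("<boundary_condition> ", x$variant, "\n", sep = "")
  invisible(x)
}

# ghost-fill descriptor for a field role under a boundary condition
fill_for <- function(grid, bc, role) {
  if (role == "raw") return(list(type = "none", value = 0))
  if (grid$geometry == "periodic_square") return(list(type = "periodic", value = 0))
  if (is.null(bc)) bc <- boundary_condition()
  if (bc$variant == "open_pinned") {
    v <- switch(role, height = bc$h_edge, pressure = bc$p_edge,
                density = bc$C_edge, lap2 = 0,
                stop("unknown field role `", role, "`", call. = FALSE))
    list(type = "dirichlet", value = v)
  } else {
    if (role == "lap2") list(type = "dirichlet", value = 0)
    else list(type = "mirror", value = 0)
  }
}

# returns full matrix with exterior nodes replaced by ghost values
ghost_fill <- function(f, grid, fill) {
  if (fill$type == "periodic" || fill$type == "none") return(f)
  out <- f
  if (fill$type == "dirichlet") {
    out[!grid$interior] <- fill$value
  } else {
    gh <- as.numeric(grid$mirror_M %*% as.vector(f))
    out[!grid$interior] <- gh[!grid$intv]
  }
  out
}

check_same_shape <- function(f, grid) {
  if (!is.matrix(f) || nrow(f) != grid$nx || ncol(f) != grid$ny) {
    stop("field shape (", paste(dim(f), collapse = "x"),
         ") does not match grid (", grid$nx, "x", grid$ny, ")", call. = FALSE)
  }
  invisible(TRUE)
}

nbr_vals <- function(v, nbr_col) {
  out <- v[nbr_col]
  if (anyNA(nbr_col)) out[is.na(nbr_col)] <- 0
  out
}

#' Discrete Laplacian
#'
#' Second-order centred 5-point Laplacian of a scalar field, with periodic
#' wrap or ghost-ring closure at the disk boundary according to the active
#' boundary condition. Exterior nodes of the result are zero.
#'
#' @param f Field matrix on the grid.
#' @param grid A [make_grid()] object.
#' @param bc A [boundary_condition()] (ignored for periodic grids).
#' @param role Field role used to pick the ghost closure: one of
#'   `"height"`, `"pressure"`, `"density"`, `"lap2"`.
#' @return Matrix of the same shape.
#' @export
op_laplacian <- function(f, grid, bc = NULL, role = "height") {
  check_same_shape(f, grid)
  fill <- fill_for(grid, bc, role)
  g <- ghost_fill(f, grid, fill)
  v <- as.vector(g)
  res <- (nbr_vals(v, grid$nbr[, 1]) + nbr_vals(v, grid$nbr[, 2]) +
          nbr_vals(v, grid$nbr[, 3]) + nbr_vals(v, grid$nbr[, 4]) - 4 * v) / grid$dx^2
  out <- matrix(res, grid$nx, grid$ny)
  out[!grid$interior] <- 0
  out
}

#' Discrete biharmonic operator
#'
#' \eqn{\nabla^4 f} as the Laplacian applied twice. At a disk boundary the
#' intermediate field \eqn{\nabla^2 f} is closed with the torque-free
#' condition \eqn{\nabla^2 f = 0} on the ghost ring (zero bending moment).
#'
#' @inheritParams op_laplacian
#' @return Matrix of the same shape.
#' @export
op_biharmonic <- function(f, grid, bc = NULL, role = "height") {
  g <- op_laplacian(f, grid, bc, role)
  op_laplacian(g, grid, bc, role = "lap2")
}

# generic conservative divergence accumulator over oriented faces:
# res gains +F/dx at the low node and -F/dx at the high node of each face
accumulate_div <- function(grid, face_flux_x, face_flux_y, keep_x, keep_y) {
  res <- numeric(grid$nx * grid$ny)
  fx <- grid$faces$x; fy <- grid$faces$y
  qx <- face_flux_x; qx[!keep_x] <- 0
  qy <- face_flux_y; qy[!keep_y] <- 0
  res[fx[, 1]] <- res[fx[, 1]] + qx
  res[fx[, 2]] <- res[fx[, 2]] - qx
  res[fy[, 1]] <- res[fy[, 1]] + qy
  res[fy[, 2]] <- res[fy[, 2]] - qy
  res / grid$dx
}

face_keep <- function(grid, bc) {
  open <- is.null(bc) || bc$variant == "open_pinned"
  key <- paste0("keep_", grid$geometry, "_", open)
  hit <- grid$cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- if (grid$geometry == "periodic_square") {
    list(x = rep(TRUE, nrow(grid$faces$x)), y = rep(TRUE, nrow(grid$faces$y)))
  } else {
    keep1 <- function(fc) {
      a_in <- grid$intv[fc[, 1]]; b_in <- grid$intv[fc[, 2]]
      if (open) a_in | b_in else a_in & b_in
    }
    list(x = keep1(grid$faces$x), y = keep1(grid$faces$y))
  }
  grid$cache[[key]] <- out
  out
}

#' Conservative flux-form divergence
#'
#' \eqn{\nabla \cdot (c \nabla g)} in conservative form: face coefficients
#' are arithmetic means of the adjacent nodes, face fluxes telescope so that
#' under no-flux boundaries the discrete interior sum vanishes to round-off.
#'
#' @param coef Non-negative coefficient field (e.g. the mobility `h^3`).
#' @param g Field whose gradient drives the flux (e.g. pressure).
#' @inheritParams op_laplacian
#' @param coef_role,g_role Ghost-closure roles for the two fields.
#' @return Matrix of the same shape.
#' @export
op_div_flux <- function(coef, g, grid, bc = NULL,
                        coef_role = "height", g_role = "pressure") {
  check_same_shape(coef, grid); check_same_shape(g, grid)
  if (any(coef[grid$interior] < 0)) {
    stop("negative flux coefficient: positivity lost upstream", call. = FALSE)
  }
  cf <- as.vector(ghost_fill(coef, grid, fill_for(grid, bc, coef_role)))
  gv <- as.vector(ghost_fill(g, grid, fill_for(grid, bc, g_role)))
  keep <- face_keep(grid, bc)
  fx <- grid$faces$x; fy <- grid$faces$y
  qx <- 0.5 * (cf[fx[, 1]] + cf[fx[, 2]]) * (gv[fx[, 2]] - gv[fx[, 1]]) / grid$dx
  qy <- 0.5 * (cf[fy[, 1]] + cf[fy[, 2]]) * (gv[fy[, 2]] - gv[fy[, 1]]) / grid$dx
  res <- accumulate_div(grid, qx, qy, keep$x, keep$y)
  out <- matrix(res, grid$nx, grid$ny)
  out[!grid$interior] <- 0
  out
}

#' Upwinded advection term for bound receptors
#'
#' The discrete counterpart of \eqn{(u_f) \nabla p \cdot \nabla C}: bound
#' complexes are carried with velocity \eqn{v = -(u_f) \nabla p} (down
#' pressure gradients when `u_factor > 0`), and \eqn{\nabla C} is upwinded
#' against that velocity for monotonicity.
#'
#' @param u_factor Field of advective prefactors (e.g. `eps^2 * lam * h`).
#' @param p Pressure field.
#' @param C Bound-density field.
#' @inheritParams op_laplacian
#' @return Matrix of the same shape: the advective rate of change of `C`.
#' @export
op_advect <- function(u_factor, p, C, grid, bc = NULL) {
  check_same_shape(u_factor, grid); check_same_shape(p, grid); check_same_shape(C, grid)
  dx <- grid$dx
  pv <- as.vector(ghost_fill(p, grid, fill_for(grid, bc, "pressure")))
  Cv <- as.vector(ghost_fill(C, grid, fill_for(grid, bc, "density")))
  uf <- as.vector(u_factor)
  nb <- grid$nbr
  pE <- nbr_vals(pv, nb[, 1]); pW <- nbr_vals(pv, nb[, 2])
  pN <- nbr_vals(pv, nb[, 3]); pS <- nbr_vals(pv, nb[, 4])
  vx <- -uf * (pE - pW) / (2 * dx)
  vy <- -uf * (pN - pS) / (2 * dx)
  CE <- nbr_vals(Cv, nb[, 1]); CW <- nbr_vals(Cv, nb[, 2])
  CN <- nbr_vals(Cv, nb[, 3]); CS <- nbr_vals(Cv, nb[, 4])
  upx <- vx > 0; upy <- vy > 0
  dCdx <- (upx * (Cv - CW) + (!upx) * (CE - Cv)) / dx
  dCdy <- (upy * (Cv - CS) + (!upy) * (CN - Cv)) / dx
  res <- -(vx * dCdx + vy * dCdy)
  out <- matrix(res, grid$nx, grid$ny)
  out[!grid$interior] <- 0
  out
}

#' Conservative sliding (drift) divergence
#'
#' \eqn{\nabla \cdot (C (h - \lambda) \nabla h)} in conservative flux form
#' with donor-cell upwinding of `C` at faces, so that bound densities remain
#' non-negative under a CFL-limited explicit update and the interior total
#' is conserved under no-flux boundaries.
#'
#' @param C Bound-density field.
#' @param h Gap-height field.
#' @param lam Natural bond length of the species in units of l2.
#' @inheritParams op_laplacian
#' @return Matrix of the same shape.
#' @export
op_slide_div <- function(C, h, lam, grid, bc = NULL) {
  check_same_shape(C, grid); check_same_shape(h, grid)
  dx <- grid$dx
  hv <- as.vector(ghost_fill(h, grid, fill_for(grid, bc, "height")))
  Cv <- as.vector(ghost_fill(C, grid, fill_for(grid, bc, "density")))
  keep <- face_keep(grid, bc)
  flux_dir <- function(fc) {
    # w = (h - lam) dh/dn at the face; transport velocity of C is -w
    w <- 0.5 * ((hv[fc[, 1]] - lam) + (hv[fc[, 2]] - lam)) *
      (hv[fc[, 2]] - hv[fc[, 1]]) / dx
    u <- -w
    don <- u >= 0
    Cface <- don * Cv[fc[, 1]] + (!don) * Cv[fc[, 2]]
    Cface * u   # flux of C with velocity u, oriented a -> b
  }
  Gx <- flux_dir(grid$faces$x)
  Gy <- flux_dir(grid$faces$y)
  div_Cu <- accumulate_div(grid, Gx, Gy, keep$x, keep$y)
  out <- matrix(-div_Cu, grid$nx, grid$ny)   # term = +div(C w) = -div(C u)
  out[!grid$interior] <- 0
  out
}

#' Interior integral of a field
#'
#' Sum of a field over interior nodes times the cell area, in units of
#' (field unit) x L^2.
#'
#' @param f Field matrix.
#' @param grid A [make_grid()] object.
#' @return Scalar.
#' @export
field_integral <- function(f, grid) {
  sum(f[grid$interior]) * grid$dx^2
}
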