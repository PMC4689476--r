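# Sparse-operator assembly for the semi-implicit height solve and the
# implicit density diffusion. Operators act on the vector of interior
# unknowns; ghost closures enter through an affine fill map
#   f_full = P %*% f_int + g0
# so that a full-grid operator A restricted to the interior becomes the
# affine pair (A[int, ] %*% P,  A[int, ] %*% g0).

lap_full_matrix <- function(grid) {
  key <- "lap_full"
  if (!is.null(grid$cache[[key]])) return(grid$cache[[key]])
  N <- grid$nx * grid$ny
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  deg <- numeric(N)
  for (d in 1:4) {
    nb <- grid$nbr[, d]
    ok <- !is.na(nb)
    ii <- c(ii, which(ok)); jj <- c(jj, nb[ok]); xx <- c(xx, rep(1, sum(ok)))
    deg[ok] <- deg[ok] + 1
  }
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(N)), j = c(jj, seq_len(N)),
                            x = c(xx, -deg), dims = c(N, N)) / grid$dx^2
  grid$cache[[key]] <- A
  A
}

fill_map <- function(grid, fill) {
  N <- grid$nx * grid$ny
  n_int <- grid$n_int
  if (fill$type %in% c("periodic", "none")) {
    return(list(P = Matrix::Diagonal(N), g0 = numeric(N)))
  }
  P <- Matrix::sparseMatrix(i = grid$idx_int, j = seq_len(n_int), x = 1,
                            dims = c(N, n_int))
  g0 <- numeric(N)
  if (fill$type == "dirichlet") {
    g0[!grid$intv] <- fill$value
  } else {
    P <- P + grid$mirror_M[, grid$idx_int, drop = FALSE]
  }
  list(P = P, g0 = g0)
}

# divergence-of-flux matrix for given face coefficients (already ghost
# filled); acts on a full-grid vector of the driven field
divflux_matrix <- function(grid, coef_full, keep) {
  fx <- grid$faces$x; fy <- grid$faces$y
  cfx <- 0.5 * (coef_full[fx[, 1]] + coef_full[fx[, 2]]); cfx[!keep$x] <- 0
  cfy <- 0.5 * (coef_full[fy[, 1]] + coef_full[fy[, 2]]); cfy[!keep$y] <- 0
  N <- grid$nx * grid$ny
  i <- c(fx[, 1], fx[, 1], fx[, 2], fx[, 2], fy[, 1], fy[, 1], fy[, 2], fy[, 2])
  j <- c(fx[, 1], fx[, 2], fx[, 2], fx[, 1], fy[, 1], fy[, 2], fy[, 2], fy[, 1])
  x <- c(-cfx, cfx, -cfx, cfx, -cfy, cfy, -cfy, cfy)
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(N, N)) / grid$dx^2
}

# constant (per grid x bc) pieces of the implicit machinery, memoised on the
# grid's cache environment
engine_constants <- function(grid, bc) {
  key <- paste0("eng_", if (is.null(bc)) "none" else
    paste(bc$variant, bc$h_edge, bc$p_edge, bc$C_edge, sep = "_"))
  if (!is.null(grid$cache[[key]])) return(grid$cache[[key]])
  Lap <- lap_full_matrix(grid)
  Ri <- grid$idx_int
  Lint <- Lap[Ri, , drop = FALSE]
  fm_h <- fill_map(grid, fill_for(grid, bc, "height"))
  fm_p <- fill_map(grid, fill_for(grid, bc, "pressure"))
  fm_0 <- fill_map(grid, fill_for(grid, bc, "lap2"))
  fm_C <- fill_map(grid, fill_for(grid, bc, "density"))
  A1 <- Lint %*% fm_h$P                  # interior Laplacian of h
  b1 <- as.numeric(Lint %*% fm_h$g0)
  A2 <- Lint %*% fm_0$P                  # Laplacian with torque-free closure
  biA <- A2 %*% A1                       # interior biharmonic of h
  bib <- as.numeric(A2 %*% b1)
  keep <- face_keep(grid, bc)
  closed <- grid$geometry == "disk" && !is.null(bc) &&
    bc$variant == "closed_free"
  if (closed) {
    # no-flux closure in conservative flux form (boundary faces dropped):
    # interior column sums vanish exactly, so the implicit solves preserve
    # fluid volume and receptor totals to round-off
    Fnf <- divflux_matrix(grid, rep(1, grid$nx * grid$ny), keep)
    Lnf <- Fnf[Ri, Ri, drop = FALSE]
    AC <- Lnf; bC <- numeric(grid$n_int)
    Lp <- Lnf
  } else {
    AC <- Lint %*% fm_C$P                # interior Laplacian of densities
    bC <- as.numeric(Lint %*% fm_C$g0)
    Lp <- Lint %*% fm_p$P                # interior Laplacian with p-closure
  }
  Lp6 <- Lp %*% biA                      # sixth-order stabiliser stencil
  out <- list(Lint = Lint, fm_h = fm_h, fm_p = fm_p, fm_C = fm_C,
              A1 = A1, b1 = b1, biA = biA, bib = bib, AC = AC, bC = bC,
              Lp = Lp, Lp6 = Lp6,
              keep = keep,
              diff_factors = new.env(parent = emptyenv()),
              stab_factors = new.env(parent = emptyenv()))
  grid$cache[[key]] <- out
  out
}

# affine pressure operator given frozen densities: p_int = pA %*% h_int + pb
pressure_affine <- function(cons, cfg, C1i, C2i) {
  diag_coef <- C1i + cfg$lam1 * C2i
  pA <- cfg$B * cons$biA + Matrix::Diagonal(x = diag_coef)
  pb <- cfg$B * cons$bib - cfg$lam1 * (C1i + C2i)
  if (cfg$Gamma > 0) {
    pA <- pA - cfg$Gamma * cfg$eps^2 * cons$A1
    pb <- pb - cfg$Gamma * cfg$eps^2 * cons$b1
  }
  list(A = pA, b = pb)
}

# affine drainage operator dh/dt = M_A h + M_b for lagged mobility h^3
height_affine <- function(grid, bc, cons, cfg, h_full, C1i, C2i) {
  hf <- ghost_fill(h_full, grid, fill_for(grid, bc, "height"))
  Fm <- divflux_matrix(grid, as.vector(hf)^3, cons$keep)
  Fint <- Fm[grid$idx_int, , drop = FALSE]
  FP <- Fint %*% cons$fm_p$P
  Fg <- as.numeric(Fint %*% cons$fm_p$g0)
  pr <- pressure_affine(cons, cfg, C1i, C2i)
  cc <- cfg$eps^2 / 12
  list(A = cc * (FP %*% pr$A),
       b = cc * (as.numeric(FP %*% pr$b) + Fg),
       pA = pr$A, pb = pr$b)
}

# factorisation of the constant-coefficient stabiliser
#   Abar = (eps^2/12) * mbar * (B * Lp6 + cbar * Lp)
# which majorises the linearised drainage operator when mbar >= max h^3 and
# cbar >= max(C1 + lam1 C2); reused across steps until dt or the rounded
# majorants change
stabilizer_factor <- function(cons, cfg, grid, mbar, cbar, theta, dt) {
  key <- paste(format(dt, digits = 17), format(mbar, digits = 6),
               format(cbar, digits = 6), format(theta, digits = 6), sep = "|")
  hit <- cons$stab_factors[[key]]
  if (!is.null(hit)) return(hit)
  cc <- cfg$eps^2 / 12
  Abar <- (cc * mbar) * (cfg$B * cons$Lp6 + cbar * cons$Lp)
  if (cfg$Gamma > 0) {
    Abar <- Abar - (cc * mbar * cfg$Gamma * cfg$eps^2) * cons$Lp %*% cons$A1
  }
  Asys <- Matrix::Diagonal(grid$n_int) - (theta * dt) * Abar
  out <- list(fac = Matrix::lu(Asys), Abar = Abar)
  # keep the cache small: refactorisations are rare but keys accumulate
  if (length(ls(cons$stab_factors)) > 24) {
    rm(list = ls(cons$stab_factors), envir = cons$stab_factors)
  }
  cons$stab_factors[[key]] <- out
  out
}
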