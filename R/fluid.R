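# Fluid-domain layout and pressure-field operations.
#
# The two scalae are 2-D rectangular compartments on a regular grid:
# compartment 1 (top, scala vestibuli/media) spans 0 <= z <= H, compartment
# 2 (bottom, scala tympani) spans -H <= z <= 0. Column c corresponds to
# section c; level k = 0..nz counts away from the OCC (z = +/- k h).
# The pressure field satisfies the Laplace equation (inviscid,
# incompressible fluid) with Neumann rows at the oval window and the
# fluid-structure interfaces, a pressure-release round window, and
# pressure equality plus net-flux closure at the helicotrema.

fluid_layout <- function(spec) {
  nx <- spec$n_sections
  nz <- spec$nz
  K1 <- nz + 1L
  list(nx = nx, nz = nz, K1 = K1, h = spec$pitch_um * 1e-6,
       hx = spec$dx_um * 1e-6, ndof = 2L * nx * K1)
}

# fluid DOF index within the fluid block (1-based)
fluid_idx <- function(fl, comp, col, k) {
  (comp - 1L) * fl$nx * fl$K1 + (col - 1L) * fl$K1 + k + 1L
}

#' Slow (traveling-wave) component of the pressure field
#'
#' Subtracts the helicotrema pressure, \eqn{p_{slow}(x,z) = p(x,z) -
#' p(L,0)}, isolating the anti-symmetric slow-wave component from the
#' global (fast) component.
#'
#' @param p complex pressure array of dimension (2, nx, nz+1).
#' @return array of the same shape; exactly zero at (L, 0).
#' @export
slow_pressure <- function(p) {
  stopifnot(length(dim(p)) == 3, dim(p)[1] == 2)
  p - p[1, dim(p)[2], 1]
}

#' Longitudinal fluid velocity from the slow pressure
#'
#' \eqn{v_f = -(1/j\omega\rho)\, \partial p_{slow}/\partial x}, with a
#' centred finite-difference gradient (one-sided at the ends).
#'
#' @param p_slow complex array (2, nx, nz+1).
#' @param rho fluid density (kg/m^3).
#' @param omega angular frequency (rad/s), positive.
#' @param h grid pitch (m).
#' @return complex array of the longitudinal velocity (m/s).
#' @export
fluid_velocity <- function(p_slow, rho, omega, h) {
  if (omega <= 0) stop("omega must be positive")
  d <- dim(p_slow)
  nx <- d[2]
  g <- p_slow
  if (nx < 2) stop("need at least two columns")
  g[, 2:(nx - 1), ] <- (p_slow[, 3:nx, , drop = FALSE] -
                        p_slow[, 1:(nx - 2), , drop = FALSE]) / (2 * h)
  g[, 1, ] <- (p_slow[, 2, ] - p_slow[, 1, ]) / h
  g[, nx, ] <- (p_slow[, nx, ] - p_slow[, nx - 1, ]) / h
  -g / (1i * omega * rho)
}

# Triplets and RHS for the fluid block and its couplings, with global DOF
# offsets. Returns list(i, j, re+im values as complex, b_rows, b_vals,
# colmap additions are handled by the caller).
fluid_operator_triplets <- function(model, omega, off_fluid, off_struct,
                                    off_vm) {
  spec <- model$spec
  fl <- model$fluid
  nx <- fl$nx; nz <- fl$nz; K1 <- fl$K1; h <- fl$h; hx <- fl$hx
  rx <- (h / hx)^2          # anisotropy weight of the x-stencil
  rho <- spec$rho
  cp <- model$mats$cp
  gi <- function(comp, col, k) off_fluid + fluid_idx(fl, comp, col, k)

  ii <- integer(0); jj <- integer(0); vv <- complex(0)
  addt <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); vv <<- c(vv, v)
  }

  cols_mid <- 2:(nx - 1)
  for (comp in 1:2) {
    # interior rows 0 < k < nz
    if (nz >= 2) {
      kk <- 1:(nz - 1)
      g <- expand.grid(col = cols_mid, k = kk)
      ctr <- gi(comp, g$col, g$k)
      addt(ctr, ctr, rep(-2 * (1 + rx) + 0i, length(ctr)))
      addt(ctr, gi(comp, g$col - 1L, g$k), rep(rx + 0i, length(ctr)))
      addt(ctr, gi(comp, g$col + 1L, g$k), rep(rx + 0i, length(ctr)))
      addt(ctr, gi(comp, g$col, g$k - 1L), rep(1 + 0i, length(ctr)))
      addt(ctr, gi(comp, g$col, g$k + 1L), rep(1 + 0i, length(ctr)))
    }
    # rigid outer wall k = nz (z = +/- H): mirror ghost
    ctr <- gi(comp, cols_mid, nz)
    addt(ctr, ctr, rep(-2 * (1 + rx) + 0i, length(ctr)))
    addt(ctr, gi(comp, cols_mid - 1L, nz), rep(rx + 0i, length(ctr)))
    addt(ctr, gi(comp, cols_mid + 1L, nz), rep(rx + 0i, length(ctr)))
    addt(ctr, gi(comp, cols_mid, nz - 1L), rep(2 + 0i, length(ctr)))
  }

  # FSI rows k = 0, interior columns: dp/dz one-sided = rho omega^2 u kappa
  wsc <- spec$scala_width_factor
  for (comp in 1:2) {
    ctr <- gi(comp, cols_mid, 0L)
    nxt <- gi(comp, cols_mid, 1L)
    sgn <- if (comp == 1L) 1 else 1  # both rows written as p1 - p0 = ...
    addt(ctr, nxt, rep(1 + 0i, length(ctr)))
    addt(ctr, ctr, rep(-1 + 0i, length(ctr)))
    udof <- if (comp == 1L) cp$T2y[cols_mid] else cp$B2y[cols_mid]
    kap <- if (comp == 1L) cp$w_tm[cols_mid] / (wsc * cp$w_bm[cols_mid])
           else rep(1 / wsc, length(cols_mid))
    ok <- !is.na(udof)
    # top compartment: (p1 - p0)/h = +rho w^2 u kappa
    # bottom compartment: (p0 - p1)/h = +rho w^2 u kappa, i.e. (p1 - p0)/h = -..
    csgn <- if (comp == 1L) -1 else 1
    addt(ctr[ok], off_struct + udof[ok],
         csgn * h * rho * omega^2 * kap[ok] + 0i)
  }

  # oval window column (top compartment, x = 0): (p2 - p1)/hx = -j w rho v_st
  bi <- integer(0); bv <- complex(0)
  ctr <- gi(1L, 1L, 0:nz)
  addt(ctr, gi(1L, 2L, 0:nz), rep(1 + 0i, K1))
  addt(ctr, ctr, rep(-1 + 0i, K1))
  bi <- c(bi, ctr)
  bv <- c(bv, rep(-hx * 1i * omega * rho * spec$v_stapes, K1))

  # round window column (bottom compartment, x = 0): p = 0
  ctr <- gi(2L, 1L, 0:nz)
  addt(ctr, ctr, rep(1 + 0i, K1))

  # helicotrema column (x = L): equality to reference + net-flux closure
  ref <- gi(1L, nx, 0L)
  others <- c(gi(1L, nx, 1:nz), gi(2L, nx, 0:nz))
  addt(others, others, rep(1 + 0i, length(others)))
  addt(others, rep(ref, length(others)), rep(-1 + 0i, length(others)))
  allk <- c(gi(1L, nx, 0:nz), gi(2L, nx, 0:nz))
  prev <- c(gi(1L, nx - 1L, 0:nz), gi(2L, nx - 1L, 0:nz))
  addt(rep(ref, length(allk)), allk, rep(-1 + 0i, length(allk)))
  addt(rep(ref, length(prev)), prev, rep(1 + 0i, length(prev)))

  list(i = ii, j = jj, v = vv, b_i = bi, b_v = bv)
}
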