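#' Assemble stiffness, mass and damping matrices of the OCC
#'
#' Beam elements are assembled into symmetric sparse stiffness and
#' consistent-mass matrices over the free DOFs.  The damping matrix is
#' stiffness-proportional Rayleigh damping with the position-dependent
#' coefficient [damping_coefficient()], plus two families of discrete
#' dampers: the subtectorial-space shear damper on the hair-bundle DOF
#' pair and the OHC axial damper.
#'
#' @param mesh mesh from [build_occ_mesh()].
#' @param params section parameter table.
#' @param spec a [model_spec()].
#' @return list with sparse \code{K}, \code{M}, \code{C} over free DOFs,
#'   triplet representations (\code{ktrip}, \code{mtrip}, \code{ctrip}),
#'   the free-DOF map and the per-section coupling registry.
#' @export
assemble_matrices <- function(mesh, params, spec) {
  nv <- 0.3  # Poisson ratio for soft tissue shear modulus
  damp_scale <- if ("damping" %in% names(spec$scales))
    spec$scales[["damping"]] else 1
  beams <- mesh$beams
  nb <- nrow(beams)
  nodes <- mesh$nodes
  nraw <- nrow(nodes) * 6L

  ti <- integer(nb * 144L); tj <- integer(nb * 144L)
  kv <- numeric(nb * 144L); mv <- numeric(nb * 144L)
  esec <- integer(nb * 144L)
  idx12 <- function(n1, n2) c((n1 - 1L) * 6L + 1:6, (n2 - 1L) * 6L + 1:6)
  bE <- beams$E; bA <- beams$A; bIy <- beams$Iy; bIz <- beams$Iz
  bJ <- beams$J; bn1 <- beams$n1; bn2 <- beams$n2; bsec <- beams$sec
  ptr <- 0L
  for (e in seq_len(nb)) {
    gm <- beam_global_matrices(bE[e], bE[e] / (2 * (1 + nv)), bA[e], bIy[e],
                               bIz[e], bJ[e], spec$rho_tissue,
                               nodes[bn1[e], ], nodes[bn2[e], ])
    gi <- idx12(bn1[e], bn2[e])
    rng <- ptr + 1:144
    ti[rng] <- rep(gi, times = 12L)
    tj[rng] <- rep(gi, each = 12L)
    kv[rng] <- as.vector(gm$k)
    mv[rng] <- as.vector(gm$m)
    esec[rng] <- bsec[e]
    ptr <- ptr + 144L
  }
  # Rayleigh damping: alpha_C(x_e) * K_e (alpha in seconds)
  alpha_e <- damping_coefficient(params$x_mm)[esec] * 1e-6 * damp_scale
  cv <- kv * alpha_e

  # discrete elements ------------------------------------------------------
  reg <- mesh$reg
  N <- spec$n_sections
  um <- 1e-6
  zdof <- function(nids) (nids - 1L) * 6L + 3L
  # hair-bundle shear spring (3 merged rows per 10 um of length) +
  # subtectorial damper
  ncell <- 3 * spec$dx_um / 10
  k_hb <- ncell * params$k_ohb * 1e-3
  c_sts <- damp_scale * subtectorial_damping(
    spec$mu_sts, spec$dx_um * um,
    params$tm_width_body * um, spec$h_sts)
  alpha_s <- damping_coefficient(params$x_mm) * 1e-6 * damp_scale
  iR <- zdof(reg$R2); iT <- zdof(reg$T2)
  pair_i <- c(iR, iT, iR, iT)
  pair_j <- c(iR, iT, iT, iR)
  pair_k <- c(k_hb, k_hb, -k_hb, -k_hb)
  pair_c <- rep(alpha_s, 4L) * pair_k + c(c_sts, c_sts, -c_sts, -c_sts)
  ti <- c(ti, pair_i); tj <- c(tj, pair_j)
  kv <- c(kv, pair_k); mv <- c(mv, numeric(4L * N))
  cv <- c(cv, pair_c); esec <- c(esec, rep(reg$sec, 4L))
  # stereocilia axial strut: the bundle is orders of magnitude stiffer
  # along its height (transverse, y) than in pivot shear
  k_ax_hb <- spec$hb_axial_factor * k_hb
  iRy <- (reg$R2 - 1L) * 6L + 2L; iTy <- (reg$T2 - 1L) * 6L + 2L
  ti <- c(ti, iRy, iTy, iRy, iTy)
  tj <- c(tj, iRy, iTy, iTy, iRy)
  kvy <- c(k_ax_hb, k_ax_hb, -k_ax_hb, -k_ax_hb)
  kv <- c(kv, kvy); mv <- c(mv, numeric(4L * N))
  cv <- c(cv, rep(alpha_s, 4L) * kvy); esec <- c(esec, rep(reg$sec, 4L))
  # OHC axial damper (3 merged rows), truss pattern c * a a^T
  c_ax <- ncell * params$c_ohc * 1e-6 * damp_scale
  sD <- pmin(pmax(reg$sec - spec$ohc_tilt, 1L), N)
  regD1 <- reg$D1[sD]
  aR <- nodes[reg$R2, ]; aD <- nodes[regD1, ]
  av <- aR - aD
  av <- av / sqrt(rowSums(av^2))
  tdof <- function(nids, d) (nids - 1L) * 6L + d
  for (d1 in 1:3) for (d2 in 1:3) {
    blk <- c_ax * av[, d1] * av[, d2]
    ti <- c(ti, tdof(reg$R2, d1), tdof(regD1, d1),
            tdof(reg$R2, d1), tdof(regD1, d1))
    tj <- c(tj, tdof(reg$R2, d2), tdof(regD1, d2),
            tdof(regD1, d2), tdof(reg$R2, d2))
    cv <- c(cv, blk, blk, -blk, -blk)
    kv <- c(kv, numeric(4L * N)); mv <- c(mv, numeric(4L * N))
    esec <- c(esec, rep(reg$sec, 4L))
  }

  # constrain and renumber -------------------------------------------------
  fixed <- mesh$fixed
  freeidx <- rep(NA_integer_, nraw)
  freeidx[!fixed] <- seq_len(sum(!fixed))
  nfree <- sum(!fixed)
  keep <- !fixed[ti] & !fixed[tj]
  fi <- freeidx[ti[keep]]; fj <- freeidx[tj[keep]]
  kvf <- kv[keep]; mvf <- mv[keep]; cvf <- cv[keep]; secf <- esec[keep]
  sp <- function(v) Matrix::sparseMatrix(i = fi, j = fj, x = v,
                                         dims = c(nfree, nfree))
  K <- sp(kvf); M <- sp(mvf); C <- sp(cvf)

  # per-section coupling registry over free DOFs
  fdof <- function(raw) freeidx[raw]
  cp <- data.frame(sec = reg$sec, x_mm = params$x_mm)
  cp$B2y <- fdof((reg$B2 - 1L) * 6L + 2L)
  cp$T2y <- fdof((reg$T2 - 1L) * 6L + 2L)
  cp$T2z <- fdof(zdof(reg$T2))
  cp$R2z <- fdof(zdof(reg$R2))
  for (d in 1:3) {
    cp[[paste0("R2t", d)]] <- fdof(tdof(reg$R2, d))
    cp[[paste0("D1t", d)]] <- fdof(tdof(regD1, d))
  }
  cp$ax <- av[, 1]; cp$ay <- av[, 2]; cp$az <- av[, 3]
  cp$ohc_len <- sqrt(rowSums((aR - aD)^2))
  cp$w_bm <- (params$bm_width_a + params$bm_width_p) * um
  cp$w_tm <- params$tm_width_body * um
  cp$k_hb <- k_hb

  dof_sec <- mesh$node_sec[ceiling(seq_len(nraw) / 6)][!fixed]
  list(K = K, M = M, C = C,
       ktrip = list(i = fi, j = fj, v = kvf),
       mtrip = list(i = fi, j = fj, v = mvf),
       ctrip = list(i = fi, j = fj, v = cvf, sec = secf),
       freeidx = freeidx, fixed = fixed, nfree = nfree,
       dof_sec = dof_sec, cp = cp)
}

#' Static solve of the structural system
#'
#' Solves \eqn{K u = f} over the free DOFs with a sparse Cholesky
#' factorization and verifies the relative residual.
#'
#' @param mats matrices from [assemble_matrices()] (or a
#'   \code{cochlea_model$mats}).
#' @param load numeric vector (or matrix of right-hand sides) over free
#'   DOFs.
#' @param tol relative residual tolerance.
#' @return displacement vector (or matrix) over free DOFs.
#' @export
static_solve <- function(mats, load, tol = 1e-10) {
  K <- mats$K
  load <- as.matrix(load)
  if (nrow(load) != mats$nfree) stop("load must cover the free DOFs")
  ch <- tryCatch(
    Matrix::Cholesky(Matrix::forceSymmetric(K), LDL = FALSE, super = TRUE),
    error = function(e)
      stop("singular stiffness matrix (unconstrained mechanism): ",
           conditionMessage(e)))
  u <- as.matrix(Matrix::solve(ch, load))
  r <- K %*% u - load
  nl <- sqrt(colSums(load^2))
  nr <- sqrt(colSums(as.matrix(r)^2))
  relres <- ifelse(nl > 0, nr / nl, nr)
  if (any(relres > tol & nl > 0))
    warning("static solve residual above contract: ", max(relres))
  if (ncol(u) == 1L) drop(u) else u
}
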