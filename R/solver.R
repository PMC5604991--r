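#' Assemble the coupled fluid-structure-electrical system at one frequency
#'
#' Builds the complex triplet representation of the monolithic matrix over
#' structural, membrane-potential and fluid-pressure unknowns, with the
#' harmonic convention \eqn{e^{+j\omega t}}.  The structural diagonal
#' block is \eqn{K + j\omega C - \omega^2 M}; fluid rows implement the
#' discrete Laplace operator with window/FSI/helicotrema boundary rows;
#' off-diagonal blocks couple pressure to structural force, structural
#' velocity to the fluid Neumann rows, bundle shear to the transduction
#' current and membrane potential to the active forces.  When
#' \code{active} is \code{FALSE} only the force-coupling columns are
#' zeroed; the electrical circuit is still driven and solved.
#'
#' @param model a [build_model()] bundle.
#' @param omega angular frequency (rad/s), positive.
#' @param active include the OHC force feedback columns.
#' @param g_ohc_scale,g_met_scale overrides of the spec's gain scales.
#' @return list with triplets, right-hand side, column (block) map and
#'   index offsets.
#' @export
assemble_coupled <- function(model, omega, active = model$spec$active,
                             g_ohc_scale = model$spec$g_ohc_scale,
                             g_met_scale = model$spec$g_met_scale) {
  spec <- model$spec
  mats <- model$mats
  elec <- model$elec
  cp <- mats$cp
  fl <- model$fluid
  N <- spec$n_sections
  ns <- mats$nfree
  off_vm <- ns
  off_fluid <- ns + N
  ntot <- off_fluid + fl$ndof

  # structural block
  si <- c(mats$ktrip$i, mats$ctrip$i, mats$mtrip$i)
  sj <- c(mats$ktrip$j, mats$ctrip$j, mats$mtrip$j)
  sv <- c(mats$ktrip$v + 0i, 1i * omega * mats$ctrip$v,
          -omega^2 * mats$mtrip$v)

  # membrane-potential rows: (G + jwC) V - S_I * eps * (z_T2 - z_R2) = 0
  eps <- spec$met_sign
  vm_rows <- off_vm + seq_len(N)
  ei <- vm_rows; ej <- vm_rows
  ev <- elec$G_tot + 1i * omega * elec$C_tot
  ok <- !is.na(cp$T2z) & !is.na(cp$R2z)
  ei <- c(ei, vm_rows[ok], vm_rows[ok])
  ej <- c(ej, cp$T2z[ok], cp$R2z[ok])
  ev <- c(ev, -eps * elec$S_I[ok] + 0i, eps * elec$S_I[ok] + 0i)

  ai <- integer(0); aj <- integer(0); av <- complex(0)
  if (active) {
    # somatic force columns: f_OHC = g_eff * V_m, contraction-positive pair
    ge <- elec$g_eff * g_ohc_scale
    avec <- cbind(cp$ax, cp$ay, cp$az)
    for (d in 1:3) {
      rR <- cp[[paste0("R2t", d)]]; rD <- cp[[paste0("D1t", d)]]
      ok <- !is.na(rR) & !is.na(rD)
      ai <- c(ai, rR[ok], rD[ok])
      aj <- c(aj, vm_rows[ok], vm_rows[ok])
      av <- c(av, ge[ok] * avec[ok, d] + 0i, -ge[ok] * avec[ok, d] + 0i)
    }
    # hair-bundle gating force: negative spring c_f between shear DOFs
    cf <- elec$f_met_eff * elec$dp_dX * g_met_scale
    ok <- !is.na(cp$T2z) & !is.na(cp$R2z)
    ai <- c(ai, cp$T2z[ok], cp$T2z[ok], cp$R2z[ok], cp$R2z[ok])
    aj <- c(aj, cp$T2z[ok], cp$R2z[ok], cp$T2z[ok], cp$R2z[ok])
    av <- c(av, -cf[ok] + 0i, cf[ok] + 0i, cf[ok] + 0i, -cf[ok] + 0i)
  }

  # pressure -> structural force columns
  dxm <- spec$dx_um * 1e-6
  pb0 <- off_fluid + fluid_idx(fl, 2L, seq_len(N), 0L)
  pt0 <- off_fluid + fluid_idx(fl, 1L, seq_len(N), 0L)
  okb <- !is.na(cp$B2y); okt <- !is.na(cp$T2y)
  fi <- c(cp$B2y[okb], cp$T2y[okt])
  fj <- c(pb0[okb], pt0[okt])
  fv <- c(-dxm * cp$w_bm[okb] + 0i, dxm * cp$w_tm[okt] + 0i)

  flt <- fluid_operator_triplets(model, omega, off_fluid, 0L, off_vm)

  b <- complex(ntot)
  b[flt$b_i] <- flt$b_v

  colmap <- c(mats$dof_sec, seq_len(N),
              rep(rep(seq_len(fl$nx), each = fl$K1), 2))
  list(i = c(si, ei, ai, fi, flt$i), j = c(sj, ej, aj, fj, flt$j),
       v = c(sv, ev, av, fv, flt$v), b = b, colmap = colmap,
       ntot = ntot, off_vm = off_vm, off_fluid = off_fluid,
       omega = omega, active = active,
       g_ohc_scale = g_ohc_scale, g_met_scale = g_met_scale)
}

#' Solve the coupled system at one frequency
#'
#' Direct block-tridiagonal factorization of the monolithic complex
#' system (unknowns ordered by longitudinal column).  The relative
#' residual contract is 1e-8.
#'
#' @param model a [build_model()] bundle.
#' @param freq_hz stimulating frequency (Hz).
#' @param active,g_ohc_scale,g_met_scale see [assemble_coupled()].
#' @return object of class \code{cochlea_solution}: complex pressure array
#'   \code{p} (compartment, column, level), structural displacement
#'   \code{u}, and a per-section data frame \code{sections} with BM/TM
#'   displacements, bundle shear, OHC state (\code{V_m}, \code{i_met},
#'   \code{d_ohc} contraction-positive, \code{v_ohc}, \code{f_ohc},
#'   \code{f_met}) per cell.
#' @export
solve_harmonic <- function(model, freq_hz, active = model$spec$active,
                           g_ohc_scale = model$spec$g_ohc_scale,
                           g_met_scale = model$spec$g_met_scale) {
  if (freq_hz <= 0) stop("frequency must be positive")
  omega <- 2 * pi * freq_hz
  sys <- assemble_coupled(model, omega, active, g_ohc_scale, g_met_scale)
  sol <- block_tridiag_solve(sys$ntot, max(sys$colmap), sys$colmap,
                             sys$i, sys$j, Re(sys$v), Im(sys$v),
                             Re(sys$b), Im(sys$b))
  if (sol$relres > 1e-8)
    stop(sprintf("harmonic solve residual %.2e at %g Hz", sol$relres,
                 freq_hz))
  x <- complex(real = sol$re, imaginary = sol$im)

  spec <- model$spec
  fl <- model$fluid
  N <- spec$n_sections
  u <- x[seq_len(sys$off_vm)]
  V_m <- x[sys$off_vm + seq_len(N)]
  p <- array(x[(sys$off_fluid + 1):sys$ntot], dim = c(fl$K1, fl$nx, 2))
  p <- aperm(p, c(3, 2, 1))   # (compartment, column, level)

  cp <- model$mats$cp
  elec <- model$elec
  pick <- function(col) {
    out <- rep(0 + 0i, length(col))
    ok <- !is.na(col)
    out[ok] <- u[col[ok]]
    out
  }
  eps <- spec$met_sign
  d_hb <- eps * (pick(cp$T2z) - pick(cp$R2z))
  elong <- complex(N)
  for (d in 1:3) {
    a_d <- c(cp$ax, cp$ay, cp$az)[(d - 1) * N + seq_len(N)]
    elong <- elong + a_d * (pick(cp[[paste0("R2t", d)]]) -
                            pick(cp[[paste0("D1t", d)]]))
  }
  d_ohc <- -elong                      # contraction-positive length change
  g_cell <- elec$g_cell * (if (active) g_ohc_scale else 0)
  sections <- data.frame(
    sec = cp$sec, x_mm = cp$x_mm,
    y_bm = pick(cp$B2y), y_tm = pick(cp$T2y),
    z_tm = pick(cp$T2z), z_rl = pick(cp$R2z),
    d_hb = d_hb,
    i_met = elec$S_I * d_hb,
    dp_open = elec$dp_dX * d_hb,
    V_m = V_m,
    d_ohc = d_ohc, v_ohc = 1i * omega * d_ohc,
    f_ohc = g_cell * V_m,
    f_met = elec$f_met_cell * g_met_scale * elec$dp_dX * d_hb *
      (if (active) 1 else 0))

  out <- list(freq_hz = freq_hz, omega = omega, active = active,
              g_ohc_scale = sys$g_ohc_scale, g_met_scale = sys$g_met_scale,
              u = u, V_m = V_m, p = p, sections = sections,
              relres = sol$relres, v_stapes = spec$v_stapes)
  class(out) <- "cochlea_solution"
  out
}

#' @export
print.cochlea_solution <- function(x, ...) {
  pk <- peak_location(x)
  cat(sprintf("<cochlea_solution> %.3g kHz, %s; |y_BM| peak %.3g nm at x = %.2f mm\n",
              x$freq_hz / 1000, if (x$active) "active" else "passive",
              max(abs(x$sections$y_bm)) * 1e9, pk))
  invisible(x)
}

#' Location of the peak BM displacement
#' @param sol a \code{cochlea_solution}.
#' @return x (mm) of the section with maximal BM displacement magnitude.
#' @export
peak_location <- function(sol) {
  s <- sol$sections
  s$x_mm[which.max(abs(s$y_bm))]
}

#' Average pressure magnitude over the oval window
#' @param sol a \code{cochlea_solution}.
#' @return mean |p| (Pa) over the oval-window boundary cells.
#' @export
stapes_pressure <- function(sol) {
  mean(abs(sol$p[1, 1, ]))
}

#' Frequency sweep
#'
#' Solves the coupled system at each frequency; failures are caught and
#' reported per frequency while the sweep continues.
#'
#' @param model a [build_model()] bundle.
#' @param freqs_hz vector of frequencies (Hz).
#' @param active,g_ohc_scale,g_met_scale see [assemble_coupled()].
#' @return object of class \code{cochlea_sweep}: list of solutions plus
#'   the frequency vector.
#' @export
frequency_sweep <- function(model, freqs_hz, active = model$spec$active,
                            g_ohc_scale = model$spec$g_ohc_scale,
                            g_met_scale = model$spec$g_met_scale) {
  if (length(freqs_hz) == 0) stop("frequency list is empty")
  sols <- vector("list", length(freqs_hz))
  for (k in seq_along(freqs_hz)) {
    sols[[k]] <- tryCatch(
      solve_harmonic(model, freqs_hz[k], active, g_ohc_scale, g_met_scale),
      error = function(e) {
        warning("solve failed at ", freqs_hz[k], " Hz: ",
                conditionMessage(e))
        NULL
      })
  }
  out <- list(freqs_hz = freqs_hz, solutions = sols, active = active)
  class(out) <- "cochlea_sweep"
  out
}

#' BM displacement gain re stapes displacement, in dB
#'
#' Gain at section \code{sec} for each solved frequency:
#' \eqn{20 \log_{10}(|y_{BM}| / |d_{stapes}|)} with
#' \eqn{|d_{stapes}| = v_{stapes}/\omega}.
#'
#' @param sweep a \code{cochlea_sweep}.
#' @param sec section index.
#' @return data frame with \code{freq_hz}, \code{gain_db}, \code{phase_cyc}
#'   (BM phase re stapes displacement, unwrapped, in cycles).
#' @export
sweep_gain <- function(sweep, sec) {
  rows <- lapply(sweep$solutions, function(s) {
    if (is.null(s)) return(NULL)
    y <- s$sections$y_bm[sec]
    dst <- s$v_stapes / (1i * s$omega)   # stapes displacement phasor
    data.frame(freq_hz = s$freq_hz, gain_db = 20 * log10(abs(y) / abs(dst)),
               phase_raw = Arg(y / dst))
  })
  d <- do.call(rbind, rows)
  d <- d[order(d$freq_hz), ]
  ph <- d$phase_raw
  if (length(ph) > 1) {
    dp <- diff(ph)
    dp <- dp - 2 * pi * round(dp / (2 * pi))
    ph <- cumsum(c(ph[1], dp))
  }
  d$phase_cyc <- ph / (2 * pi)
  d$phase_raw <- NULL
  d
}
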