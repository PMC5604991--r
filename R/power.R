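# Cycle-averaged power metrics: power flux carried by the scala fluid,
# viscous dissipation in the OCC, stapes input power, fluid-to-structure
# power, the effective stapes width calibration, per-OHC power, and the
# cochlear input impedance.

#' Scala width profile used in the power integrals
#'
#' The 2-D fluid model carries an implied radial width; power integrals
#' multiply by the scala width \eqn{w(x)}, taken proportional to the BM
#' width (factor \code{scala_width_factor} of the spec).
#'
#' @param model a [build_model()] bundle.
#' @return numeric vector of widths (m), one per column.
#' @export
scala_width <- function(model) {
  model$spec$scala_width_factor * model$mats$cp$w_bm
}

#' Acoustic power flux along the cochlea
#'
#' \eqn{P_{flux}(x) = \tfrac12 w \int_{-H}^{H} Re(p_{slow} v_f^{*})\,dz}
#' by trapezoidal quadrature over both compartments; positive values flow
#' toward the apex.
#'
#' @param model a [build_model()] bundle.
#' @param sol a \code{cochlea_solution}.
#' @return data frame with \code{x_mm} and \code{P_flux} (W).
#' @export
power_flux <- function(model, sol) {
  fl <- model$fluid
  ps <- slow_pressure(sol$p)
  vf <- fluid_velocity(ps, model$spec$rho, sol$omega, fl$hx)
  integrand <- Re(ps * Conj(vf))        # (comp, col, level)
  wz <- rep(fl$h, fl$K1); wz[c(1, fl$K1)] <- fl$h / 2   # trapezoid in z
  iz <- apply(integrand, c(1, 2), function(v) sum(v * wz))
  flux <- 0.5 * scala_width(model) * (iz[1, ] + iz[2, ])
  data.frame(x_mm = model$mats$cp$x_mm, P_flux = flux)
}

#' Viscous power dissipated in the OCC
#'
#' \eqn{P_{loss} = \tfrac12 v^{H} C v} with \eqn{v = j\omega u}; returns
#' the total and the per-section decomposition (element damping grouped by
#' section), which sums to the total.
#'
#' @param model a [build_model()] bundle.
#' @param sol a \code{cochlea_solution}.
#' @return list with \code{total} (W) and \code{per_section} data frame.
#' @export
power_loss <- function(model, sol) {
  ct <- model$mats$ctrip
  u <- sol$u
  contrib <- 0.5 * sol$omega^2 * Re(Conj(u[ct$i]) * ct$v * u[ct$j])
  per <- tapply(contrib, ct$sec, sum)
  ps <- numeric(model$spec$n_sections)
  ps[as.integer(names(per))] <- per
  list(total = sum(contrib),
       per_section = data.frame(x_mm = model$mats$cp$x_mm, P_loss = ps))
}

#' Power delivered through the stapes
#'
#' \eqn{P_{stapes} = \tfrac12 w_{stapes} \int_0^H Re(p(0,z) v_f^{*}(0,z))
#' \,dz}.  At the oval window the longitudinal fluid velocity equals the
#' prescribed stapes velocity.
#'
#' @param model a [build_model()] bundle.
#' @param sol a \code{cochlea_solution}.
#' @param w_stapes effective stapes width (m); defaults to the calibrated
#'   value stored in the model, else 1.
#' @return power (W).
#' @export
stapes_power <- function(model, sol, w_stapes = NULL) {
  if (is.null(w_stapes))
    w_stapes <- if (!is.null(model$w_stapes)) model$w_stapes else 1
  fl <- model$fluid
  wz <- rep(fl$h, fl$K1); wz[c(1, fl$K1)] <- fl$h / 2
  vst <- model$spec$v_stapes + 0i
  0.5 * w_stapes * sum(Re(sol$p[1, 1, ] * Conj(vst)) * wz)
}

#' Power provided by the fluid to the OCC
#'
#' \eqn{P_{f2s} = \tfrac12 \int_0^L Re(f_{fluid} v_{CP}^{*})\,dx} where
#' \eqn{v_{CP}} holds the transverse velocities of the two interface
#' surfaces (TM edge above, BM midline below) and \eqn{f_{fluid}} the
#' pressure forces consistent with the discrete coupling.
#'
#' @param model a [build_model()] bundle.
#' @param sol a \code{cochlea_solution}.
#' @return power (W).
#' @export
fluid_to_structure_power <- function(model, sol) {
  spec <- model$spec
  cp <- model$mats$cp
  s <- sol$sections
  dxm <- spec$dx_um * 1e-6
  jw <- 1i * sol$omega
  f_bot <- sol$p[2, , 1] * dxm * cp$w_bm       # pushes +y from below
  f_top <- -sol$p[1, , 1] * dxm * cp$w_tm      # pushes -y from above
  0.5 * sum(Re(f_bot * Conj(jw * s$y_bm) + f_top * Conj(jw * s$y_tm)))
}

#' Calibrate the effective stapes width
#'
#' Solves the passive model at a reference frequency and sets
#' \eqn{w_{stapes}} from the equality \eqn{P_{stapes} = P_{f2s}} that
#' holds for a passive cochlea.  The width is stored in the model and
#' reused unchanged for active runs.
#'
#' @param model a [build_model()] bundle.
#' @param freq_hz calibration frequency (Hz); a passive mid-frequency run.
#' @return the model with \code{w_stapes} set (m).
#' @export
calibrate_stapes_width <- function(model, freq_hz = 4000) {
  sol <- solve_harmonic(model, freq_hz, active = FALSE)
  p1 <- stapes_power(model, sol, w_stapes = 1)
  if (abs(p1) < 1e-300) stop("vanishing stapes power integrand")
  model$w_stapes <- fluid_to_structure_power(model, sol) / p1
  model
}

#' Power generated by outer hair cells
#'
#' \eqn{P_{OHC} = \tfrac12 Re(f_{OHC} v_{OHC}^{*})} per cell (both
#' phasors contraction-positive); positive when the cell powers its
#' surroundings.  The merged-row element power is three times the
#' per-cell value.
#'
#' @param model a [build_model()] bundle.
#' @param sol a \code{cochlea_solution}.
#' @return data frame with \code{x_mm}, \code{P_ohc_cell} (W per cell),
#'   \code{P_ohc_section} (W, all 3 cells) and the f-v phase
#'   \code{phase_deg} (phase of v_OHC minus phase of f_OHC, degrees,
#'   wrapped to (-180, 180]).
#' @export
ohc_power <- function(model, sol) {
  s <- sol$sections
  Pc <- 0.5 * Re(s$f_ohc * Conj(s$v_ohc))
  ph <- (Arg(s$v_ohc) - Arg(s$f_ohc)) * 180 / pi
  ph <- ((ph + 180) %% 360) - 180
  ph[ph == -180] <- 180
  data.frame(x_mm = s$x_mm, P_ohc_cell = Pc,
             P_ohc_section = model$elec$ncell * Pc, phase_deg = ph)
}

#' Active hair-bundle power (extension)
#'
#' Cycle-averaged power of the gating force pair, computed analogously to
#' the somatic OHC power.  With instantaneous (displacement-proportional)
#' gating this is numerically zero; it is reported to close the active
#' energy balance.
#'
#' @param model a [build_model()] bundle.
#' @param sol a \code{cochlea_solution}.
#' @return total power (W) over all sections (merged rows).
#' @export
met_power <- function(model, sol) {
  s <- sol$sections
  jw <- 1i * sol$omega
  # force pair acts on the shear coordinate d_hb; per section = 3 cells
  sum(0.5 * Re(model$elec$ncell * s$f_met * Conj(jw * s$d_hb)))
}

#' Cochlear input impedance
#'
#' \eqn{Z = p_{stapes} / (v_{stapes} A_{stapes})}.
#'
#' @param sol a \code{cochlea_solution}.
#' @param area_stapes stapes footplate area (m^2); 0.8 mm^2 default.
#' @return impedance magnitude (Pa s/m^3).
#' @export
input_impedance <- function(sol, area_stapes = 0.8e-6) {
  v <- sol$v_stapes
  if (v == 0) stop("zero stapes velocity")
  stapes_pressure(sol) / (v * area_stapes)
}

#' Decibels re 1 fW
#' @param P power (W).
#' @return dB re 1 fW (1e-15 W).
#' @export
db_re_fw <- function(P) 10 * log10(P / 1e-15)

#' Full power report at one frequency
#'
#' @param model a [build_model()] bundle (ideally with a calibrated
#'   stapes width).
#' @param sol a \code{cochlea_solution}.
#' @return list of class \code{power_report}.
#' @export
power_report <- function(model, sol) {
  pl <- power_loss(model, sol)
  ohc <- ohc_power(model, sol)
  out <- list(freq_hz = sol$freq_hz, active = sol$active,
              P_flux = power_flux(model, sol),
              P_loss_total = pl$total, P_loss = pl$per_section,
              P_stapes = stapes_power(model, sol),
              P_f2s = fluid_to_structure_power(model, sol),
              P_ohc = ohc, P_ohc_total = sum(ohc$P_ohc_section),
              P_met_total = met_power(model, sol),
              w_stapes = model$w_stapes,
              Z_input = input_impedance(sol))
  class(out) <- "power_report"
  out
}

#' @export
print.power_report <- function(x, ...) {
  cat(sprintf("<power_report> %.3g kHz (%s)\n", x$freq_hz / 1000,
              if (x$active) "active" else "passive"))
  cat(sprintf("  P_stapes = %.4g W, P_f2s = %.4g W, P_loss = %.4g W\n",
              x$P_stapes, x$P_f2s, x$P_loss_total))
  cat(sprintf("  sum P_OHC = %.4g W, P_MET = %.4g W, Z = %.3g GPa s/m^3\n",
              x$P_ohc_total, x$P_met_total, x$Z_input / 1e9))
  invisible(x)
}
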