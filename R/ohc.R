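#' Small-signal mechano-transduction sensitivity
#'
#' The transduction channel is linearized as a two-state Boltzmann gate.
#' The gating force is the product of the gating swing b and the gating
#' spring stiffness k_gs; the open-probability sensitivity to bundle shear
#' X is \eqn{dp/dX = b k_{gs} p_0 (1-p_0) / k_B T} and the current
#' sensitivity is \eqn{dI/dX = G_{s,max} (E_e - v_{m,0})\, dp/dX} with the
#' conventional MET driving potential (endocochlear potential minus the
#' negative resting potential).
#'
#' @param G_s_max stereocilia conductance (S).
#' @param E_e endocochlear potential (V).
#' @param v_m0 resting membrane potential (V), negative.
#' @param p_open0 resting open probability.
#' @param gating_swing gating swing (m).
#' @param k_gs gating spring stiffness (N/m).
#' @param kBT thermal energy (J).
#' @return list with \code{z_gate} (N), \code{dp_dX} (1/m) and
#'   \code{dI_dX} (A/m).
#' @export
met_sensitivity <- function(G_s_max, E_e, v_m0, p_open0,
                            gating_swing = 0.7e-9, k_gs = 6e-3,
                            kBT = 4.28e-21) {
  z_gate <- gating_swing * k_gs
  dp_dX <- z_gate * p_open0 * (1 - p_open0) / kBT
  dI_dX <- G_s_max * (E_e - v_m0) * dp_dX
  list(z_gate = z_gate, dp_dX = dp_dX, dI_dX = dI_dX)
}

#' First-order RC response of the OHC basolateral membrane
#'
#' \eqn{V_m = i_{MET} / (G_{tot} + j\omega C_{tot})}.  The lumping folds
#' the resting stereocilia conductance into the membrane node:
#' \eqn{G_{tot} = G_m + G_{s,max} p_0}, \eqn{C_{tot} = C_m + C_s}.  Above
#' the corner frequency \eqn{G_{tot}/(2\pi C_{tot})} the receptor
#' potential lags the transduction current by approaching a quarter
#' cycle.
#'
#' @param G_tot,C_tot lumped conductance (S) and capacitance (F).
#' @param omega angular frequency (rad/s), non-negative.
#' @param i_met complex transduction current (A).
#' @return complex membrane potential (V).
#' @export
membrane_response <- function(G_tot, C_tot, omega, i_met) {
  if (any(omega < 0)) stop("omega must be non-negative")
  i_met / (G_tot + 1i * omega * C_tot)
}

#' RC corner frequency
#' @param G conductance (S).
#' @param C capacitance (F).
#' @return corner frequency (Hz).
#' @export
rc_corner <- function(G, C) G / (2 * pi * C)

# Per-section electrical coefficients in SI units. The circuit is per
# cell; merged-element (3 rows) force gains carry the factor 3.
electrical_coefficients <- function(params, spec) {
  nS <- 1e-9; pF <- 1e-12; mV <- 1e-3
  ncell <- 3 * spec$dx_um / 10   # merged OHC rows per section
  sens <- met_sensitivity(params$G_s_max * nS, params$E_e * mV,
                          params$v_m0 * mV, params$p_open0,
                          spec$gating_swing, spec$k_gs, spec$kBT)
  data.frame(
    sec = seq_len(nrow(params)),
    ncell = ncell,
    S_I = sens$dI_dX,                       # A per m of bundle shear, per cell
    dp_dX = sens$dp_dX,                     # 1/m
    G_tot = params$G_m * nS + params$G_s_max * nS * params$p_open0,
    C_tot = params$C_m * pF + params$C_s * pF,
    g_eff = ncell * params$g_ohc * 1e-6,    # N/V, merged rows
    g_cell = params$g_ohc * 1e-6,           # N/V, single cell
    f_met_eff = ncell * params$f_met_max * 1e-12,
    f_met_cell = params$f_met_max * 1e-12
  )
}

#' Active OHC forces from the electrical state
#'
#' The somatic force is proportional to the membrane potential change,
#' \eqn{f_{OHC} = g_{OHC} V_m} (contraction-positive: depolarization
#' shortens the cell), applied as a self-equilibrated axial pair at the
#' OHC ends.  The hair-bundle reactive force is
#' \eqn{f_{MET} = f_{MET,max}\, \Delta p_{open}} applied as a
#' self-equilibrated pair on the bundle shear DOFs, pulling the bundle in
#' the excitatory direction.
#'
#' @param V_m complex membrane potential (V).
#' @param dp_open complex open-probability change.
#' @param g_ohc somatic gain (N/V).
#' @param f_met_max maximal bundle force (N).
#' @param g_ohc_scale,g_met_scale gain scales.
#' @return list of complex \code{f_ohc} and \code{f_met} (N).
#' @export
active_forces <- function(V_m, dp_open, g_ohc, f_met_max,
                          g_ohc_scale = 1, g_met_scale = 1) {
  list(f_ohc = g_ohc_scale * g_ohc * V_m,
       f_met = g_met_scale * f_met_max * dp_open)
}
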