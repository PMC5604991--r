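# Tuning-curve analyses: best frequency, amplification, Q10dB, OCC
# transfer functions and parameter-sensitivity experiments.

#' Tuning quality Q10dB of a gain curve
#'
#' Best frequency divided by the bandwidth 10 dB below the peak, with
#' linear interpolation between frequency grid points.  Returns NA (with
#' attribute \code{flag}) when a -10 dB point lies outside the sweep.
#'
#' @param freq_hz frequencies (Hz), ascending.
#' @param gain_db gains (dB).
#' @return Q10dB (dimensionless) or NA.
#' @export
q10db <- function(freq_hz, gain_db) {
  o <- order(freq_hz)
  f <- freq_hz[o]; g <- gain_db[o]
  ip <- which.max(g)
  thr <- g[ip] - 10
  cross <- function(idx) {
    # linear interpolation of the threshold crossing between idx, idx+1
    f[idx] + (thr - g[idx]) * (f[idx + 1] - f[idx]) / (g[idx + 1] - g[idx])
  }
  lo <- NA_real_
  if (ip > 1) {
    below <- which(g[1:(ip - 1)] < thr)
    if (length(below)) lo <- cross(max(below))
  }
  hi <- NA_real_
  if (ip < length(g)) {
    below <- which(g[(ip + 1):length(g)] < thr) + ip
    if (length(below)) hi <- cross(min(below) - 1)
  }
  if (is.na(lo) || is.na(hi)) {
    out <- NA_real_
    attr(out, "flag") <- "-10 dB point outside sweep range"
    return(out)
  }
  f[ip] / (hi - lo)
}

#' Amplification and tuning report
#'
#' For each requested location, extracts the active and passive gain
#' curves versus frequency, their peak gains and best frequencies, the
#' amplification (active minus passive peak gain, dB) and Q10dB.
#'
#' @param active_sweep,passive_sweep \code{cochlea_sweep} objects over the
#'   same model.
#' @param model the model the sweeps were run on.
#' @param x_mm locations (mm).
#' @return data frame of class \code{amplification_report}.
#' @export
amplification_and_q <- function(active_sweep, passive_sweep, model, x_mm) {
  rows <- lapply(x_mm, function(x) {
    sec <- section_at(model, x)
    ga <- sweep_gain(active_sweep, sec)
    gp <- sweep_gain(passive_sweep, sec)
    ia <- which.max(ga$gain_db); ip <- which.max(gp$gain_db)
    data.frame(
      x_mm = x,
      best_freq_active = ga$freq_hz[ia],
      best_freq_passive = gp$freq_hz[ip],
      peak_gain_active = ga$gain_db[ia],
      peak_gain_passive = gp$gain_db[ip],
      amplification_db = ga$gain_db[ia] - gp$gain_db[ip],
      q10_active = as.numeric(q10db(ga$freq_hz, ga$gain_db)),
      q10_passive = as.numeric(q10db(gp$freq_hz, gp$gain_db)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("amplification_report", class(out))
  out
}

#' Default logarithmic frequency grid
#' @param f_lo,f_hi range (Hz).
#' @param per_octave points per octave.
#' @return frequency vector (Hz).
#' @export
freq_grid <- function(f_lo, f_hi, per_octave = 15) {
  n <- max(2, ceiling(log2(f_hi / f_lo) * per_octave) + 1)
  exp(seq(log(f_lo), log(f_hi), length.out = n))
}

#' OCC transfer functions relative to the BM displacement
#'
#' At each location, the solution at that location's best frequency (the
#' sweep frequency maximizing the local BM displacement) provides the
#' complex ratios of hair-bundle shear, TM radial and transverse
#' displacement, receptor potential, transduction current and OHC length
#' change to the BM displacement, plus the phase of v_OHC with respect to
#' f_OHC.  Points with BM displacement below \code{floor_m} are masked.
#'
#' @param sweep a \code{cochlea_sweep} (typically active).
#' @param model the model.
#' @param x_mm locations (mm).
#' @param floor_m numeric floor on |y_BM| (m).
#' @return data frame: per location, \code{gain_*} (magnitude ratios;
#'   V_m in mV/nm, i_MET in nA/nm) and \code{ph_*} (degrees, wrapped to
#'   (-180, 180]).
#' @export
transfer_functions <- function(sweep, model, x_mm, floor_m = 1e-16) {
  wrap <- function(deg) {
    d <- ((deg + 180) %% 360) - 180
    d[d == -180] <- 180
    d
  }
  rows <- lapply(x_mm, function(x) {
    sec <- section_at(model, x)
    mags <- vapply(sweep$solutions, function(s)
      if (is.null(s)) -Inf else abs(s$sections$y_bm[sec]), numeric(1))
    s <- sweep$solutions[[which.max(mags)]]
    r <- s$sections[sec, ]
    if (abs(r$y_bm) < floor_m)
      return(NULL)
    rel <- function(z) z / r$y_bm
    data.frame(
      x_mm = x, best_freq = s$freq_hz,
      gain_dhb = abs(rel(r$d_hb)), ph_dhb = wrap(Arg(rel(r$d_hb)) * 180 / pi),
      gain_ztm = abs(rel(r$z_tm)), ph_ztm = wrap(Arg(rel(r$z_tm)) * 180 / pi),
      gain_ytm = abs(rel(r$y_tm)), ph_ytm = wrap(Arg(rel(r$y_tm)) * 180 / pi),
      gain_vm = abs(rel(r$V_m)) * 1e-6,                      # mV per nm
      ph_vm = wrap(Arg(rel(r$V_m)) * 180 / pi),
      gain_imet = abs(rel(r$i_met)) * 1e9 * 1e-9,            # nA per nm
      ph_imet = wrap(Arg(rel(r$i_met)) * 180 / pi),
      gain_dohc = abs(rel(r$d_ohc)),
      ph_dohc = wrap(Arg(rel(r$d_ohc)) * 180 / pi),
      ph_v_re_f = if (abs(r$f_ohc) > 0)
        wrap((Arg(r$v_ohc) - Arg(r$f_ohc)) * 180 / pi) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Amplification at a fixed stimulating frequency
#'
#' Amplification factor from one active and one passive solve at the same
#' frequency: difference (dB) of the spatial peak BM displacement
#' magnitudes, the convention used by the parameter-sensitivity analysis
#' (the peak section of a 4 kHz tone lies near x = 6 mm).
#'
#' @param sol_active,sol_passive solutions at the same frequency.
#' @return amplification (dB).
#' @export
amplification_at_freq <- function(sol_active, sol_passive) {
  20 * log10(max(abs(sol_active$sections$y_bm)) /
             max(abs(sol_passive$sections$y_bm)))
}

#' Parameter sensitivity of the amplification
#'
#' Re-solves the model at one frequency with a single parameter scaled by
#' each factor (all other parameters standard) and reports the
#' amplification factor near the peak location.
#'
#' @param spec a [model_spec()] (standard configuration).
#' @param param scalable parameter id: one of \code{"k_ohc"},
#'   \code{"k_ohb"}, \code{"k_bm"}, \code{"k_tm"}, \code{"k_other"},
#'   \code{"damping"}, \code{"g_ohc"}, \code{"g_met"}.
#' @param factors numeric scale factors (e.g. \code{2^(-3:3)}).
#' @param freq_hz probe frequency (Hz); 4 kHz peaks near x = 6 mm.
#' @return data frame with \code{factor} and \code{amplification_db}.
#' @export
sensitivity_sweep <- function(spec, param, factors, freq_hz = 4000) {
  gains_only <- param %in% c("g_ohc", "g_met")
  if (!gains_only && !param %in% c(names(scale_groups()), "damping"))
    stop("unknown parameter id: ", param)
  base_model <- if (gains_only) build_model(spec) else NULL
  base_passive <- if (gains_only)
    solve_harmonic(base_model, freq_hz, active = FALSE) else NULL
  rows <- lapply(factors, function(f) {
    if (gains_only) {
      m <- base_model
      sa <- solve_harmonic(m, freq_hz, active = TRUE,
        g_ohc_scale = if (param == "g_ohc") f * spec$g_ohc_scale
                      else spec$g_ohc_scale,
        g_met_scale = if (param == "g_met") f * spec$g_met_scale
                      else spec$g_met_scale)
      sp <- base_passive
    } else {
      sc <- spec$scales
      sc[param] <- f * (if (param %in% names(sc)) sc[[param]] else 1)
      sp2 <- spec; sp2$scales <- sc
      m <- build_model(sp2)
      sa <- solve_harmonic(m, freq_hz, active = TRUE)
      sp <- solve_harmonic(m, freq_hz, active = FALSE)
    }
    data.frame(factor = f, amplification_db = amplification_at_freq(sa, sp),
               peak_x_mm = peak_location(sa))
  })
  do.call(rbind, rows)
}
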