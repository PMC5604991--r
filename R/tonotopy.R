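#' Standard tonotopic parameter anchors for the gerbil cochlea
#'
#' Geometric, elastic and electrical properties of the organ of Corti complex
#' (OCC) and outer hair cells (OHC) are anchored at two longitudinal
#' positions, x = 2 mm (base) and x = 10 mm (apex), and interpolated
#' in between.  Values are stored in the customary units of the cochlear
#' mechanics literature (micrometres, MPa, mN/m, nS, pF, mV, pN).
#'
#' @return A data frame with one row per parameter and columns
#'   \code{param}, \code{base} (value at x = 2 mm), \code{apex} (value at
#'   x = 10 mm), \code{law} (interpolation law, \code{"loglin"} or
#'   \code{"linear"}) and \code{unit}.
#' @export
standard_anchors <- function() {
  a <- function(param, base, apex, unit, law = "loglin")
    data.frame(param = param, base = base, apex = apex, law = law,
               unit = unit, stringsAsFactors = FALSE)
  rbind(
    a("bm_width_a",     53,   93,  "um"),
    a("bm_width_p",    107,  187,  "um"),
    a("bm_thick_a",    0.6, 0.14,  "um"),
    a("bm_thick_p",      3,  0.7,  "um"),
    a("bm_E_rad",     1000, 1000, "MPa"),
    a("bm_E_long",     0.4,  0.1, "MPa"),
    a("ohc_diam",        9,    9,  "um"),
    a("ohc_len",        20,   50,  "um"),
    a("ohc_E",       0.045, 0.045, "MPa"),
    a("hb_height",       2,    6,  "um"),
    a("hb_width",        8,    8,  "um"),
    a("k_ohb",          40,  4.5, "mN/m"),
    a("pc_diam",         8,    4,  "um"),
    a("pc_E",           10,   10, "MPa"),
    a("dc_body_diam",   10,   10,  "um"),
    a("dc_phal_diam",  1.5,    1,  "um"),
    a("dc_body_E",     0.5,  0.5, "MPa"),
    a("dc_phal_E",       3,    3, "MPa"),
    a("rl_thick_pc",     5,    5,  "um"),
    a("rl_thick_ohc",    2,    1,  "um"),
    a("rl_E_rad",       10,    2, "MPa"),
    a("rl_E_long",     0.2, 0.05, "MPa"),
    a("tm_width_body",  53,  140,  "um"),
    a("tm_width_root",  27,   70,  "um"),
    a("tm_thick_body",  30,   50,  "um"),
    a("tm_thick_root",  20,   25,  "um"),
    a("tm_E_rad_body", 0.2, 0.01, "MPa"),
    a("tm_E_rad_root", 0.8, 0.04, "MPa"),
    a("tm_E_long",   0.002, 0.002, "MPa"),
    a("E_e",            90,   90,  "mV"),
    a("G_s_max",        90,   27,  "nS"),
    a("C_s",           2.6,    9,  "pF"),
    a("p_open0",       0.4,  0.4,  ""),
    a("f_met_max",     100,   12,  "pN"),
    a("E_K",            75,   75,  "mV"),
    a("v_m0",          -53,  -37,  "mV"),
    a("G_m",           230,   39,  "nS"),
    a("C_m",           4.3,   15,  "pF"),
    a("g_ohc",         0.1,  0.1, "nN/mV"),
    a("c_ohc",         0.3, 0.75, "uN.s/m"),
    a("pillar_len",     50,   80,  "um"),
    a("theta_deg",     1.5,   -3.5, "deg", law = "linear")
  )
}

# anchor positions of the parameter table (mm)
X_BASE <- 2
X_APEX <- 10

#' Interpolate tonotopic parameters at a longitudinal position
#'
#' Parameters are anchored at x = 2 and 10 mm and follow, by default, a
#' log-linear (exponential-in-x) law between and beyond the anchors,
#' consistent with the exponential frequency-position map of the cochlea.
#' Sign-changing parameters (the TM attachment angle) interpolate linearly.
#'
#' @param x numeric vector of longitudinal positions (mm), within
#'   \code{[0, L]}.
#' @param table anchor table as returned by [standard_anchors()].
#' @param rule default interpolation law for parameters whose \code{law}
#'   column is \code{"loglin"}; one of \code{"loglin"} or \code{"linear"}.
#' @param L model length (mm), used only for the domain check.
#' @return data frame with one row per element of \code{x}; first column
#'   \code{x_mm}, remaining columns one per parameter.
#' @export
interpolate_params <- function(x, table = standard_anchors(),
                               rule = c("loglin", "linear"), L = 12) {
  rule <- match.arg(rule)
  if (any(!is.finite(x)) || any(x < 0) || any(x > L))
    stop("x must lie within [0, ", L, "] mm")
  t <- (x - X_BASE) / (X_APEX - X_BASE)
  out <- list(x_mm = x)
  for (k in seq_len(nrow(table))) {
    p <- table[k, ]
    law <- if (p$law == "linear") "linear" else rule
    if (law == "loglin" && sign(p$base) == sign(p$apex) && p$base != 0) {
      s <- sign(p$base)
      v <- s * exp(log(abs(p$base)) * (1 - t) + log(abs(p$apex)) * t)
    } else {
      v <- p$base * (1 - t) + p$apex * t
    }
    out[[p$param]] <- v
  }
  as.data.frame(out)
}

#' Stiffness-proportional Rayleigh damping coefficient
#'
#' The viscous damping matrix of the OCC is the element stiffness matrix
#' scaled by a position-dependent coefficient
#' \eqn{\alpha_C(x) = 0.963\,e^{0.413 x}} microseconds (x in mm), chosen so
#' that the passive cochlea is slightly under-damped.
#'
#' @param x longitudinal position (mm), non-negative.
#' @return Rayleigh coefficient in microseconds.
#' @export
damping_coefficient <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) stop("x must be non-negative (mm)")
  0.963 * exp(0.413 * x)
}

#' Viscous damping of the subtectorial space
#'
#' Couette-flow approximation of the shear drag in the gap between the
#' reticular lamina and the tectorial membrane:
#' \eqn{c_{STS} = \mu L w / h}.
#'
#' @param mu dynamic viscosity (Pa s); endolymph default 0.7 mPa s.
#' @param L,w,h length, width and height of the gap (m).
#' @return damping coefficient (N s/m).
#' @export
subtectorial_damping <- function(mu, L, w, h) {
  if (any(c(mu, L, w, h) < 0)) stop("arguments must be non-negative")
  if (any(h == 0)) stop("gap height h must be positive")
  mu * L * w / h
}

# Apply named multiplicative scale factors to a parameter table.
# Recognised group names expand to parameter columns; any name matching a
# column scales that column directly.
scale_groups <- function() {
  list(
    k_ohc  = "ohc_E",
    k_ohb  = "k_ohb",
    k_bm   = c("bm_E_rad", "bm_E_long"),
    k_tm   = c("tm_E_rad_body", "tm_E_rad_root", "tm_E_long"),
    k_other = c("pc_E", "dc_body_E", "dc_phal_E", "rl_E_rad", "rl_E_long"),
    g_ohc  = "g_ohc",
    g_met  = "f_met_max"
  )
}

apply_scales <- function(params, scales) {
  if (is.null(scales) || length(scales) == 0) return(params)
  if (is.null(names(scales)) || any(names(scales) == ""))
    stop("scales must be a named numeric vector")
  groups <- scale_groups()
  for (nm in names(scales)) {
    if (nm == "damping") next  # handled at assembly time
    cols <- if (nm %in% names(groups)) groups[[nm]]
            else if (nm %in% names(params)) nm
            else stop("unknown scalable parameter: ", nm)
    for (cl in cols) params[[cl]] <- params[[cl]] * scales[[nm]]
  }
  params
}
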