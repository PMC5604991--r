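#' Model configuration
#'
#' A \code{model_spec} collects every knob of the coupled cochlear model:
#' geometry of the fluid box, discretization, stimulus, active-feedback
#' scales and per-parameter scale factors.  Defaults reproduce the
#' standard full-scale gerbil model (12 mm, 10 um section pitch, 0.3 mm
#' chamber height, 1 nm/ms stapes velocity).
#'
#' @param L_mm model length (mm).
#' @param dx_um longitudinal section pitch (um); \code{L_mm/dx_um} must be
#'   an integer.
#' @param H_mm height of each fluid compartment (mm).
#' @param pitch_um fluid grid pitch (um); defaults to \code{dx_um} and must
#'   divide \code{H_mm}.
#' @param rho fluid density (kg/m^3); water.
#' @param rho_tissue tissue density for structural mass (kg/m^3).
#' @param v_stapes stapes velocity amplitude (m/s); 1 nm/ms.
#' @param active logical, include OHC force feedback.
#' @param g_ohc_scale,g_met_scale multiplicative scales on the somatic and
#'   hair-bundle active force gains.
#' @param scales named numeric vector of parameter scale factors (see
#'   [standard_anchors()] for names; groups \code{k_ohc}, \code{k_ohb},
#'   \code{k_bm}, \code{k_tm}, \code{k_other}, \code{g_ohc}, \code{g_met},
#'   \code{damping}).
#' @param s_bm shape factor on the radial bending rigidity of the basilar
#'   membrane, standing in for the fibrous-composite plate behaviour that a
#'   homogeneous thin beam underestimates; calibrated once against the
#'   model's tonotopic map (see the methods vignette).
#' @param s_tm shape factor on the radial bending rigidity of the
#'   tectorial membrane (radially fibrous composite), calibrated with
#'   \code{s_bm} against the tonotopic map.
#' @param scala_width_factor ratio of scala width to BM width, used for the
#'   2-D fluid coupling strength and the power-flux width w(x).
#' @param hb_axial_factor stiffness of the stereocilia axial strut
#'   (transverse link between reticular lamina and TM underside) relative
#'   to the bundle pivot-shear stiffness.
#' @param met_sign orientation (+1/-1) of the excitatory hair-bundle shear
#'   direction relative to the +z (radial) axis.
#' @param ohc_tilt longitudinal tilt of the OHC in sections; the default
#'   -1 places the cell's Deiters insertion one section apical of its
#'   reticular-lamina apex, the anatomical orientation (0 = in-plane).
#' @param mu_sts dynamic viscosity of the subtectorial fluid (Pa s).
#' @param h_sts height of the subtectorial gap for the shear-film damper
#'   (m).
#' @param kBT thermal energy used in the gating-channel linearization (J).
#' @param gating_swing MET gating swing (m).
#' @param k_gs gating spring stiffness (N/m).
#' @param seed integer seed for optional fixture jitter (the standard
#'   generator is fully deterministic; the seed only feeds robustness
#'   perturbations).
#' @return object of class \code{model_spec}.
#' @export
model_spec <- function(L_mm = 12, dx_um = 10, H_mm = 0.3, pitch_um = dx_um,
                       rho = 1000, rho_tissue = 1000,
                       v_stapes = 1e-6, active = TRUE,
                       g_ohc_scale = 1, g_met_scale = 1,
                       scales = c(), s_bm = 4, s_tm = 8, scala_width_factor = 2,
                       hb_axial_factor = 100, ohc_tilt = -1L,
                       met_sign = 1, mu_sts = 0.7e-3, h_sts = 1e-6,
                       kBT = 4.28e-21, gating_swing = 0.7e-9, k_gs = 6e-3,
                       seed = 1L) {
  nsec <- L_mm * 1000 / dx_um
  if (abs(nsec - round(nsec)) > 1e-9)
    stop("L_mm/dx_um must be an integer number of sections")
  nzf <- H_mm * 1000 / pitch_um
  if (abs(nzf - round(nzf)) > 1e-9)
    stop("fluid pitch must divide the chamber height H")
  if (!met_sign %in% c(-1, 1)) stop("met_sign must be +1 or -1")
  spec <- list(L_mm = L_mm, dx_um = dx_um, H_mm = H_mm, pitch_um = pitch_um,
               rho = rho, rho_tissue = rho_tissue, v_stapes = v_stapes,
               hb_axial_factor = hb_axial_factor, ohc_tilt = as.integer(ohc_tilt),
               active = active, g_ohc_scale = g_ohc_scale,
               g_met_scale = g_met_scale, scales = scales, s_bm = s_bm,
               s_tm = s_tm,
               scala_width_factor = scala_width_factor, met_sign = met_sign,
               mu_sts = mu_sts, h_sts = h_sts, kBT = kBT, gating_swing = gating_swing,
               k_gs = k_gs, seed = as.integer(seed),
               n_sections = as.integer(round(nsec)) + 1L,
               nz = as.integer(round(nzf)))
  class(spec) <- "model_spec"
  spec
}

#' Preset model configurations
#'
#' \code{"full"} is the standard 12-mm model with 10-um pitch (1201
#' sections, as in the full-scale simulations).  \code{"coarse"} keeps the
#' full 12-mm length at 30-um pitch (401 sections) for frequency sweeps.
#' \code{"tiny"} is a 1.2-mm, 50-um-pitch fixture (25 sections) that
#' assembles and solves in well under ten seconds, for tests.
#'
#' @param name preset name.
#' @param ... overrides passed on to [model_spec()].
#' @return a \code{model_spec}.
#' @export
preset_spec <- function(name = c("full", "coarse", "tiny"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    full   = list(L_mm = 12, dx_um = 10),
    coarse = list(L_mm = 12, dx_um = 30),
    tiny   = list(L_mm = 1.2, dx_um = 50))
  do.call(model_spec, utils::modifyList(args, list(...)))
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> L =", x$L_mm, "mm, dx =", x$dx_um, "um (",
      x$n_sections, "sections ), H =", x$H_mm, "mm, nz =", x$nz,
      ",", if (x$active) "active" else "passive", "\n")
  invisible(x)
}

#' Section parameter table for a model
#'
#' Interpolates the anchored tonotopic parameters at every section of a
#' model and applies the configured scale factors.  One row per section.
#'
#' @param spec a [model_spec()].
#' @param table anchor table, by default [standard_anchors()].
#' @return data frame of section parameters (one row per section).
#' @export
section_param_table <- function(spec, table = standard_anchors()) {
  x <- seq(0, spec$L_mm, length.out = spec$n_sections)
  params <- interpolate_params(x, table = table, L = spec$L_mm)
  params <- apply_scales(params, spec$scales)
  params$alpha_us <- damping_coefficient(x)
  params
}

#' Build a complete model bundle
#'
#' Generates the section parameter table, the 3-D beam mesh of the organ
#' of Corti complex, the assembled stiffness/mass/damping matrices, the
#' fluid-grid layout and the per-section electrical coefficients.  The
#' result is deterministic for a given spec (and seed).
#'
#' @param spec a [model_spec()].
#' @param params optional pre-computed/modified section parameter table
#'   (as from [section_param_table()]); used by the stiffness-ratio
#'   adjustment experiments.
#' @return object of class \code{cochlea_model}.
#' @export
build_model <- function(spec, params = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(params)) params <- section_param_table(spec)
  if (nrow(params) != spec$n_sections)
    stop("params must have one row per section")
  mesh <- build_occ_mesh(params, spec)
  mats <- assemble_matrices(mesh, params, spec)
  model <- list(spec = spec, params = params, mesh = mesh, mats = mats,
                elec = electrical_coefficients(params, spec),
                fluid = fluid_layout(spec),
                w_stapes = NULL)
  class(model) <- "cochlea_model"
  model
}

#' @export
print.cochlea_model <- function(x, ...) {
  cat("<cochlea_model>", x$spec$n_sections, "sections,",
      nrow(x$mesh$nodes), "nodes,", x$mats$nfree, "free structural DOFs,",
      2 * x$spec$n_sections * (x$spec$nz + 1), "fluid DOFs\n")
  invisible(x)
}

# x (mm) of each section
section_x <- function(model) model$params$x_mm

# nearest section index to x (mm)
section_at <- function(model, x_mm) {
  which.min(abs(section_x(model) - x_mm))
}
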