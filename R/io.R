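# Run orchestration: YAML configs, manifests, deterministic CSV/JSON
# serialization of results.

#' Export the section parameter table as CSV
#' @param model a [build_model()] bundle.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_params_csv <- function(model, path) {
  utils::write.csv(model$params, path, row.names = FALSE)
  invisible(path)
}

#' Export the mesh as node/element CSV pair
#' @param model a [build_model()] bundle.
#' @param prefix path prefix; writes \code{<prefix>_nodes.csv} and
#'   \code{<prefix>_elements.csv}.
#' @return the two paths, invisibly.
#' @export
write_mesh_csv <- function(model, prefix) {
  nodes <- data.frame(id = seq_len(nrow(model$mesh$nodes)),
                      sec = model$mesh$node_sec, model$mesh$nodes)
  pn <- paste0(prefix, "_nodes.csv")
  pe <- paste0(prefix, "_elements.csv")
  utils::write.csv(nodes, pn, row.names = FALSE)
  utils::write.csv(model$mesh$beams, pe, row.names = FALSE)
  invisible(c(pn, pe))
}

# per-section summary of one solution, in reporting units
solution_summary <- function(sol) {
  s <- sol$sections
  data.frame(
    x_mm = s$x_mm,
    y_bm_nm = abs(s$y_bm) * 1e9, phase_bm_deg = Arg(s$y_bm) * 180 / pi,
    y_tm_nm = abs(s$y_tm) * 1e9, z_tm_nm = abs(s$z_tm) * 1e9,
    d_hb_nm = abs(s$d_hb) * 1e9,
    V_m_mV = abs(s$V_m) * 1e3, i_met_nA = abs(s$i_met) * 1e9,
    f_ohc_pN = abs(s$f_ohc) * 1e12, v_ohc_um_s = abs(s$v_ohc) * 1e6)
}

run_manifest <- function(config) {
  list(package = "cortimech",
       version = as.character(utils::packageVersion("cortimech")),
       config = config,
       config_hash = digest_config(config))
}

# small deterministic config hash (no external digest dependency)
digest_config <- function(config) {
  s <- paste(deparse(config), collapse = "")
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 1e9
}

#' Run an experiment from a configuration file
#'
#' The YAML (or JSON) configuration names an experiment and its
#' parameters and the run writes a manifest plus CSV/JSON results to
#' \code{out_dir}.  Supported experiments: \code{solve} (one frequency,
#' active and/or passive), \code{sweep} (gain curves at locations),
#' \code{probe} (static stiffness probes), \code{sensitivity}.
#' Identical configurations produce identical outputs.
#'
#' @param config path to a YAML config, or an equivalent named list.
#' @param out_dir output directory (created if needed).
#' @return list of written paths, invisibly.
#' @export
run_experiment <- function(config, out_dir = ".") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- function(nm, default = NULL) {
    if (!is.null(config[[nm]])) config[[nm]]
    else if (!is.null(default)) default
    else stop("config field missing: ", nm)
  }
  exp_name <- need("experiment")
  if (!exp_name %in% c("solve", "sweep", "probe", "sensitivity"))
    stop("unknown experiment: ", exp_name)
  preset <- need("preset", "tiny")
  overrides <- config$spec %||% list()
  spec <- do.call(preset_spec, c(list(name = preset), overrides))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  model <- build_model(spec)
  if (exp_name == "solve") {
    f <- need("freq_khz") * 1000
    sol <- solve_harmonic(model, f, active = need("active", spec$active))
    put(solution_summary(sol), sprintf("solve_%gkHz", f / 1000))
    rep <- power_report(model, sol)
    jp <- file.path(out_dir, "power.json")
    jsonlite::write_json(list(P_stapes = rep$P_stapes, P_f2s = rep$P_f2s,
                              P_loss = rep$P_loss_total,
                              P_ohc_total = rep$P_ohc_total,
                              Z_input = rep$Z_input),
                         jp, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, jp)
  } else if (exp_name == "sweep") {
    f <- freq_grid(need("f_lo_khz") * 1000, need("f_hi_khz") * 1000,
                   need("per_octave", 15))
    sa <- frequency_sweep(model, f, active = TRUE)
    sp <- frequency_sweep(model, f, active = FALSE)
    rep <- amplification_and_q(sa, sp, model, unlist(need("x_mm")))
    put(rep, "amplification")
  } else if (exp_name == "probe") {
    put(probe_stiffness(model, unlist(need("x_mm"))), "probes")
  } else if (exp_name == "sensitivity") {
    put(sensitivity_sweep(spec, need("param"),
                          unlist(need("factors")),
                          need("freq_khz", 4) * 1000), "sensitivity")
  }
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(run_manifest(config), mp, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(paths, mp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
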