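#' Build the 3-D beam mesh of the organ of Corti complex
#'
#' Every 10-um (by default) section carries a minimal cross-section
#' topology: a two-zone basilar membrane (arcuate/pectinate) hinged at the
#' spiral lamina and clamped at the spiral ligament, a pillar-cell truss,
#' the merged outer-hair-cell axial element standing on a Deiters-cell
#' body, the reticular lamina, and a two-zone tectorial membrane (root +
#' body) clamped at the spiral limbus and attached at the configured
#' angle.  Adjacent sections are tied by longitudinal beams for the BM,
#' RL and TM and by the Deiters phalangeal process, which spans one
#' section apically (longitudinal feed-forward).  The hair bundle is a
#' radial shear spring (with subtectorial damper) linking the reticular
#' lamina to the TM underside.
#'
#' Coordinates: x longitudinal (base to apex), y transverse (positive
#' toward scala media), z radial (lamina to ligament).  Units: metres.
#'
#' @param params section parameter table ([section_param_table()]).
#' @param spec a [model_spec()].
#' @return list with \code{nodes}, \code{beams}, \code{fixed} (logical per
#'   raw DOF), \code{reg} (per-section registry of node ids) and
#'   \code{roles}.
#' @export
build_occ_mesh <- function(params, spec) {
  N <- spec$n_sections
  if (nrow(params) != N) stop("missing section parameters")
  um <- 1e-6
  roles <- c("B0", "B1", "B2", "B3", "R1", "R2", "D1", "T0", "T1", "T2")
  nid <- function(sec, role) (sec - 1L) * 10L + match(role, roles)

  p <- params
  x <- p$x_mm * 1e-3
  za <- p$bm_width_a * um; zp <- p$bm_width_p * um
  cpl <- p$pillar_len * um
  z_ohc <- za + 0.2 * zp
  z_d1 <- za + 0.3 * zp
  Lohc <- p$ohc_len * um
  Lv <- sqrt(pmax(Lohc^2 - (0.1 * zp)^2, (0.3 * Lohc)^2))
  yD1 <- cpl - Lv
  th <- p$theta_deg * pi / 180
  yT2 <- cpl + p$hb_height * um
  wb <- p$tm_width_body * um; wr <- p$tm_width_root * um

  crd <- function(y, z) cbind(x, y, z)
  coords <- list(
    B0 = crd(0, 0),
    B1 = crd(0, za),
    B2 = crd(0, za + zp / 2),
    B3 = crd(0, za + zp),
    R1 = crd(cpl, za),
    R2 = crd(cpl, z_ohc),
    D1 = crd(yD1, z_d1),
    T0 = crd(yT2 + (wb + wr) * tan(th), z_ohc - wb - wr),
    T1 = crd(yT2 + wb * tan(th), z_ohc - wb),
    T2 = crd(yT2, z_ohc)
  )
  nodes <- matrix(0, N * 10L, 3)
  for (r in seq_along(roles)) nodes[(seq_len(N) - 1L) * 10L + r, ] <- coords[[r]]
  colnames(nodes) <- c("x", "y", "z")
  node_sec <- rep(seq_len(N), each = 10L)

  MPa <- 1e6
  dxm <- spec$dx_um * um
  s <- seq_len(N)
  sL <- seq_len(N - 1L)   # sections with a neighbour toward the apex

  beams <- list()
  add <- function(tag, sec, n1, n2, E, sect) {
    beams[[length(beams) + 1L]] <<- data.frame(
      tag = tag, sec = sec, n1 = n1, n2 = n2, E = E,
      A = sect$A, Iy = sect$Iy, Iz = sect$Iz, J = sect$J)
  }
  # cross-section beams (per section)
  add("BM_arcuate", s, nid(s, "B0"), nid(s, "B1"),
      p$bm_E_rad * MPa * spec$s_bm, rect_section(dxm, p$bm_thick_a * um))
  add("BM_pectinate", s, nid(s, "B1"), nid(s, "B2"),
      p$bm_E_rad * MPa * spec$s_bm, rect_section(dxm, p$bm_thick_p * um))
  add("BM_pectinate", s, nid(s, "B2"), nid(s, "B3"),
      p$bm_E_rad * MPa * spec$s_bm, rect_section(dxm, p$bm_thick_p * um))
  add("pillar", s, nid(s, "B0"), nid(s, "R1"),
      p$pc_E * MPa, circ_section(p$pc_diam * um))
  # outer pillar inclines outward; its head fuses with the reticular
  # lamina at the first OHC row
  add("pillar", s, nid(s, "B1"), nid(s, "R2"),
      p$pc_E * MPa, circ_section(p$pc_diam * um))
  add("RL", s, nid(s, "R1"), nid(s, "R2"),
      p$rl_E_rad * MPa, rect_section(dxm, p$rl_thick_ohc * um))
  # OHCs tilt toward the base: apex on the RL at section s, base on the
  # Deiters cell one section basal (feed-forward geometry)
  dtl <- spec$ohc_tilt
  sD <- pmin(pmax(s - dtl, 1L), N)
  # merged element represents all OHC rows in a section: 3 cells per 10 um
  ohc_sect <- lapply(circ_section(p$ohc_diam * um),
                     function(v) v * spec$dx_um / 10)
  add("OHC", s, nid(s, "R2"), nid(sD, "D1"),
      p$ohc_E * MPa, ohc_sect)
  add("Deiters_body", s, nid(s, "B2"), nid(s, "D1"),
      p$dc_body_E * MPa, circ_section(p$dc_body_diam * um))
  add("TM_body", s, nid(s, "T1"), nid(s, "T2"),
      p$tm_E_rad_body * MPa * spec$s_tm, rect_section(dxm, p$tm_thick_body * um))
  add("TM_root", s, nid(s, "T0"), nid(s, "T1"),
      p$tm_E_rad_root * MPa * spec$s_tm, rect_section(dxm, p$tm_thick_root * um))
  # longitudinal beams (section s -> s+1); strip properties at section s
  lng <- function(w, t) rect_section(w, t, longitudinal = TRUE)
  add("BM_long", sL, nid(sL, "B1"), nid(sL + 1L, "B1"),
      p$bm_E_long[sL] * MPa, lng(za[sL], p$bm_thick_a[sL] * um))
  add("BM_long", sL, nid(sL, "B2"), nid(sL + 1L, "B2"),
      p$bm_E_long[sL] * MPa, lng(zp[sL], p$bm_thick_p[sL] * um))
  add("RL_long", sL, nid(sL, "R1"), nid(sL + 1L, "R1"),
      p$rl_E_long[sL] * MPa, lng(za[sL], p$rl_thick_pc[sL] * um))
  add("RL_long", sL, nid(sL, "R2"), nid(sL + 1L, "R2"),
      p$rl_E_long[sL] * MPa, lng(0.2 * zp[sL], p$rl_thick_ohc[sL] * um))
  add("TM_long", sL, nid(sL, "T1"), nid(sL + 1L, "T1"),
      p$tm_E_long[sL] * MPa, lng(wr[sL], p$tm_thick_root[sL] * um))
  add("TM_long", sL, nid(sL, "T2"), nid(sL + 1L, "T2"),
      p$tm_E_long[sL] * MPa, lng(wb[sL], p$tm_thick_body[sL] * um))
  add("Deiters_phalange", sL, nid(sL, "D1"), nid(sL + 1L, "R2"),
      p$dc_phal_E[sL] * MPa, circ_section(p$dc_phal_diam[sL] * um))
  beams <- do.call(rbind, beams)

  # boundary conditions ----------------------------------------------------
  fixed <- rep(FALSE, N * 10L * 6L)
  dofs_of <- function(nids) rep((nids - 1L) * 6L, each = 6L) + 1:6
  # BM hinged along the spiral lamina: translations fixed, rotations free
  fixed[rep((nid(s, "B0") - 1L) * 6L, each = 3L) + 1:3] <- TRUE
  # clamped: spiral ligament (B3) and spiral limbus (T0)
  fixed[dofs_of(nid(s, "B3"))] <- TRUE
  fixed[dofs_of(nid(s, "T0"))] <- TRUE
  # clamped end cross-sections at x = 0 and x = L
  end_nodes <- c(nid(rep(1L, 10L), roles), nid(rep(N, 10L), roles))
  fixed[dofs_of(end_nodes)] <- TRUE

  reg <- data.frame(sec = s)
  for (r in roles) reg[[r]] <- nid(s, r)
  list(nodes = nodes, node_sec = node_sec, beams = beams, fixed = fixed,
       reg = reg, roles = roles)
}
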