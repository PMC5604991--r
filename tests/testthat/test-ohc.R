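test_that("gating force and transduction sensitivity match the printed chain", {
  s <- met_sensitivity(G_s_max = 90e-9, E_e = 90e-3, v_m0 = -53e-3,
                       p_open0 = 0.4)
  expect_equal(s$z_gate, 4.2e-12)                 # 0.7 nm x 6 mN/m
  expect_equal(0.4 * 0.6, 0.24)
  expect_equal(s$dp_dX, 4.2e-12 * 0.24 / 4.28e-21, tolerance = 1e-12)
  expect_equal(s$dp_dX * 1e-9, 0.2355, tolerance = 1e-3)  # per nm
  expect_equal(s$dI_dX, 90e-9 * 0.143 * s$dp_dX, tolerance = 1e-12)
  expect_equal(s$dI_dX, 3.03, tolerance = 0.01)   # A per metre of shear
})

test_that("membrane RC response has the right corner and limits", {
  G <- 39e-9; C <- 15e-12
  expect_equal(rc_corner(G, C), 414, tolerance = 0.01)  # ~0.41 kHz
  i0 <- 1e-9 + 0i
  expect_equal(membrane_response(G, C, 0, i0), i0 / G)
  wc <- G / C
  Vc <- membrane_response(G, C, wc, i0)
  V0 <- membrane_response(G, C, 0, i0)
  expect_equal(abs(Vc), abs(V0) / sqrt(2), tolerance = 1e-12)
  expect_equal(Arg(Vc), -pi / 4, tolerance = 1e-12)
  Vhi <- membrane_response(G, C, 100 * wc, i0)
  expect_lt(Arg(Vhi), -85 * pi / 180)   # approaches a quarter-cycle lag
  expect_error(membrane_response(G, C, -1, i0), "non-negative")
})

test_that("active forces scale with membrane potential and gains", {
  f <- active_forces(V_m = 1e-3 + 0i, dp_open = 0 + 0i, g_ohc = 1e-7,
                     f_met_max = 100e-12)
  expect_equal(f$f_ohc, 0.1e-9 + 0i)   # 0.1 nN per mV per cell
  expect_equal(active_forces(0 + 0i, 0 + 0i, 1e-7, 1e-12)$f_ohc, 0 + 0i)
  f2 <- active_forces(1e-3 + 0i, 0.1 + 0i, 1e-7, 100e-12,
                      g_ohc_scale = 2, g_met_scale = 3)
  expect_equal(f2$f_ohc, 0.2e-9 + 0i)
  expect_equal(f2$f_met, 3 * 100e-12 * 0.1 + 0i)
})

test_that("active force columns are self-equilibrated pairs", {
  m <- tiny_model()
  sys <- assemble_coupled(m, 2 * pi * 2000, active = TRUE)
  sysp <- assemble_coupled(m, 2 * pi * 2000, active = FALSE)
  extra <- length(sys$i) - length(sysp$i)
  expect_gt(extra, 0)
  # the added columns are the force couplings; net somatic force per V_m
  # column must vanish (equal-and-opposite pair along the OHC axis)
  add <- seq(length(sysp$i) - length(sys$i) + 1, 0) # placeholder
  vm_cols <- sys$off_vm + seq_len(m$spec$n_sections)
  som <- sys$j %in% vm_cols & sys$i <= m$mats$nfree
  sums <- tapply(sys$v[som], sys$j[som], sum)
  expect_lt(max(abs(sums)), 1e-20)
})

test_that("passive assembly zeroes only the force-coupling columns", {
  m <- tiny_model()
  omega <- 2 * pi * 2000
  sysa <- assemble_coupled(m, omega, active = TRUE)
  sysp <- assemble_coupled(m, omega, active = FALSE)
  n <- sysa$ntot
  dense <- function(sys) {
    A <- matrix(0 + 0i, n, n)
    for (k in seq_along(sys$i))
      A[sys$i[k], sys$j[k]] <- A[sys$i[k], sys$j[k]] + sys$v[k]
    A
  }
  D <- dense(sysa) - dense(sysp)
  nz <- which(D != 0, arr.ind = TRUE)
  expect_gt(nrow(nz), 0)
  vm_cols <- sysa$off_vm + seq_len(m$spec$n_sections)
  cpd <- m$mats$cp
  shear <- stats::na.omit(c(cpd$T2z, cpd$R2z))
  ok <- (nz[, "col"] %in% vm_cols & nz[, "row"] <= m$mats$nfree) |
        (nz[, "row"] %in% shear & nz[, "col"] %in% shear)
  expect_true(all(ok))
  expect_identical(sysa$b, sysp$b)
})
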