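test_that("anchor positions reproduce the published parameter table", {
  p <- interpolate_params(c(2, 10))
  expect_equal(p$ohc_len, c(20, 50))
  expect_equal(p$k_ohb, c(40, 4.5))
  expect_equal(p$G_m, c(230, 39))
  expect_equal(p$C_m, c(4.3, 15))
  expect_equal(p$bm_width_a, c(53, 93))
  expect_equal(p$bm_thick_p, c(3, 0.7))
  expect_equal(p$v_m0, c(-53, -37))
  expect_equal(p$g_ohc, c(0.1, 0.1))
  expect_equal(p$f_met_max, c(100, 12))
  expect_equal(p$p_open0, c(0.4, 0.4))
})

test_that("log-linear interpolation gives geometric means and monotone profiles", {
  p6 <- interpolate_params(6)
  expect_equal(p6$ohc_len, sqrt(20 * 50), tolerance = 1e-12)
  expect_equal(p6$k_ohb, sqrt(40 * 4.5), tolerance = 1e-12)
  x <- seq(0, 12, by = 0.25)
  prof <- interpolate_params(x)
  expect_true(all(diff(prof$ohc_len) > 0))
  expect_true(all(diff(prof$k_ohb) < 0))
  expect_true(all(diff(prof$G_m) < 0))
  # continuity across the anchors (no kinks beyond the law itself)
  expect_equal(interpolate_params(2 + 1e-9)$ohc_len, 20, tolerance = 1e-6)
  expect_error(interpolate_params(13), "within")
  expect_error(interpolate_params(-0.1), "within")
})

test_that("hair-bundle stiffness base/apex ratio is about nine", {
  p <- interpolate_params(c(2, 10))
  r <- p$k_ohb[1] / p$k_ohb[2]
  expect_equal(r, 8.89, tolerance = 0.01)
  expect_equal(round(r), 9)
})

test_that("Rayleigh coefficient follows the tonotopic exponential law", {
  expect_equal(damping_coefficient(0), 0.963)
  expect_equal(damping_coefficient(2), 0.963 * exp(0.826), tolerance = 1e-12)
  x <- seq(0, 12, by = 0.5)
  expect_true(all(diff(damping_coefficient(x)) > 0))
  expect_gt(damping_coefficient(10), damping_coefficient(2))
  expect_error(damping_coefficient(-1), "non-negative")
})

test_that("scale hooks multiply exactly the targeted parameter", {
  spec0 <- preset_spec("tiny")
  spec2 <- preset_spec("tiny", scales = c(k_ohb = 2))
  p0 <- section_param_table(spec0)
  p2 <- section_param_table(spec2)
  expect_equal(p2$k_ohb, 2 * p0$k_ohb)
  same <- setdiff(names(p0), "k_ohb")
  for (cl in same) expect_equal(p2[[cl]], p0[[cl]])
  expect_error(section_param_table(preset_spec("tiny", scales = c(bogus = 2))),
               "unknown scalable")
})

test_that("extrapolated RC corners bracket the hearing range at the extremes", {
  p <- interpolate_params(c(0, 12))
  nS <- 1e-9; pF <- 1e-12
  G <- p$G_m * nS + p$G_s_max * nS * p$p_open0
  C <- (p$C_m + p$C_s) * pF
  f <- rc_corner(G, C)
  expect_gt(f[1], 15000 / 2)   # basal extreme ~15 kHz within factor 2
  expect_lt(f[1], 15000 * 2)
  expect_gt(f[2], 200 / 2)     # apical extreme ~0.2 kHz within factor 2
  expect_lt(f[2], 200 * 2)
})

test_that("fixture generation is deterministic and respects the grid contract", {
  expect_error(model_spec(L_mm = 1.2, dx_um = 70), "integer number")
  s1 <- preset_spec("tiny")
  expect_equal(s1$n_sections, 25L)
  m1 <- build_model(s1)
  m2 <- build_model(preset_spec("tiny"))
  expect_identical(m1$params, m2$params)
  expect_identical(m1$mesh$nodes, m2$mesh$nodes)
  expect_equal(preset_spec("full")$n_sections, 1201L)
})
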