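test_that("harmonic solutions meet the residual contract", {
  m <- tiny_model()
  sol <- solve_harmonic(m, 4000, active = FALSE)
  expect_lt(sol$relres, 1e-8)
  sola <- solve_harmonic(m, 4000, active = TRUE)
  expect_lt(sola$relres, 1e-8)
  expect_error(solve_harmonic(m, -5), "positive")
})

test_that("the model is exactly linear in the stimulus", {
  m1 <- tiny_model()
  m2 <- build_model(preset_spec("tiny", v_stapes = 2e-6))
  s1 <- solve_harmonic(m1, 3000, active = TRUE)
  s2 <- solve_harmonic(m2, 3000, active = TRUE)
  for (fld in c("y_bm", "y_tm", "d_hb", "V_m", "i_met", "d_ohc", "f_ohc")) {
    a <- s1$sections[[fld]][3:23]
    b <- s2$sections[[fld]][3:23]
    expect_equal(b, 2 * a, tolerance = 1e-9)
  }
  expect_equal(max(abs(s2$p)), 2 * max(abs(s1$p)), tolerance = 1e-9)
})

test_that("OHC state invariants hold exactly", {
  m <- tiny_model()
  s <- solve_harmonic(m, 3000, active = TRUE)$sections
  expect_equal(s$v_ohc, 1i * 2 * pi * 3000 * s$d_ohc)
  g_cell <- m$elec$g_cell
  expect_equal(s$f_ohc, g_cell * s$V_m)
  sp <- solve_harmonic(m, 3000, active = FALSE)$sections
  expect_true(all(sp$f_ohc == 0))           # no active force when passive
  expect_gt(max(abs(sp$V_m)), 0)            # circuit still solved
})

test_that("passive power balance closes: P_stapes = P_f2s = total loss", {
  m <- calibrate_stapes_width(tiny_model(), 4000)
  sol <- solve_harmonic(m, 4000, active = FALSE)
  pf2s <- fluid_to_structure_power(m, sol)
  ploss <- power_loss(m, sol)$total
  pst <- stapes_power(m, sol)
  expect_equal(pf2s / ploss, 1, tolerance = 1e-4)
  expect_equal(pst / pf2s, 1, tolerance = 1e-4)  # by calibration
  # calibrated width is consistent across nearby frequencies
  for (f in c(3000, 6000)) {
    s2 <- solve_harmonic(m, f, active = FALSE)
    expect_equal(stapes_power(m, s2) / fluid_to_structure_power(m, s2), 1,
                 tolerance = 0.15)
  }
  # stapes width is independent of the stimulus amplitude
  m2 <- calibrate_stapes_width(
    build_model(preset_spec("tiny", v_stapes = 3e-6)), 4000)
  expect_equal(m2$w_stapes, m$w_stapes, tolerance = 1e-9)
})

test_that("active power balance: stapes + OHC power equals dissipation", {
  m <- calibrate_stapes_width(tiny_model(), 4000)
  sol <- solve_harmonic(m, 4000, active = TRUE)
  pin <- stapes_power(m, sol) + sum(ohc_power(m, sol)$P_ohc_section) +
    met_power(m, sol)
  ploss <- power_loss(m, sol)$total
  expect_equal(pin / ploss, 1, tolerance = 0.05)
})

test_that("passive peak location decreases monotonically with frequency", {
  m <- tiny_model()
  pk <- sapply(c(16000, 24000, 36000), function(f)
    peak_location(solve_harmonic(m, f, active = FALSE)))
  expect_true(all(diff(pk) < 0))
})

test_that("a one-frequency sweep equals a single solve and failures are contained", {
  m <- tiny_model()
  sw <- frequency_sweep(m, 2500, active = FALSE)
  one <- solve_harmonic(m, 2500, active = FALSE)
  expect_equal(sw$solutions[[1]]$sections$y_bm, one$sections$y_bm)
  expect_error(frequency_sweep(m, numeric(0)), "empty")
})

test_that("sweep gain unwraps phase and reports dB re stapes displacement", {
  m <- tiny_model()
  sw <- frequency_sweep(m, c(1000, 2000, 4000, 8000), active = FALSE)
  g <- sweep_gain(sw, section_at(m, 0.6))
  expect_equal(nrow(g), 4)
  expect_true(all(is.finite(g$gain_db)))
  # phase referenced to stapes displacement accumulates (non-increasing trend)
  expect_lt(g$phase_cyc[4], g$phase_cyc[1] + 0.5)
})
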