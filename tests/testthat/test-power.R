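test_that("dissipated power matches a dense quadratic-form oracle", {
  m <- tiny_model()
  set.seed(11)
  n <- m$mats$nfree
  u <- complex(real = rnorm(n), imaginary = rnorm(n)) * 1e-9
  omega <- 2 * pi * 3000
  sol <- list(u = u, omega = omega)
  pl <- power_loss(m, sol)
  expect_equal(pl$total, dense_loss_oracle(m, u, omega), tolerance = 1e-10)
  expect_equal(sum(pl$per_section$P_loss), pl$total, tolerance = 1e-10)
  expect_gte(pl$total, 0)
  # C = 0 gives zero loss
  m0 <- build_model(preset_spec("tiny", scales = c(damping = 0)))
  expect_equal(power_loss(m0, sol)$total, 0)
})

test_that("OHC power follows the cycle-average formula", {
  m <- tiny_model()
  omega <- 2 * pi * 1000
  mk <- function(f, v) {
    s <- solve_harmonic(m, 1000, active = FALSE)
    s$sections$f_ohc[] <- f
    s$sections$v_ohc[] <- v
    s
  }
  Fa <- 1e-10; Va <- 1e-6
  p_in <- ohc_power(m, mk(Fa + 0i, Va + 0i))
  expect_equal(p_in$P_ohc_cell[5], Fa * Va / 2)
  expect_equal(p_in$P_ohc_section[5], 3 * Fa * Va / 2)  # merged bookkeeping
  p_quad <- ohc_power(m, mk(Fa + 0i, 1i * Va))
  expect_equal(p_quad$P_ohc_cell[5], 0)                 # 90 deg out of phase
  expect_equal(p_quad$phase_deg[5], 90)
})

test_that("power flux vanishes when pressure and velocity are in quadrature", {
  m <- tiny_model()
  sol <- solve_harmonic(m, 2000, active = FALSE)
  # real-valued slow pressure -> purely imaginary velocity -> zero flux
  sol$p <- array(seq_len(prod(dim(sol$p))) + 0i, dim = dim(sol$p))
  pf <- power_flux(m, sol)
  expect_lt(max(abs(pf$P_flux)), 1e-25)
})

test_that("zero stimulus gives zero fields and powers", {
  m0 <- build_model(preset_spec("tiny", v_stapes = 0))
  sol <- solve_harmonic(m0, 2000, active = TRUE)
  expect_lt(max(abs(sol$u)), 1e-30)
  expect_lt(abs(stapes_power(m0, sol, 1)), 1e-40)
  expect_lt(abs(fluid_to_structure_power(m0, sol)), 1e-40)
})

test_that("input impedance reproduces the printed value chain", {
  sol <- list(p = array(0.08 + 0i, dim = c(2, 4, 3)), v_stapes = 1e-6)
  class(sol) <- "cochlea_solution"
  expect_equal(input_impedance(sol), 1e11)          # 100 GPa s/m^3
  expect_equal(input_impedance(sol, 1.6e-6), 5e10)  # doubling area halves
  sol$v_stapes <- 0
  expect_error(input_impedance(sol), "zero")
  expect_equal(db_re_fw(1e-15), 0)
  expect_equal(db_re_fw(1e-12), 30)
})
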