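test_that("slow pressure subtracts the helicotrema value exactly", {
  set.seed(3)
  p <- array(complex(real = rnorm(2 * 11 * 5), imaginary = rnorm(110)),
             dim = c(2, 11, 5))
  ps <- slow_pressure(p)
  expect_equal(ps[1, 11, 1], 0 + 0i)
  # independent elementwise oracle
  expect_equal(ps, p - p[1, 11, 1])
  pc <- array(4 + 2i, dim = c(2, 11, 5))
  expect_true(all(slow_pressure(pc) == 0))
})

test_that("fluid velocity implements the pressure-gradient relation", {
  h <- 1e-5; rho <- 1000; omega <- 2 * pi * 1000
  nx <- 21
  x <- (0:(nx - 1)) * h
  g <- 3.7
  ps <- array(0 + 0i, dim = c(2, nx, 3))
  for (k in 1:3) for (cc in 1:2) ps[cc, , k] <- g * x
  vf <- fluid_velocity(ps, rho, omega, h)
  expected <- -g / (1i * omega * rho)
  expect_equal(vf[1, 10, 2], expected, tolerance = 1e-12)
  expect_equal(Arg(vf[1, 10, 2]), pi / 2, tolerance = 1e-12)  # +90 degrees
  expect_equal(abs(vf[1, 10, 2]), g / (omega * rho), tolerance = 1e-12)
  # uniform field has zero velocity; doubling rho halves the magnitude
  expect_true(all(fluid_velocity(ps * 0 + 5, rho, omega, h) == 0))
  expect_equal(abs(fluid_velocity(ps, 2 * rho, omega, h)[1, 10, 2]),
               abs(vf[1, 10, 2]) / 2)
  expect_error(fluid_velocity(ps, rho, 0, h), "positive")
})

test_that("solved pressure satisfies the interior Laplace equation", {
  m <- tiny_model()
  sol <- solve_harmonic(m, 4000, active = FALSE)
  p <- sol$p
  nx <- dim(p)[2]; K1 <- dim(p)[3]
  # independent 5-point stencil check on interior cells
  res <- 0
  scale <- max(abs(p))
  for (cc in 1:2) for (i in 3:(nx - 2)) for (k in 2:(K1 - 1)) {
    r <- p[cc, i - 1, k] + p[cc, i + 1, k] + p[cc, i, k - 1] +
         p[cc, i, k + 1] - 4 * p[cc, i, k]
    res <- max(res, abs(r))
  }
  expect_lt(res / scale, 1e-10)
  # round window is pressure-release
  expect_lt(max(abs(p[2, 1, ])) / scale, 1e-10)
  # helicotrema reference: slow pressure vanishes at (L, 0)
  expect_equal(slow_pressure(p)[1, nx, 1], 0 + 0i)
})

test_that("little slow-wave pressure reaches the helicotrema", {
  m <- coarse_model()
  sol <- solve_harmonic(m, 4400, active = FALSE)
  ps <- slow_pressure(sol$p)
  nx <- dim(ps)[2]
  tail_amp <- max(abs(ps[, (nx - 5):nx, ]))
  expect_lt(tail_amp, 0.01 * max(abs(ps)))
})

test_that("grid refinement changes the stapes pressure by a few percent only", {
  s1 <- preset_spec("tiny")
  s2 <- preset_spec("tiny", pitch_um = 25)
  m1 <- build_model(s1); m2 <- build_model(s2)
  p1 <- stapes_pressure(solve_harmonic(m1, 2000, active = FALSE))
  p2 <- stapes_pressure(solve_harmonic(m2, 2000, active = FALSE))
  expect_lt(abs(p1 - p2) / p2, 0.05)
})
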