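test_that("cantilever tip deflection matches the closed-form beam solution", {
  # 10-element cantilever, tip load; oracle PL^3/(3EI)
  E <- 1e6; d <- 5e-6
  sec <- cortimech:::circ_section(d)
  L <- 100e-6; ne <- 10
  nn <- ne + 1
  K <- matrix(0, nn * 6, nn * 6)
  xs <- seq(0, L, length.out = nn)
  for (e in seq_len(ne)) {
    gm <- cortimech:::beam_global_matrices(E, E / 2.6, sec$A, sec$Iy, sec$Iz,
                                           sec$J, 1000,
                                           c(xs[e], 0, 0), c(xs[e + 1], 0, 0))
    gi <- c((e - 1) * 6 + 1:6, e * 6 + 1:6)
    K[gi, gi] <- K[gi, gi] + gm$k
  }
  free <- 7:(nn * 6)
  f <- numeric(nn * 6)
  P <- 1e-9
  f[(nn - 1) * 6 + 2] <- P      # transverse tip load
  u <- solve(K[free, free], f[free])
  tip <- u[length(u) - 4]       # uy of the last node
  oracle <- P * L^3 / (3 * E * sec$Iz)
  expect_equal(tip, oracle, tolerance = 5e-3)
})

test_that("mesh has one merged OHC element and one bundle link per section", {
  m <- tiny_model()
  expect_equal(sum(m$mesh$beams$tag == "OHC"), 25)
  expect_equal(nrow(m$mats$cp), 25)
  expect_true(all(!is.na(m$mats$cp$T2z[2:24])))
  # per-cell axial stiffness at the base: EA/L ~ 47.5 mN/m (merged / 3)
  p2 <- interpolate_params(2)
  EA <- p2$ohc_E * 1e6 * pi * (p2$ohc_diam * 1e-6)^2 / 4
  expect_equal(EA / 3 / (p2$ohc_len * 1e-6), 47.7e-3, tolerance = 0.02)
})

test_that("boundary conditions hinge the lamina and clamp ligament and limbus", {
  m <- tiny_model()
  mesh <- m$mesh
  s <- 10
  roles <- mesh$roles
  nid <- function(role) (s - 1) * 10 + match(role, roles)
  dofs <- function(n) (n - 1) * 6 + 1:6
  b0 <- mesh$fixed[dofs(nid("B0"))]
  expect_equal(b0, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))  # hinge
  expect_true(all(mesh$fixed[dofs(nid("B3"))]))               # ligament clamp
  expect_true(all(mesh$fixed[dofs(nid("T0"))]))               # limbus clamp
  end_nodes <- c(1:10, (25 - 1) * 10 + 1:10)
  expect_true(all(mesh$fixed[as.vector(sapply(end_nodes, dofs))]))
})

test_that("system matrices are symmetric and (semi)definite", {
  m <- tiny_model()
  K <- m$mats$K; M <- m$mats$M; C <- m$mats$C
  expect_lt(max(abs(K - Matrix::t(K))) / max(abs(K)), 1e-12)
  expect_lt(max(abs(M - Matrix::t(M))) / max(abs(M)), 1e-12)
  expect_lt(max(abs(C - Matrix::t(C))) / max(abs(C)), 1e-12)
  set.seed(7)
  n <- m$mats$nfree
  for (k in 1:100) {
    v <- rnorm(n)
    expect_gt(as.numeric(t(v) %*% (K %*% v)), 0)
  }
  v <- rnorm(n)
  expect_gt(as.numeric(t(v) %*% (M %*% v)), 0)
  expect_gte(as.numeric(t(v) %*% (C %*% v)), 0)
})

test_that("zero Rayleigh coefficient and dampers give zero damping matrix", {
  m0 <- build_model(preset_spec("tiny", scales = c(damping = 0)))
  expect_equal(max(abs(m0$mats$C)), 0)
})

test_that("subtectorial damping follows the viscous film formula", {
  expect_equal(subtectorial_damping(0.7e-3, 10e-6, 10e-6, 1e-6), 7e-8)
  c1 <- subtectorial_damping(0.7e-3, 10e-6, 10e-6, 1e-6)
  expect_equal(subtectorial_damping(0.7e-3, 10e-6, 10e-6, 10e-6), c1 / 10)
  expect_equal(subtectorial_damping(0, 1e-6, 1e-6, 1e-6), 0)
  expect_error(subtectorial_damping(0.7e-3, 1e-6, 1e-6, 0), "positive")
})

test_that("static solves satisfy reciprocity and energy consistency", {
  m <- tiny_model()
  n <- m$mats$nfree
  cp <- m$mats$cp
  i <- cp$B2y[10]; j <- cp$T2y[15]
  F <- matrix(0, n, 2)
  F[i, 1] <- 1e-9
  F[j, 2] <- 1e-9
  U <- static_solve(m$mats, F)
  expect_equal(U[j, 1], U[i, 2], tolerance = 1e-8)      # Maxwell-Betti
  u <- U[, 1]
  w_int <- 0.5 * as.numeric(t(u) %*% (m$mats$K %*% u))
  w_ext <- 0.5 * sum(F[, 1] * u)
  expect_equal(w_int, w_ext, tolerance = 1e-8)
  expect_equal(static_solve(m$mats, numeric(n)), numeric(n))
})

test_that("interior sections are translation-invariant for constant parameters", {
  # constant-parameter fixture: interior cross-sections respond identically
  tab <- standard_anchors()
  tab$apex <- tab$base
  spec <- preset_spec("tiny")
  params <- interpolate_params(seq(0, 1.2, length.out = 25), table = tab,
                               L = 1.2)
  params$alpha_us <- damping_coefficient(params$x_mm)
  m <- build_model(spec, params = params)
  cp <- m$mats$cp
  n <- m$mats$nfree
  comp <- sapply(c(12, 13), function(s) {
    f <- numeric(n); f[cp$B2y[s]] <- 1e-9
    static_solve(m$mats, f)[cp$B2y[s]]
  })
  expect_equal(comp[1], comp[2], tolerance = 1e-6)
})

test_that("doubling the length of a constant fixture leaves mid compliance unchanged", {
  tab <- standard_anchors()
  tab$apex <- tab$base
  mk <- function(L) {
    spec <- preset_spec("tiny", L_mm = L)
    params <- interpolate_params(seq(0, L, length.out = spec$n_sections),
                                 table = tab, L = L)
    params$alpha_us <- damping_coefficient(params$x_mm)
    build_model(spec, params = params)
  }
  m1 <- mk(1.2); m2 <- mk(2.4)
  cmid <- function(m) {
    s <- round(m$spec$n_sections / 2)
    f <- numeric(m$mats$nfree); f[m$mats$cp$B2y[s]] <- 1e-9
    static_solve(m$mats, f)[m$mats$cp$B2y[s]]
  }
  expect_equal(cmid(m1), cmid(m2), tolerance = 0.01)
})
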