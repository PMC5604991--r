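# 3-D Euler-Bernoulli space-frame elements (6 DOF/node, 12x12 matrices).
# Local DOF order per node: ux, uy, uz, rx, ry, rz; local x = beam axis,
# bending about local z deflects along local y and uses Iz, bending about
# local y deflects along local z and uses Iy.

beam_k_local <- function(E, G, A, Iy, Iz, J, L) {
  k <- matrix(0, 12, 12)
  ea <- E * A / L
  gj <- G * J / L
  k[c(1, 7), c(1, 7)] <- ea * matrix(c(1, -1, -1, 1), 2)
  k[c(4, 10), c(4, 10)] <- gj * matrix(c(1, -1, -1, 1), 2)
  # bending about z: dofs (uy1, rz1, uy2, rz2) = (2, 6, 8, 12)
  bz <- E * Iz / L^3 * matrix(c(
    12,    6 * L,  -12,    6 * L,
    6 * L, 4 * L^2, -6 * L, 2 * L^2,
    -12,  -6 * L,   12,   -6 * L,
    6 * L, 2 * L^2, -6 * L, 4 * L^2), 4, 4, byrow = TRUE)
  k[c(2, 6, 8, 12), c(2, 6, 8, 12)] <- k[c(2, 6, 8, 12), c(2, 6, 8, 12)] + bz
  # bending about y: dofs (uz1, ry1, uz2, ry2) = (3, 5, 9, 11); sign flip
  by <- E * Iy / L^3 * matrix(c(
    12,   -6 * L,  -12,   -6 * L,
    -6 * L, 4 * L^2, 6 * L, 2 * L^2,
    -12,   6 * L,   12,    6 * L,
    -6 * L, 2 * L^2, 6 * L, 4 * L^2), 4, 4, byrow = TRUE)
  k[c(3, 5, 9, 11), c(3, 5, 9, 11)] <- k[c(3, 5, 9, 11), c(3, 5, 9, 11)] + by
  k
}

beam_m_local <- function(rho, A, Iy, Iz, J, L) {
  m <- matrix(0, 12, 12)
  mA <- rho * A * L
  m[c(1, 7), c(1, 7)] <- mA / 6 * matrix(c(2, 1, 1, 2), 2)
  Ip <- Iy + Iz
  mT <- rho * Ip * L
  m[c(4, 10), c(4, 10)] <- mT / 6 * matrix(c(2, 1, 1, 2), 2)
  bend <- function(L) matrix(c(
    156,      22 * L,   54,     -13 * L,
    22 * L,   4 * L^2,  13 * L, -3 * L^2,
    54,       13 * L,   156,    -22 * L,
    -13 * L, -3 * L^2, -22 * L,  4 * L^2), 4, 4, byrow = TRUE)
  bz <- mA / 420 * bend(L)
  m[c(2, 6, 8, 12), c(2, 6, 8, 12)] <- m[c(2, 6, 8, 12), c(2, 6, 8, 12)] + bz
  S <- diag(c(1, -1, 1, -1))
  by <- S %*% bz %*% S   # mirrored rotation sign for the other plane
  m[c(3, 5, 9, 11), c(3, 5, 9, 11)] <- m[c(3, 5, 9, 11), c(3, 5, 9, 11)] + by
  m
}

# rotation matrix rows = local axes in global coordinates
beam_axes <- function(p1, p2) {
  d <- p2 - p1
  L <- sqrt(sum(d^2))
  if (L <= 0) stop("zero-length beam")
  ex <- d / L
  ref <- if (abs(ex[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  ez <- c(ex[2] * ref[3] - ex[3] * ref[2],
          ex[3] * ref[1] - ex[1] * ref[3],
          ex[1] * ref[2] - ex[2] * ref[1])
  ez <- ez / sqrt(sum(ez^2))
  ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
          ez[3] * ex[1] - ez[1] * ex[3],
          ez[1] * ex[2] - ez[2] * ex[1])
  list(R = rbind(ex, ey, ez), L = L)
}

beam_global_matrices <- function(E, G, A, Iy, Iz, J, rho, p1, p2) {
  ax <- beam_axes(p1, p2)
  Tm <- matrix(0, 12, 12)
  for (b in 0:3) Tm[b * 3 + 1:3, b * 3 + 1:3] <- ax$R
  kl <- beam_k_local(E, G, A, Iy, Iz, J, ax$L)
  ml <- beam_m_local(rho, A, Iy, Iz, J, ax$L)
  list(k = crossprod(Tm, kl %*% Tm), m = crossprod(Tm, ml %*% Tm), L = ax$L)
}

# section property helpers -------------------------------------------------

circ_section <- function(d) {
  A <- pi * d^2 / 4
  I <- pi * d^4 / 64
  list(A = A, Iy = I, Iz = I, J = 2 * I)
}

# rectangular strip: `w` along the beam-transverse in-plane direction,
# `t` thickness. For cross-section-plane beams local y is in-plane (width
# w) and local z is the thickness direction; for longitudinal beams local
# y is the thickness (transverse) direction and local z in-plane.
rect_section <- function(w, t, longitudinal = FALSE) {
  A <- w * t
  Ithin <- w * t^3 / 12
  Ithick <- t * w^3 / 12
  J <- w * t^3 / 3
  if (longitudinal) list(A = A, Iy = Ithick, Iz = Ithin, J = J)
  else list(A = A, Iy = Ithin, Iz = Ithick, J = J)
}
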