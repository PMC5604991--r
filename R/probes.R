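#' Static stiffness probes of the organ of Corti complex
#'
#' A self-equilibrated unit force pair is applied either at the ends of
#' the merged OHC element (axial, \eqn{f_C}) or across the hair-bundle
#' shear DOFs (\eqn{f_B}); the resulting relative displacement
#' (\eqn{\delta_C} or \eqn{\delta_B}) gives the total stiffness
#' \eqn{f/\delta}, which decomposes into the element's own stiffness plus
#' the stiffness of the surrounding OCC.  The impedance-matching ratios
#' are \eqn{r_{OHC} = (f_C/\delta_C - k_{OHC})/k_{OHC}} and
#' \eqn{r_{OHB} = (f_B/\delta_B - k_{OHB})/k_{OHB}}.  Probes use the
#' static structural system without fluid.
#'
#' @param model a [build_model()] bundle.
#' @param x_mm positions to probe (mm); must be interior (not the clamped
#'   end cross-sections).
#' @return data frame of class \code{probe_result} with per-position
#'   stiffnesses (N/m, merged 3-row convention) and ratios.
#' @export
probe_stiffness <- function(model, x_mm) {
  cp <- model$mats$cp
  secs <- vapply(x_mm, function(x) section_at(model, x), integer(1))
  edge <- is.na(cp$R2t1[secs]) | is.na(cp$T2z[secs])
  if (any(edge))
    stop("cannot probe clamped end sections (x = ",
         paste(x_mm[edge], collapse = ", "), " mm)")
  n <- length(secs)
  nfree <- model$mats$nfree
  Fm <- matrix(0, nfree, 2 * n)
  for (k in seq_len(n)) {
    s <- secs[k]
    a <- c(cp$ax[s], cp$ay[s], cp$az[s])
    for (d in 1:3) {   # expansion pair on the OHC ends
      Fm[cp[[paste0("R2t", d)]][s], k] <- a[d]
      Fm[cp[[paste0("D1t", d)]][s], k] <- -a[d]
    }
    Fm[cp$T2z[s], n + k] <- 1     # shear pair across the bundle
    Fm[cp$R2z[s], n + k] <- -1
  }
  U <- static_solve(model$mats, Fm)
  k_tot_c <- k_tot_b <- numeric(n)
  for (k in seq_len(n)) {
    s <- secs[k]
    a <- c(cp$ax[s], cp$ay[s], cp$az[s])
    dC <- sum(a * (U[c(cp$R2t1[s], cp$R2t2[s], cp$R2t3[s]), k] -
                   U[c(cp$D1t1[s], cp$D1t2[s], cp$D1t3[s]), k]))
    dB <- U[cp$T2z[s], n + k] - U[cp$R2z[s], n + k]
    k_tot_c[k] <- 1 / dC
    k_tot_b[k] <- 1 / dB
  }
  p <- model$params[secs, ]
  k_ohc <- model$elec$ncell[secs] / 3 *
    p$ohc_E * 1e6 * pi * (p$ohc_diam * 1e-6)^2 / 4 /
    cp$ohc_len[secs]                     # merged axial EA/L
  k_ohb <- cp$k_hb[secs]                 # merged bundle stiffness
  out <- data.frame(
    x_mm = cp$x_mm[secs], sec = secs,
    k_ohc = k_ohc, k_occ_c = k_tot_c - k_ohc,
    r_ohc = (k_tot_c - k_ohc) / k_ohc,
    k_ohb = k_ohb, k_occ_b = k_tot_b - k_ohb,
    r_ohb = (k_tot_b - k_ohb) / k_ohb)
  class(out) <- c("probe_result", class(out))
  out
}

#' Adjust a stiffness profile to impose a target r-ratio profile
#'
#' Iteratively rescales the tonotopic profile of either the OHC axial
#' stiffness (via its Young's modulus) or the hair-bundle stiffness so
#' that \eqn{r_{OHC}(x)} or \eqn{r_{OHB}(x)} matches a target profile:
#' the standard profile mirrored about the mid-point x = L/2, or a
#' constant.  The surrounding-OCC stiffness felt at each probe point is
#' re-measured at every iteration, and the element stiffness is set to
#' \eqn{k = k_{OCC}/r_{target}}; convergence is declared when the
#' relative r-error is below \code{tol} everywhere.
#'
#' @param model a [build_model()] bundle.
#' @param which \code{"r_ohc"} or \code{"r_ohb"}.
#' @param target \code{"mirror"} or \code{"constant"}.
#' @param value constant target value (required for
#'   \code{target = "constant"}).
#' @param probe_x probe grid (mm).
#' @param tol relative tolerance on the achieved r profile.
#' @param maxit maximum fixed-point iterations.
#' @return list with the adjusted \code{model}, the achieved \code{probes},
#'   the \code{target} profile, iteration count and the base-to-apex
#'   stiffness ratio \code{k_ratio} (value at 2 mm over value at 10 mm).
#' @export
adjust_r_profile <- function(model, which = c("r_ohc", "r_ohb"),
                             target = c("mirror", "constant"), value = NULL,
                             probe_x = NULL, tol = 0.02, maxit = 50) {
  which <- match.arg(which)
  target <- match.arg(target)
  spec <- model$spec
  L <- spec$L_mm
  if (is.null(probe_x))
    probe_x <- seq(0.05 * L, 0.95 * L, length.out = 19)
  pr0 <- probe_stiffness(model, probe_x)
  r0 <- if (which == "r_ohc") pr0$r_ohc else pr0$r_ohb
  r_t <- switch(target,
    mirror = stats::approx(probe_x, r0, xout = L - probe_x, rule = 2)$y,
    constant = {
      if (is.null(value)) stop("constant target needs a value")
      rep(value, length(probe_x))
    })
  col <- if (which == "r_ohc") "ohc_E" else "k_ohb"
  params <- model$params
  cur <- model
  for (it in seq_len(maxit)) {
    pr <- probe_stiffness(cur, probe_x)
    k_elem <- if (which == "r_ohc") pr$k_ohc else pr$k_ohb
    k_occ <- if (which == "r_ohc") pr$k_occ_c else pr$k_occ_b
    r_cur <- k_occ / k_elem
    err <- max(abs(r_cur - r_t) / abs(r_t))
    if (err < tol) {
      kx <- stats::approx(probe_x, k_elem, xout = c(2, 10), rule = 2)$y
      return(list(model = cur, probes = pr, target = r_t,
                  iterations = it - 1L, k_ratio = kx[1] / kx[2],
                  err = err))
    }
    fac <- (k_occ / r_t) / k_elem
    lf <- stats::approx(probe_x, log(fac), xout = params$x_mm, rule = 2)$y
    params[[col]] <- params[[col]] * exp(lf)
    cur <- build_model(spec, params = params)
  }
  stop("r-profile adjustment did not converge; residual ", signif(err, 3))
}
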