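## Guided modes of step-index waveguides under the scalar, weakly-guiding
## (LP) approximation, and the Gaussian fundamental-mode model for the
## single-mode corelets.

## Ratio K_{l+1}(w) / K_l(w), robust to overflow of besselK at high order /
## small argument, where the exact small-argument power law gives 2l/w.
besselK_ratio <- function(w, l) {
  a <- besselK(w, l + 1, expon.scaled = TRUE)
  b <- besselK(w, l, expon.scaled = TRUE)
  r <- a / b
  bad <- !is.finite(r)
  if (any(bad)) r[bad] <- (l + sqrt(l^2 + w[bad]^2)) / w[bad]
  r
}

## LP dispersion residual for azimuthal order l at normalized frequency V:
##   u J_{l+1}(u) K_l(w) - w K_{l+1}(w) J_l(u) = 0,  w = sqrt(V^2 - u^2).
## Written with the K-ratio so it stays finite at high order.
lp_dispersion <- function(u, l, V) {
  w <- sqrt(pmax(V^2 - u^2, 0))
  w <- pmax(w, 1e-12)
  u * besselJ(u, l + 1) - w * besselK_ratio(w, l) * besselJ(u, l)
}

## All roots u of the LP dispersion relation for order l in (0, V).
lp_roots_l <- function(l, V, n_scan = NULL) {
  if (is.null(n_scan)) n_scan <- max(1200L, ceiling(30 * V))
  us <- seq(1e-6, V * (1 - 1e-9), length.out = n_scan)
  gs <- lp_dispersion(us, l, V)
  sgn <- sign(gs)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  vapply(idx, function(i) {
    stats::uniroot(lp_dispersion, c(us[i], us[i + 1]), l = l, V = V,
                   tol = 1e-12)$root
  }, numeric(1))
}

## Table of guided LP(l, m) branches below V: columns l, m, u, w.
lp_mode_table <- function(V) {
  rows <- list()
  for (l in 0:ceiling(V + 2)) {
    u <- lp_roots_l(l, V)
    if (length(u) == 0) {
      if (l > 0) break else next
    }
    rows[[length(rows) + 1L]] <-
      data.frame(l = l, m = seq_along(u), u = u, w = sqrt(V^2 - u^2))
  }
  if (length(rows) == 0)
    return(data.frame(l = integer(), m = integer(),
                      u = numeric(), w = numeric()))
  do.call(rbind, rows)
}

## Radial profile K_l(w r / a) / K_l(w) for r > a, with the small-argument
## power-law fallback (r/a)^{-l} where besselK overflows.
lp_outer_radial <- function(rho, l, w) {     # rho = r / a >= 1
  num <- besselK(w * rho, l, expon.scaled = TRUE)
  den <- besselK(w, l, expon.scaled = TRUE)
  out <- num / den * exp(-w * (rho - 1))
  bad <- !is.finite(out)
  if (any(bad)) out[bad] <- rho[bad]^(-l) * exp(-w * (rho[bad] - 1))
  out
}

lp_radial <- function(r, a, l, u, w) {
  rho <- r / a
  out <- numeric(length(r))
  inside <- rho <= 1
  if (any(inside))
    out[inside] <- besselJ(u * rho[inside], l) / besselJ(u, l)
  if (any(!inside))
    out[!inside] <- lp_outer_radial(rho[!inside], l, w)
  out
}

#' Solve the guided LP modes of a step-index waveguide
#'
#' Finds all scalar LP(l, m) modes with cutoff below the V-number by root
#' bracketing of the weakly-guiding characteristic equation, samples them on
#' a centered grid, and (by default) polishes the sampled set to exact
#' discrete orthonormality by symmetric (Loewdin) orthogonalization.
#' Degenerate `l > 0` branches are returned as cos/sin orientation pairs.
#'
#' Propagation constants are returned as offsets from the cladding plane-wave
#' constant (`beta - k n_clad`, rad/um), which avoids catastrophic
#' cancellation between near-equal large numbers.
#'
#' @param core_diameter core diameter (um).
#' @param na numerical aperture.
#' @param wavelength wavelength (nm).
#' @param n grid size (points per side).
#' @param extent physical grid side length (um); default `2 * core_diameter`.
#' @param max_modes cap on the number of scalar modes returned; if the guided
#'   set is larger, the lowest-order modes are kept and the result carries
#'   `truncated = TRUE`, with a warning.
#' @param n_clad cladding refractive index (silica default).
#' @param orthonormalize polish the discrete basis to orthonormality.
#' @return An object of class `mode_set`: list with `fields` (npix x nmodes
#'   matrix, columns are modes flattened column-major as `matrix(n, n)`),
#'   `labels` (data frame `l`, `m`, `orientation`), `u`, `w`, `beta_offset`
#'   (rad/um), `n`, `pitch`, `wavelength`, `v`, `truncated`.
#' @export
#' @examples
#' ms <- solve_lp_modes(10, 0.1, 488, n = 96)   # V ~ 6.4
#' ncol(ms$fields)
solve_lp_modes <- function(core_diameter, na, wavelength, n = 256,
                           extent = NULL, max_modes = Inf, n_clad = 1.45,
                           orthonormalize = TRUE) {
  v <- v_number(core_diameter, na, wavelength)
  if (is.null(extent)) extent <- 2 * core_diameter
  pitch <- extent / n
  a <- core_diameter / 2
  lam <- wavelength * 1e-3
  k <- 2 * pi / lam
  tab <- lp_mode_table(v)
  if (nrow(tab) == 0) hf_invalid("no guided modes below V; check arguments")
  ## beta - k n_clad = (w/a)^2 / (beta + k n_clad)
  n_core <- sqrt(n_clad^2 + na^2)
  beta <- sqrt(pmax((k * n_core)^2 - (tab$u / a)^2, 0))
  tab$beta_offset <- (tab$w / a)^2 / (beta + k * n_clad)
  ## expand orientation pairs, order by decreasing propagation constant
  reps <- ifelse(tab$l == 0, 1L, 2L)
  idx <- rep(seq_len(nrow(tab)), reps)
  ori <- unlist(lapply(reps, function(r) if (r == 1L) "cos" else c("cos", "sin")))
  tab <- tab[idx, , drop = FALSE]
  tab$orientation <- ori
  ord <- order(-tab$beta_offset, tab$l, tab$m, tab$orientation)
  tab <- tab[ord, , drop = FALSE]
  truncated <- FALSE
  if (nrow(tab) > max_modes) {
    truncated <- TRUE
    warning(sprintf("guided set (%d scalar modes) truncated to max_modes = %d",
                    nrow(tab), max_modes))
    tab <- tab[seq_len(max_modes), , drop = FALSE]
  }
  xs <- grid_axis(n, pitch)
  x <- matrix(xs, n, n, byrow = TRUE)
  y <- matrix(xs, n, n)
  phi <- atan2(y, x)
  rr <- sqrt(x^2 + y^2)
  fields <- matrix(0, n * n, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    rad <- lp_radial(as.vector(rr), a, tab$l[i], tab$u[i], tab$w[i])
    az <- if (tab$l[i] == 0) 1
          else if (tab$orientation[i] == "cos") cos(tab$l[i] * as.vector(phi))
          else sin(tab$l[i] * as.vector(phi))
    f <- rad * az
    nrm <- sqrt(sum(f^2) * pitch^2)
    fields[, i] <- f / nrm
  }
  if (orthonormalize && ncol(fields) > 1) {
    s <- crossprod(fields) * pitch^2
    e <- eigen(s, symmetric = TRUE)
    if (min(e$values) < 1e-6)
      warning("mode Gram matrix nearly singular; grid may be too coarse")
    shalf <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
    fields <- fields %*% shalf
  }
  rownames(tab) <- NULL
  structure(list(fields = fields,
                 labels = tab[, c("l", "m", "orientation")],
                 u = tab$u, w = tab$w, beta_offset = tab$beta_offset,
                 n = n, pitch = pitch, wavelength = wavelength,
                 v = v, core_diameter = core_diameter, na = na,
                 truncated = truncated),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("<mode_set: %d scalar LP modes, V = %.3f, grid %d x %d @ %.3g um>\n",
              ncol(x$fields), x$v, x$n, x$n, x$pitch))
  invisible(x)
}

#' Extract one mode as a complex_field
#'
#' @param modes a [solve_lp_modes()] result.
#' @param i mode index.
#' @return a [complex_field()].
#' @export
mode_field <- function(modes, i) {
  complex_field(matrix(modes$fields[, i], modes$n, modes$n), modes$pitch,
                wavelength = modes$wavelength)
}

#' Gaussian fundamental-mode model of a corelet
#'
#' For a single-mode corelet (V <= 2.405) the fundamental mode is modeled as
#' a Gaussian with the Marcuse waist
#' `w = a * (0.65 + 1.619 V^{-3/2} + 2.879 V^{-6})`, `a` the core radius.
#'
#' @param spec a [fiber_spec()] (corelet geometry fields are used).
#' @param center corelet center `(x, y)` (um).
#' @return An object of class `gaussian_mode`: list with `waist`, `center`,
#'   `wavelength`.
#' @export
#' @examples
#' corelet_mode(fiber_preset("m3cf"))$waist
corelet_mode <- function(spec, center = c(0, 0)) {
  if (!inherits(spec, "fiber_spec")) hf_invalid("`spec` must be a fiber_spec")
  v <- v_number(spec$corelet_core_diameter, spec$corelet_na, spec$wavelength)
  if (v > 2.405)
    hf_stop(sprintf("corelet V = %.3f > 2.405: not single-mode", v),
            "holofiber_not_single_mode")
  a <- spec$corelet_core_diameter / 2
  w <- a * (0.65 + 1.619 * v^(-3 / 2) + 2.879 * v^(-6))
  structure(list(waist = w, center = as.numeric(center),
                 wavelength = spec$wavelength, v = v),
            class = "gaussian_mode")
}

#' Sample a Gaussian mode on a grid
#'
#' @param mode a [corelet_mode()] result.
#' @param n grid size.
#' @param pitch grid pitch (um).
#' @param z propagation distance from the facet (um).
#' @param grid_center physical grid center (um).
#' @return a unit-power [complex_field()].
#' @export
gaussian_mode_field <- function(mode, n, pitch, z = 0,
                                grid_center = c(0, 0)) {
  gaussian_field(n, pitch, center = mode$center, waist = mode$waist, z = z,
                 wavelength = mode$wavelength, grid_center = grid_center)
}

## Radial normalization integral of an LP branch: int_0^Inf R(r)^2 r dr.
lp_radial_norm <- function(a, l, u, w) {
  inner <- stats::integrate(function(r) lp_radial(r, a, l, u, w)^2 * r,
                            0, a, rel.tol = 1e-10)$value
  outer_ <- stats::integrate(function(r) lp_radial(r, a, l, u, w)^2 * r,
                             a, Inf, rel.tol = 1e-9)$value
  inner + outer_
}

#' Diffraction-limited focus of full modal control (mode-projection kernel)
#'
#' The tightest focus reachable with complete control of the guided modes is
#' the projection of a point target onto the guided subspace,
#' `K(r; r0) = sum_m psi_m(r) conj(psi_m(r0))`.  This evaluates the kernel
#' semi-analytically (exact radial profiles, 1-D quadrature norms, azimuthal
#' sums in closed form) on a local grid around the target, which stays cheap
#' and accurate at V-numbers where gridded mode sets become unwieldy.
#'
#' @param core_diameter core diameter (um).
#' @param na numerical aperture.
#' @param wavelength wavelength (nm).
#' @param target focus position `(x, y)` (um), inside the core.
#' @param n local grid size.
#' @param pitch local grid pitch (um).
#' @return a [complex_field()] (real-valued) centered on `target`, amplitude
#'   the kernel; squared modulus is the ideal focus intensity.
#' @export
#' @examples
#' psf <- mode_projection_psf(20, 0.1, 488, n = 64, pitch = 0.3)
mode_projection_psf <- function(core_diameter, na, wavelength,
                                target = c(0, 0), n = 128, pitch = 0.15) {
  a <- core_diameter / 2
  r0 <- sqrt(sum(target^2))
  if (r0 >= a) hf_invalid("`target` must lie inside the core")
  phi0 <- atan2(target[2], target[1])
  v <- v_number(core_diameter, na, wavelength)
  tab <- lp_mode_table(v)
  xs <- grid_axis(n, pitch)
  x <- matrix(xs, n, n, byrow = TRUE) + target[1]
  y <- matrix(xs, n, n) + target[2]
  r <- sqrt(x^2 + y^2)
  dphi <- atan2(y, x) - phi0
  kern <- matrix(0, n, n)
  for (i in seq_len(nrow(tab))) {
    l <- tab$l[i]; u <- tab$u[i]; w <- tab$w[i]
    nrm <- lp_radial_norm(a, l, u, w) * (if (l == 0) 2 * pi else pi)
    R0 <- lp_radial(r0, a, l, u, w)
    if (abs(R0) < 1e-14) next
    Rr <- matrix(lp_radial(as.vector(r), a, l, u, w), n, n)
    az <- if (l == 0) 1 else cos(l * dphi)
    kern <- kern + Rr * az * (R0 / nrm)
  }
  complex_field(kern, pitch, center = as.numeric(target),
                wavelength = wavelength)
}
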