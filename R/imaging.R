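## Raster-scan fluorescence image formation in the multimode regime, the
## 61-pixel corelet image in the multicore regime, detector noise, and
## image-quality metrics.

#' Scan plan for raster imaging
#'
#' @param n output grid size (points per side); the full-scale default is
#'   352, tests typically use 88 at 2.8 um pitch (same physical extent).
#' @param pitch scan pitch (um).
#' @param core_diameter diameter of the scanned core circle (um).
#' @param working_distance imaging-plane offset from the facet (um).
#' @return An object of class `scan_plan`: includes the core `mask`, the
#'   row-major raster order of masked scan points, and their positions.
#' @export
#' @examples
#' plan <- scan_plan(88, 2.8, 232)
#' sum(plan$mask)
scan_plan <- function(n = 352, pitch = 0.7, core_diameter = 232,
                      working_distance = 15) {
  mask <- aperture_mask(n, pitch, core_diameter)
  xs <- grid_axis(n, pitch)
  ## row-major raster order: x fastest within a row, rows from -y upward;
  ## `index` holds the linear (column-major) indices of the masked points
  ## in that scan order
  rowmajor <- as.vector(t(matrix(seq_len(n * n), n, n)))
  keep <- rowmajor[as.vector(t(mask))]
  ij <- arrayInd(keep, c(n, n))
  pts <- cbind(x = xs[ij[, 2]], y = xs[ij[, 1]])
  structure(list(n = n, pitch = pitch, core_diameter = core_diameter,
                 working_distance = working_distance, mask = mask,
                 index = keep, points = pts),
            class = "scan_plan")
}

#' Detector model
#'
#' The photomultiplier is abstracted to a Poisson photon counter: a scan
#' value with expected signal `s` is recorded as
#' `Poisson(photons_per_unit_signal * s + dark_rate)` counts.
#'
#' @param photons_per_unit_signal photon scale (counts per unit signal).
#' @param dark_rate dark counts per scan point.
#' @param seed detector seed.
#' @return An object of class `detector_model`, or `NULL` semantics: pass
#'   `detector = NULL` to imaging functions for an ideal (expected-value)
#'   detector.
#' @export
detector_model <- function(photons_per_unit_signal = 1e4, dark_rate = 0,
                           seed = 1L) {
  if (photons_per_unit_signal < 0 || dark_rate < 0)
    hf_invalid("detector parameters must be nonnegative")
  structure(list(photons = photons_per_unit_signal, dark = dark_rate,
                 seed = seed),
            class = "detector_model")
}

## Apply the detector to a vector of expected signals.  Tiny negative
## values (FFT roundoff) are clamped to zero before the Poisson draw.
detect <- function(values, detector) {
  if (is.null(detector)) return(values)
  with_seed(detector$seed,
            stats::rpois(length(values),
                         detector$photons * pmax(values, 0) + detector$dark))
}

#' Raster image container
#'
#' @param pixels numeric matrix on the scan grid; out-of-mask pixels are NA
#'   (invalid), never zero-filled.
#' @param plan the [scan_plan()].
#' @param metadata named list of provenance (seeds, TM identity, ...).
#' @return an object of class `raster_image`.
#' @export
raster_image <- function(pixels, plan, metadata = list()) {
  structure(list(pixels = pixels, mask = plan$mask, pitch = plan$pitch,
                 plan = plan, metadata = metadata),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image %d x %d @ %g um, %d valid px>\n",
              nrow(x$pixels), ncol(x$pixels), x$pitch, sum(x$mask)))
  invisible(x)
}

#' Raster-scan fluorescence image
#'
#' Scans a focus across the masked scan points; each scan value is the
#' overlap integral of the focus intensity at the working-distance plane
#' with the phantom's fluorophore density, passed through the detector.
#'
#' Two focus models are supported. `psf`: an explicit focus intensity
#' kernel (shift-invariant ideal foci; the image is the kernel correlated
#' with the density, computed by zero-padded FFT).  `mtm` + `system`: each
#' focus is synthesized from the measured transmission matrix and replayed
#' through the ground-truth system (shift-variant; used at reduced scale).
#'
#' @param phantom a [make_bead_phantom()] / [make_purkinje_phantom()]
#'   phantom whose grid matches the plan grid.
#' @param plan a [scan_plan()].
#' @param psf numeric matrix: focus intensity kernel sampled at the plan
#'   pitch (odd dimensions recommended), integrating to its physical power.
#' @param mtm,system alternative focus model: a `measured_tm` plus the
#'   [fiber_system()] to replay through.
#' @param detector a [detector_model()] or `NULL` for expected values.
#' @return a [raster_image()]; pixel unit is detector counts (or expected
#'   signal for `detector = NULL`).
#' @export
raster_scan_image <- function(phantom, plan, psf = NULL, mtm = NULL,
                              system = NULL, detector = NULL) {
  if (!inherits(plan, "scan_plan")) hf_invalid("`plan` must be a scan_plan")
  rho <- phantom$density
  if (!is.null(psf)) {
    if (any(dim(rho) != c(plan$n, plan$n)) ||
        abs(phantom$pitch - plan$pitch) > 1e-9)
      hf_invalid("phantom grid does not match the scan plan grid")
    vals_full <- fft_correlate(rho, psf) * plan$pitch^2
    vals <- vals_full[plan$index]
  } else if (!is.null(mtm) && !is.null(system)) {
    return(tm_raster_scan(mtm, system, phantom, plan, detector = detector))
  } else hf_invalid("provide either `psf` or both `mtm` and `system`")
  counts <- detect(vals, detector)
  px <- matrix(NA_real_, plan$n, plan$n)
  px[plan$index] <- counts
  raster_image(px, plan,
               metadata = c(list(phantom_seed = phantom$seed),
                            if (!is.null(detector)) unclass(detector)))
}

## Cross-correlation image[s] = sum_r k(r - r_s) rho(r): zero-padded FFT.
fft_correlate <- function(rho, kernel) {
  n <- dim(rho); m <- dim(kernel)
  np <- n + m
  pr <- matrix(0, np[1], np[2]); pr[seq_len(n[1]), seq_len(n[2])] <- rho
  pk <- matrix(0, np[1], np[2]); pk[seq_len(m[1]), seq_len(m[2])] <- kernel
  cc <- Re(stats::fft(stats::fft(pr) * Conj(stats::fft(pk)),
                      inverse = TRUE)) / prod(np)
  ## kernel center offset (1-based center index)
  c0 <- (m + 1) %/% 2
  cc[(seq_len(n[1]) - c0[1]) %% np[1] + 1L,
     (seq_len(n[2]) - c0[2]) %% np[2] + 1L]
}

#' Raster image through a measured transmission matrix
#'
#' Shift-variant raster imaging: every scan focus is synthesized from the
#' measured TM, replayed through the ground-truth system, propagated to the
#' working-distance plane, and integrated against the phantom density.
#' Computed with batched matrix products; intended for reduced-scale
#' systems.
#'
#' @param mtm a `measured_tm` (reference removed or not; focusing is
#'   invariant to the per-row reference factor).
#' @param system the [fiber_system()].
#' @param phantom phantom on the camera grid of the system.
#' @param plan a [scan_plan()] on the same grid.
#' @param tm_override optional `transmission_matrix` replacing the system's
#'   ground truth at replay time (e.g. a deformed fiber).
#' @param detector a [detector_model()] or `NULL`.
#' @return a [raster_image()].
#' @export
tm_raster_scan <- function(mtm, system, phantom, plan, tm_override = NULL,
                           detector = NULL) {
  m <- system$modes
  if (any(dim(phantom$density) != c(plan$n, plan$n)))
    hf_invalid("phantom grid does not match the scan plan grid")
  if (plan$n != m$n || abs(plan$pitch - m$pitch) > 1e-9)
    hf_invalid("scan plan grid must match the system camera grid")
  tm <- if (is.null(tm_override)) system$tm else tm_override
  ## matched-filter inputs for all scan targets, in the input-spot basis
  ti <- match(plan$index, mtm$mask_index)
  if (anyNA(ti)) hf_invalid("scan plan mask exceeds the measured TM mask")
  v <- Conj(t(mtm$matrix[ti, mtm$kept_inputs, drop = FALSE]))  # inputs x S
  ## input-spot -> mode coupling matrix (modes x inputs)
  spots <- vapply(mtm$kept_inputs,
                  function(p) as.vector(input_spot(system, mtm$inputs[p, ])),
                  numeric(m$n^2))
  a_sp <- crossprod(m$fields, spots) * m$pitch^2     # modes x inputs
  a <- a_sp %*% v                                    # modes x S
  ## normalize each input field to unit power: spot Gram matrix
  g_sp <- crossprod(spots) * m$pitch^2
  pw <- Re(colSums(Conj(v) * (g_sp %*% v)))
  a <- sweep(a, 2, sqrt(pmax(pw, 1e-300)), `/`)
  b <- tm$matrix %*% a                               # output mode coefs
  ## modes propagated to the working plane
  mf <- m$fields
  if (plan$working_distance != 0) {
    mf <- vapply(seq_len(ncol(mf)), function(i) {
      as.vector(propagate(mode_field(system$modes, i),
                          plan$working_distance)$amplitude)
    }, complex(m$n^2))
  }
  fields <- mf %*% b                                 # pixels x S (complex)
  vals <- as.vector(crossprod(Mod(fields)^2,
                              as.vector(phantom$density))) * m$pitch^2
  counts <- detect(vals, detector)
  px <- matrix(NA_real_, plan$n, plan$n)
  px[plan$index] <- counts
  raster_image(px, plan, metadata = list(phantom_seed = phantom$seed))
}

#' Corelet-scan (61-pixel) image in the multicore regime
#'
#' Illuminates the corelets one by one in spiral order; the value of corelet
#' `j` is the integral of its illumination intensity at the working-distance
#' plane against the phantom density, through the detector.  Because the
#' multicore transport only ever perturbs channel phases, this image is
#' invariant under fiber deformation (the resilience contract).
#'
#' @param tm a multicore `transmission_matrix` (single fiber or mated pair).
#' @param phantom the phantom (any grid; corelet beams are evaluated
#'   analytically on the phantom grid).
#' @param lattice the [hex_lattice()].
#' @param spec the [fiber_spec()].
#' @param working_distance imaging-plane offset (um).
#' @param detector a [detector_model()] or `NULL`.
#' @return An object of class `corelet_image`: data frame with
#'   `spiral_rank`, `x`, `y`, `value`.
#' @export
corelet_scan_image <- function(tm, phantom, lattice, spec,
                               working_distance = 15, detector = NULL) {
  if (!inherits(tm, "transmission_matrix") || tm$regime != "multicore")
    hf_invalid("`tm` must be a multicore transmission_matrix")
  w <- corelet_mode(spec)$waist
  n <- nrow(phantom$density)
  nc <- nrow(lattice)
  rho <- as.vector(phantom$density)
  vals <- numeric(nc)
  ## cache propagated corelet beams (identical shape, shifted): evaluate
  ## analytically per corelet on the phantom grid
  beams <- vapply(seq_len(nc), function(k) {
    as.vector(gaussian_field(n, phantom$pitch,
                             center = c(lattice$x[k], lattice$y[k]),
                             waist = w, z = working_distance,
                             wavelength = spec$wavelength)$amplitude)
  }, complex(n * n))
  for (j in seq_len(nc)) {
    cvec <- tm$matrix[, j]
    nz <- which(Mod(cvec) > 1e-10)
    fld <- beams[, nz, drop = FALSE] %*% cvec[nz]
    vals[j] <- sum(Mod(fld)^2 * rho) * phantom$pitch^2
  }
  out <- data.frame(spiral_rank = lattice$spiral_rank, x = lattice$x,
                    y = lattice$y, value = detect(vals, detector))
  class(out) <- c("corelet_image", "data.frame")
  out
}

#' Michelson contrast between two image regions
#'
#' `(mean(fg) - mean(bg)) / (mean(fg) + mean(bg))`, in `[-1, 1]`.
#'
#' @param image a [raster_image()], `corelet_image`, or numeric vector /
#'   matrix.
#' @param fg_mask,bg_mask disjoint non-empty logical selections into the
#'   image values.
#' @return Michelson contrast.
#' @export
contrast_metric <- function(image, fg_mask, bg_mask) {
  vals <- if (inherits(image, "raster_image")) image$pixels
          else if (inherits(image, "corelet_image")) image$value
          else image
  if (sum(fg_mask) == 0 || sum(bg_mask) == 0)
    hf_invalid("`fg_mask` and `bg_mask` must be non-empty")
  if (any(fg_mask & bg_mask)) hf_invalid("fg and bg masks must be disjoint")
  f <- mean(vals[fg_mask], na.rm = TRUE)
  b <- mean(vals[bg_mask], na.rm = TRUE)
  if (f + b == 0) return(0)
  (f - b) / (f + b)
}

#' FWHM of a radially averaged intensity profile
#'
#' Radially bins the intensity around `center`, interpolates the first
#' crossing of half the central value, and returns twice that radius.
#'
#' @param intensity nonnegative matrix.
#' @param pitch grid pitch (um).
#' @param center profile center `(x, y)` (um); default the intensity
#'   centroid of the top decile (robust peak estimate).
#' @param bin radial bin width (um); default `pitch / 2`.
#' @return FWHM (um); `NA` with a warning if no half-maximum crossing is
#'   found inside the grid.
#' @export
radial_fwhm <- function(intensity, pitch, center = NULL, bin = pitch / 2) {
  xs <- grid_axis(ncol(intensity), pitch)
  ys <- grid_axis(nrow(intensity), pitch)
  if (is.null(center)) {
    thr <- stats::quantile(intensity, 0.9)
    w <- intensity * (intensity >= thr)
    center <- c(sum(t(w) * xs) / sum(w), sum(w * ys) / sum(w))
  }
  r <- sqrt(outer((ys - center[2])^2, (xs - center[1])^2, `+`))
  b <- floor(r / bin)
  prof <- vapply(split(as.vector(intensity), as.vector(b)), mean, numeric(1))
  rad <- (as.numeric(names(prof)) + 0.5) * bin
  ord <- order(rad)
  prof <- prof[ord]; rad <- rad[ord]
  half <- prof[1] / 2
  below <- which(prof < half)
  if (length(below) == 0 || below[1] == 1) {
    warning("no half-maximum crossing found")
    return(NA_real_)
  }
  i <- below[1]
  r_half <- rad[i - 1] + (half - prof[i - 1]) / (prof[i] - prof[i - 1]) *
    (rad[i] - rad[i - 1])
  unname(2 * r_half)
}

#' Diffraction-limited PSF width of a fiber
#'
#' FWHM of the full-modal-control focus ([mode_projection_psf()]) of the
#' multimode waveguide, measured by radial interpolation.  Converges to the
#' NA-limited estimate `0.51 lambda / NA` as V grows.
#'
#' @param core_diameter core diameter (um).
#' @param na numerical aperture.
#' @param wavelength wavelength (nm).
#' @param target focus position (um).
#' @param n,pitch local evaluation grid.
#' @return FWHM (um).
#' @export
#' @examples
#' psf_fwhm(40, 0.1, 488)    # ~ 0.51 * 0.488 / 0.1 = 2.49 um
psf_fwhm <- function(core_diameter, na, wavelength, target = NULL,
                     n = 96, pitch = NULL) {
  dl <- 0.51 * (wavelength * 1e-3) / na
  if (is.null(pitch)) pitch <- dl / 12
  if (is.null(target)) target <- c(0.35, 0.1) * core_diameter / 2
  psf <- mode_projection_psf(core_diameter, na, wavelength, target = target,
                             n = n, pitch = pitch)
  ## the kernel grid is local: centered on the target
  radial_fwhm(Mod(psf$amplitude)^2, pitch, center = c(0, 0))
}
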