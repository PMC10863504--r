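## Binary-amplitude (Lee) hologram encoding with off-axis first-order
## isolation, four-step phase-shift interferometry, transmission-matrix
## acquisition over an input focal grid, input pruning, and phase-conjugate
## focus synthesis with quality metrics.

#' Encode a complex target field as a binary-amplitude (Lee) hologram
#'
#' A binary micromirror frame whose first diffraction order carries a field
#' proportional to `A * exp(i phi)`: pixel (x, y) is ON iff
#' `cos(2 pi (fx x + fy y) - phi) >= cos(pi q)` with
#' `q = asin(A) / pi`, `A` the target amplitude normalized to max 1.
#' A uniform unit-amplitude target produces a straight 50%-duty grating;
#' zero-amplitude regions are locally unmodulated (all mirrors off).
#'
#' @param target complex matrix (or [complex_field()]) of the desired first
#'   order; `|target|` is normalized to maximum 1.
#' @param carrier 2-vector spatial carrier frequency (cycles/pixel); its
#'   magnitude must be positive and sub-Nyquist (<= 0.5).
#' The default carrier runs along the frame diagonal with magnitude 1/24
#' cycles/pixel (a 24-pixel fringe period): long enough that the stripe
#' widths encoding moderate amplitudes stay above one mirror, and
#' incommensurate with the pixel rows so edge quantization self-dithers.
#'
#' @return An object of class `binary_pattern`: list with logical `frame`
#'   and `carrier`.
#' @export
#' @examples
#' p <- encode_hologram(matrix(1 + 0i, 64, 64), carrier = c(1, 1) / 8)
#' mean(p$frame)    # ~0.5 duty cycle
encode_hologram <- function(target, carrier = c(1, 1) / (24 * sqrt(2))) {
  if (inherits(target, "complex_field")) target <- target$amplitude
  if (!is.matrix(target)) hf_invalid("`target` must be a matrix")
  cmag <- sqrt(sum(carrier^2))
  if (length(carrier) != 2L || cmag <= 0 || cmag > 0.5)
    hf_invalid("`carrier` magnitude must lie in (0, 0.5] cycles/pixel")
  amp <- Mod(target)
  m <- max(amp)
  if (m > 0) amp <- amp / m
  phase <- Arg(target)
  nr <- nrow(target); nc <- ncol(target)
  x <- matrix(seq_len(nc) - 1L, nr, nc, byrow = TRUE)
  y <- matrix(seq_len(nr) - 1L, nr, nc)
  q <- asin(pmin(amp, 1)) / pi
  ## mirror ON iff the carrier phase (relative to the target phase) lies in
  ## the half-open window [-pi q, pi q): equivalent to the textbook
  ## cos(2 pi f.r - phi) >= cos(pi q) rule, but evaluated after exact
  ## phase reduction modulo one cycle so large carrier arguments cannot
  ## jitter pixels on the threshold contour
  frac <- (carrier[1] * x + carrier[2] * y) %% 1
  wrap <- ((2 * pi * frac - phase + pi) %% (2 * pi)) - pi
  frame <- wrap >= -pi * q - 1e-9 & wrap < pi * q - 1e-9
  frame[amp == 0] <- FALSE
  structure(list(frame = frame, carrier = as.numeric(carrier)),
            class = "binary_pattern")
}

#' Simulate first-order diffraction with iris isolation
#'
#' Fourier-transforms a binary frame, crops a circular iris around the
#' carrier frequency, recenters the order and transforms back: the optical
#' train (off-axis grating, Fourier-plane iris, relay) that turns a binary
#' frame into a smooth complex field.  Linear in the pattern.
#'
#' @param pattern a [encode_hologram()] `binary_pattern` (or any logical /
#'   numeric matrix plus `carrier`).
#' @param iris_radius iris radius (cycles/pixel); must be smaller than the
#'   distance of the carrier from both the DC term and its conjugate order,
#'   otherwise orders overlap.
#' @param carrier carrier override when `pattern` is a bare matrix.
#' @return complex matrix: the demodulated first-order field (relative
#'   units).
#' @export
simulate_first_order <- function(pattern, iris_radius = NULL,
                                 carrier = NULL) {
  if (inherits(pattern, "binary_pattern")) {
    frame <- pattern$frame
    carrier <- pattern$carrier
  } else {
    frame <- pattern
    if (is.null(carrier)) hf_invalid("`carrier` required for a bare matrix")
  }
  cmag <- sqrt(sum(carrier^2))
  if (is.null(iris_radius)) iris_radius <- 0.6 * cmag
  if (iris_radius <= 0 || iris_radius >= cmag)
    hf_invalid("`iris_radius` must lie in (0, |carrier|): orders must separate")
  nr <- nrow(frame); nc <- ncol(frame)
  sp <- stats::fft(frame * 1)
  fx <- fft_freq(nc, 1)
  fy <- fft_freq(nr, 1)
  ## wrapped frequency distance from the carrier
  wdist <- function(f, c0) {
    d <- (f - c0) %% 1
    pmin(d, 1 - d)
  }
  ## the binary frame is cos(2 pi f.r - phi) thresholded, so the order that
  ## carries A exp(+i phi) sits at MINUS the carrier frequency
  dx <- wdist(fx, -carrier[1])
  dy <- wdist(fy, -carrier[2])
  mask <- outer(dy^2, dx^2, `+`) < iris_radius^2
  sp[!mask] <- 0 + 0i
  ## recenter: integer-bin circular shift moving -carrier to DC, then
  ## remove the fractional-bin carrier residue as a real-space ramp
  kx <- (-round(carrier[1] * nc)) %% nc
  ky <- (-round(carrier[2] * nr)) %% nr
  sp <- sp[((seq_len(nr) - 1L + ky) %% nr) + 1L,
           ((seq_len(nc) - 1L + kx) %% nc) + 1L]
  out <- stats::fft(sp, inverse = TRUE) / length(sp)
  rx <- carrier[1] - round(carrier[1] * nc) / nc
  ry <- carrier[2] - round(carrier[2] * nr) / nr
  if (rx != 0 || ry != 0) {
    x <- matrix(seq_len(nc) - 1L, nr, nc, byrow = TRUE)
    y <- matrix(seq_len(nr) - 1L, nr, nc)
    out <- out * exp(2i * pi * (rx * x + ry * y))
  }
  out
}

## Fourier resampling by an integer factor (even-sized frames).
fourier_upsample <- function(a, k) {
  n <- nrow(a)
  sp <- stats::fft(a)
  big <- matrix(0 + 0i, n * k, n * k)
  h <- n / 2
  idx <- c(seq_len(h), (n * k - h + 1):(n * k))
  big[idx, idx] <- sp[c(seq_len(h), (h + 1):n), c(seq_len(h), (h + 1):n)]
  stats::fft(big, inverse = TRUE) / n^2
}

fourier_downsample <- function(a, k) {
  nn <- nrow(a)
  n <- nn / k
  sp <- stats::fft(a)
  h <- n / 2
  idx <- c(seq_len(h), (nn - h + 1):nn)
  stats::fft(sp[idx, idx], inverse = TRUE) / nn^2
}

#' Shape a complex field with a binary micromirror device
#'
#' The full light-shaping round trip of the off-axis binary-hologram path:
#' the target field is rendered onto the micromirror frame at `oversample`
#' mirrors per field sample (Fourier interpolation), Lee-encoded
#' ([encode_hologram()]), diffracted and iris-filtered
#' ([simulate_first_order()]), and resampled back onto the field grid.
#' The returned field is the one actually delivered to the fiber; its
#' deviation from the target is the (small) binarization residual of the
#' encoding.
#'
#' @param target complex matrix (even-sized, square) to synthesize.
#' @param oversample mirrors per field sample (integer >= 1).
#' @param carrier carrier frequency (cycles/mirror), as in
#'   [encode_hologram()].
#' @param iris_fraction iris radius as a fraction of the carrier magnitude.
#' @return complex matrix on the target grid, scaled so a unit-amplitude
#'   flat target returns amplitude ~1.
#' @export
dmd_modulate <- function(target, oversample = 8L,
                         carrier = c(1, 1) / (24 * sqrt(2)),
                         iris_fraction = 0.6) {
  if (inherits(target, "complex_field")) target <- target$amplitude
  if (nrow(target) != ncol(target) || nrow(target) %% 2 == 1)
    hf_invalid("`target` must be square with even size")
  up <- if (oversample > 1) fourier_upsample(target, oversample) else target
  pat <- encode_hologram(up, carrier = carrier)
  rec <- simulate_first_order(pat,
                              iris_radius = iris_fraction *
                                sqrt(sum(carrier^2)))
  out <- if (oversample > 1) fourier_downsample(rec, oversample) else rec
  ## first-order efficiency of a 50% grating is 1/pi; undo it
  out * pi * max(Mod(target))
}

#' Four-step phase-shift interferogram set
#'
#' Intensity frames of `|S + R exp(i theta)|^2` for the reference phase
#' steps `theta = 0, pi/2, pi, 3pi/2`, with optional Poisson photon noise.
#'
#' @param signal complex matrix: the signal field `S` at the camera.
#' @param reference complex matrix (or scalar): the reference field `R`.
#' @param photons expected photons per unit intensity per pixel; `NULL` for
#'   a noiseless detector.
#' @param seed detector seed (used when `photons` is not `NULL`).
#' @return An object of class `interferogram_set`: list of four nonnegative
#'   intensity matrices plus `reference_phases`.
#' @export
make_interferograms <- function(signal, reference, photons = NULL,
                                seed = 1L) {
  if (length(reference) == 1L)
    reference <- matrix(reference, nrow(signal), ncol(signal))
  if (!identical(dim(signal), dim(reference)))
    hf_invalid("`signal` and `reference` must have equal shape")
  phases <- c(0, pi / 2, pi, 3 * pi / 2)
  ints <- lapply(phases, function(th) Mod(signal + reference * exp(1i * th))^2)
  if (!is.null(photons)) {
    if (photons <= 0) hf_invalid("`photons` must be > 0")
    ints <- with_seed(seed, lapply(ints, function(I) {
      matrix(stats::rpois(length(I), photons * I), nrow(I)) / photons
    }))
  }
  structure(list(intensities = ints,
                 reference_phases = phases),
            class = "interferogram_set")
}

#' Demodulate a four-step phase-shift interferogram set
#'
#' Exact closed-form demodulation:
#' `C = ((I0 - Ipi) + i (Ipi/2 - I3pi/2)) / 4 = S * Conj(R)`,
#' the signal field modulated by the conjugate reference.  Exactly linear in
#' the signal and exact for noiseless inputs.
#'
#' @param igrams an [make_interferograms()] `interferogram_set` (or a plain
#'   list of four intensity matrices in phase order 0, pi/2, pi, 3pi/2).
#' @return complex matrix `S * Conj(R)`.
#' @export
psi_demodulate <- function(igrams) {
  ints <- if (inherits(igrams, "interferogram_set")) igrams$intensities
          else igrams
  if (length(ints) != 4L) hf_invalid("four interferograms are required")
  dims <- lapply(ints, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    hf_invalid("interferogram shapes differ")
  ((ints[[1]] - ints[[3]]) + 1i * (ints[[2]] - ints[[4]])) / 4
}

#' Scaled fiber system: ground-truth transport plus camera model
#'
#' Bundles a guided-mode basis, a ground-truth multimode transmission
#' matrix, and the interferometric reference beam into one object that maps
#' input facet fields to output facet fields.  This is the "physical truth"
#' that calibration procedures are benchmarked against.
#'
#' @param modes a [solve_lp_modes()] mode set (shared input/output facet
#'   grid and camera grid).
#' @param tm a multimode `transmission_matrix` over `modes`; default a
#'   seeded Haar-mixed matrix.
#' @param seed seed for the default `tm`.
#' @param reference_tilt reference plane-wave tilt (cycles/um, 2-vector).
#' @return An object of class `fiber_system`.
#' @export
fiber_system <- function(modes, tm = NULL, seed = 1L,
                         reference_tilt = c(0.05, 0.03)) {
  if (!inherits(modes, "mode_set")) hf_invalid("`modes` must be a mode_set")
  if (is.null(tm)) tm <- build_mm_tm(modes, seed = seed)
  if (ncol(tm$matrix) != ncol(modes$fields))
    hf_invalid("`tm` dimension does not match the mode count")
  xs <- grid_axis(modes$n, modes$pitch)
  ref <- exp(2i * pi * (outer(xs * reference_tilt[2], xs * 0, `+`) +
                        outer(xs * 0, xs * reference_tilt[1], `+`)))
  structure(list(modes = modes, tm = tm, reference = ref, seed = seed),
            class = "fiber_system")
}

#' @export
print.fiber_system <- function(x, ...) {
  cat(sprintf("<fiber_system: %d modes, grid %d x %d @ %.3g um>\n",
              ncol(x$modes$fields), x$modes$n, x$modes$n, x$modes$pitch))
  invisible(x)
}

## Mode-coefficient decomposition of an input facet field (matrix or vector).
mode_coefficients <- function(modes, field) {
  v <- as.vector(field)
  drop(crossprod(modes$fields, v)) * modes$pitch^2
}

## Output facet field (matrix) for given input facet field, through the
## ground-truth transmission matrix; optionally through a replacement tm.
system_response <- function(system, input, tm = NULL) {
  if (is.null(tm)) tm <- system$tm
  a <- mode_coefficients(system$modes, input)
  b <- drop(tm$matrix %*% a)
  matrix(system$modes$fields %*% b, system$modes$n, system$modes$n)
}

## Diffraction-limited input focus spot: Gaussian with 1/e field radius
## lambda / (pi NA), the fundamental-mode-matched spot of the fiber NA.
input_spot <- function(system, center) {
  m <- system$modes
  w0 <- (m$wavelength * 1e-3) / (pi * m$na)
  gaussian_field(m$n, m$pitch, center = center, waist = w0,
                 wavelength = m$wavelength)$amplitude
}

#' Acquire a measured transmission matrix by phase-shift interferometry
#'
#' For each input-grid focus: form the spot, transport it through the
#' ground-truth system, interfere the output with the reference beam at four
#' phase steps, demodulate, and stack the demodulated camera fields (masked
#' to the core circle) as matrix columns.  With a noiseless detector the
#' measured matrix equals the ground-truth response up to one conjugate
#' reference factor per camera pixel, which [remove_reference()] divides
#' out.
#'
#' @param system a [fiber_system()].
#' @param input_grid list with `n` (points per side) and `extent` (um): a
#'   square grid of input foci centered on the axis.
#' @param photons detector photons per unit intensity (`NULL` = noiseless).
#' @param seed detector seed.
#' @param interferometry `TRUE` (default) measures each column by four-step
#'   phase-shift interferometry against the reference beam; `FALSE` records
#'   the exact complex responses instead (ground-truth sampling, the
#'   benchmark for calibration fidelity).
#' @return An object of class `measured_tm`: list with complex `matrix`
#'   (masked camera pixels x inputs), `mask`, `mask_index`, `inputs` (input
#'   positions, um), `integrated` (per-input integrated camera intensity,
#'   for pruning), `kept_inputs` (initially all), grid metadata, and the
#'   `reference` model used.
#' @export
acquire_tm <- function(system, input_grid = list(n = 9, extent = NULL),
                       photons = NULL, seed = 1L, interferometry = TRUE) {
  m <- system$modes
  if (is.null(input_grid$extent))
    input_grid$extent <- 1.1 * m$core_diameter
  gx <- grid_axis(input_grid$n, input_grid$extent / input_grid$n)
  pts <- as.matrix(expand.grid(x = gx, y = gx))   # row-major raster, row 1 at -y
  mask <- aperture_mask(m$n, m$pitch, m$core_diameter)
  midx <- which(mask)
  ## batched transport: all input spots -> all camera responses at once
  spots <- vapply(seq_len(nrow(pts)),
                  function(p) as.vector(input_spot(system, pts[p, ])),
                  numeric(m$n^2))
  a <- crossprod(m$fields, spots) * m$pitch^2          # modes x inputs
  resp <- m$fields %*% (system$tm$matrix %*% a)        # pixels x inputs
  if (interferometry) {
    r <- as.vector(system$reference)
    phases <- c(0, pi / 2, pi, 3 * pi / 2)
    ints <- lapply(phases, function(th)
      Mod(resp + (r * exp(1i * th)))^2)                # recycled per column
    if (!is.null(photons)) {
      if (photons <= 0) hf_invalid("`photons` must be > 0")
      ints <- with_seed(seed, lapply(ints, function(I)
        matrix(stats::rpois(length(I), photons * I), nrow(I)) / photons))
    }
    dem <- ((ints[[1]] - ints[[3]]) + 1i * (ints[[2]] - ints[[4]])) / 4
  } else {
    dem <- resp
  }
  integ <- colSums(Mod(dem)^2)
  structure(list(matrix = dem[midx, , drop = FALSE], mask = mask,
                 mask_index = midx, inputs = pts, integrated = integ,
                 kept_inputs = seq_len(nrow(pts)),
                 n = m$n, pitch = m$pitch, wavelength = m$wavelength,
                 core_diameter = m$core_diameter,
                 reference = system$reference,
                 interferometry = interferometry),
            class = "measured_tm")
}

#' @export
print.measured_tm <- function(x, ...) {
  cat(sprintf("<measured_tm: %d camera pixels x %d inputs (%d kept)>\n",
              nrow(x$matrix), ncol(x$matrix), length(x$kept_inputs)))
  invisible(x)
}

#' Divide the conjugate-reference factor out of a measured TM
#'
#' Phase-shift demodulation returns `S * Conj(R)` per pixel; dividing by
#' `Conj(R)` (the reference is calibrated once, independent of the inputs)
#' recovers the bare response `S`.
#'
#' @param mtm a [acquire_tm()] `measured_tm`.
#' @return the corrected `measured_tm`.
#' @export
remove_reference <- function(mtm) {
  if (isFALSE(mtm$interferometry)) return(mtm)   # nothing to remove
  r <- Conj(mtm$reference[mtm$mask_index])
  mtm$matrix <- mtm$matrix / r
  mtm
}

#' Prune input modes by integrated output intensity
#'
#' Keeps the inputs whose integrated camera intensity reaches at least
#' `threshold_fraction` of the maximum: inputs falling outside the spatial
#' constraints of the fiber deliver almost no power and are eliminated
#' before calibration.
#'
#' @param integrated per-input integrated intensity (numeric vector), or a
#'   `measured_tm` (its `integrated` field is used and `kept_inputs`
#'   updated).
#' @param threshold_fraction keep threshold in `(0, 1)`.
#' @return index vector of kept inputs (or the updated `measured_tm`).
#' @export
prune_inputs <- function(integrated, threshold_fraction = 0.1) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    hf_invalid("`threshold_fraction` must lie in (0, 1)")
  if (inherits(integrated, "measured_tm")) {
    mtm <- integrated
    keep <- prune_inputs(mtm$integrated, threshold_fraction)
    mtm$kept_inputs <- keep
    return(mtm)
  }
  if (all(integrated == 0)) {
    warning("all-zero intensity map: no inputs kept")
    return(integer())
  }
  which(integrated >= threshold_fraction * max(integrated))
}

#' Focus quality metrics
#'
#' @param intensity nonnegative matrix: output intensity on the camera grid.
#' @param pitch grid pitch (um).
#' @param target focus position `(x, y)` (um).
#' @param disk_radius radius of the focus disk for the power ratio (um).
#' @param mask logical matrix restricting the field of view (default: all).
#' @return An object of class `focus_metrics`: list with `power_ratio`
#'   (power inside the disk / total masked power), `enhancement` (peak
#'   intensity / mean masked intensity), `fwhm` (um, radial interpolation)
#'   and `peak` (peak intensity).
#' @export
focus_metrics <- function(intensity, pitch, target = c(0, 0),
                          disk_radius, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(intensity), ncol(intensity))
  xs <- grid_axis(ncol(intensity), pitch)
  ys <- grid_axis(nrow(intensity), pitch)
  r2 <- outer((ys - target[2])^2, (xs - target[1])^2, `+`)
  disk <- r2 < disk_radius^2 & mask
  tot <- sum(intensity[mask])
  pr <- if (tot > 0) sum(intensity[disk]) / tot else 0
  enh <- if (tot > 0) max(intensity[mask]) / mean(intensity[mask]) else 0
  fw <- radial_fwhm(intensity, pitch, center = target)
  structure(list(power_ratio = pr, enhancement = enh, fwhm = fw,
                 peak = max(intensity[mask])),
            class = "focus_metrics")
}

#' Synthesize a phase-conjugate focus from a measured TM
#'
#' The input that focuses on output pixel `target_index` is the normalized
#' conjugate of the corresponding TM row (matched filter), optionally
#' reduced to unit-amplitude conjugate phases (`phase_only`).  The input
#' field is replayed through the ground-truth system and the resulting
#' output intensity is scored with [focus_metrics()].
#'
#' @param mtm a `measured_tm` (rows indexed over masked camera pixels).
#' @param target_index index into the masked camera pixels (see
#'   `mtm$mask_index`), or a `(x, y)` position (um) resolved to the nearest
#'   masked pixel.
#' @param system the [fiber_system()] used for replay.
#' @param phase_only use unit-amplitude conjugate phases.
#' @param disk_radius focus disk radius (um); default twice the diffraction
#'   limit `0.51 lambda / NA`.
#' @return list with `input` (complex input facet field), `intensity`
#'   (camera intensity matrix), `metrics` ([focus_metrics()]) and `target`
#'   (um position).
#' @export
synthesize_focus <- function(mtm, target_index, system, phase_only = FALSE,
                             disk_radius = NULL) {
  m <- system$modes
  if (length(target_index) == 2L && !is.integer(target_index)) {
    xs <- grid_axis(m$n, m$pitch)
    pos <- as.matrix(expand.grid(y = xs, x = xs))[mtm$mask_index, c(2, 1)]
    d2 <- (pos[, 1] - target_index[1])^2 + (pos[, 2] - target_index[2])^2
    target_index <- which.min(d2)
  }
  if (target_index < 1 || target_index > nrow(mtm$matrix))
    hf_invalid("`target_index` lies outside the core mask")
  row <- mtm$matrix[target_index, mtm$kept_inputs]
  v <- Conj(row)
  if (phase_only) v <- exp(1i * Arg(v))
  v[!is.finite(v)] <- 0 + 0i
  ## assemble the input facet field from the input focus spots
  input <- matrix(0 + 0i, m$n, m$n)
  for (j in seq_along(v)) {
    if (v[j] == 0) next
    input <- input + v[j] * input_spot(system, mtm$inputs[mtm$kept_inputs[j], ])
  }
  p <- sum(Mod(input)^2) * m$pitch^2
  if (p == 0) hf_invalid("degenerate (all-zero) matched filter")
  input <- input / sqrt(p)
  out <- system_response(system, input)
  intensity <- Mod(out)^2
  ## target position on the camera
  xs <- grid_axis(m$n, m$pitch)
  ij <- arrayInd(mtm$mask_index[target_index], c(m$n, m$n))
  tpos <- c(xs[ij[2]], xs[ij[1]])
  if (is.null(disk_radius))
    disk_radius <- 2 * 0.51 * (m$wavelength * 1e-3) / m$na
  met <- focus_metrics(intensity, m$pitch, target = tpos,
                       disk_radius = disk_radius, mask = mtm$mask)
  list(input = input, intensity = intensity, metrics = met, target = tpos)
}
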