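## Ground-truth light transport: multimode-regime transmission matrices,
## multicore-regime per-corelet channels, deformation operators, and the
## two-fiber mating model with rotational alignment.

#' Transmission matrix container
#'
#' @param matrix complex matrix (outputs x inputs).
#' @param regime `"multimode"` or `"multicore"`.
#' @param input_basis,output_basis free-form basis metadata.
#' @param seed seed used to draw the matrix.
#' @return an object of class `transmission_matrix`.
#' @export
transmission_matrix <- function(matrix, regime = c("multimode", "multicore"),
                                input_basis = NULL, output_basis = NULL,
                                seed = NA_integer_) {
  regime <- match.arg(regime)
  structure(list(matrix = matrix, regime = regime,
                 input_basis = input_basis, output_basis = output_basis,
                 seed = seed),
            class = "transmission_matrix")
}

#' @export
print.transmission_matrix <- function(x, ...) {
  cat(sprintf("<transmission_matrix %s, %d x %d, seed %s>\n", x$regime,
              nrow(x$matrix), ncol(x$matrix), format(x$seed)))
  invisible(x)
}

## Seeded GUE draw: Hermitian, entries CN(0, 1/n) off-diagonal.
rgue <- function(n, seed) {
  with_seed(seed, {
    g <- matrix(complex(real = stats::rnorm(n * n),
                        imaginary = stats::rnorm(n * n)), n, n) / sqrt(2)
    (g + Conj(t(g))) / (2 * sqrt(n))
  })
}

## One-parameter seeded unitary family U(t) = exp(i t S H), H a seeded GUE
## matrix (Haar-distributed eigenvectors), spectrum in ~[-1, 1].  `scale`
## sets how many radians of modal phase one unit of t applies; with
## scale = pi * sqrt(n) the t = 1 member winds phases over many cycles and
## is Haar-like, while small t stays near the identity.
interp_unitary <- function(n, t, seed, scale = pi * sqrt(n)) {
  h <- rgue(n, seed)
  e <- eigen(h, symmetric = TRUE)
  v <- e$vectors
  v %*% (exp(1i * t * scale * e$values) * Conj(t(v)))
}

#' Ground-truth multimode transmission matrix
#'
#' Builds the lossless idealization `T = U(coupling, seed) %*%
#' diag(exp(i beta_m L))`: deterministic modal phase accumulation over the
#' fiber length composed with a seeded random unitary that interpolates from
#' the identity (`coupling = 0`) to Haar-like mode mixing (`coupling = 1`).
#'
#' @param modes a [solve_lp_modes()] mode set (orthonormal).
#' @param length fiber length (um).
#' @param seed integer seed.
#' @param coupling mode-coupling strength in `[0, 1]`.
#' @return a unitary `transmission_matrix` in the mode basis
#'   (regime `"multimode"`).
#' @export
build_mm_tm <- function(modes, length = 1e5, seed = 1L, coupling = 1) {
  if (!inherits(modes, "mode_set")) hf_invalid("`modes` must be a mode_set")
  n <- ncol(modes$fields)
  if (n == 0) hf_invalid("empty mode set")
  if (!is.numeric(coupling) || coupling < 0 || coupling > 1)
    hf_invalid("`coupling` must lie in [0, 1]")
  phases <- exp(1i * modes$beta_offset * length)
  u <- if (coupling == 0) diag(n) else interp_unitary(n, coupling, seed)
  m <- u * rep(phases, each = n)        # U %*% diag(phases)
  transmission_matrix(m, "multimode", input_basis = "lp_modes",
                      output_basis = "lp_modes", seed = seed)
}

#' Ground-truth multicore transmission matrix
#'
#' In the multicore regime light is transported corelet-to-corelet with no
#' crosstalk: the matrix is diagonal over the corelet channels with seeded
#' uniform phases and unit moduli.
#'
#' @param lattice a [hex_lattice()] corelet lattice.
#' @param seed integer seed.
#' @return a diagonal `transmission_matrix` (regime `"multicore"`), one
#'   channel per corelet, ordered by `spiral_rank`.
#' @export
build_mc_tm <- function(lattice, seed = 1L) {
  if (!inherits(lattice, "corelet_lattice"))
    hf_invalid("`lattice` must be a corelet_lattice")
  n <- nrow(lattice)
  phases <- with_seed(seed, stats::runif(n, 0, 2 * pi))
  transmission_matrix(diag(exp(1i * phases)), "multicore",
                      input_basis = "corelets", output_basis = "corelets",
                      seed = seed)
}

#' Deformation state
#'
#' @param strength dimensionless deformation strength (>= 0); `0` means no
#'   deformation.  In the multimode regime a strength of 1 applies O(1) rad
#'   of random modal phase mixing.
#' @param seed integer seed.
#' @return an object of class `deformation_state`.
#' @export
deformation_state <- function(strength = 0, seed = 1L) {
  if (!is.numeric(strength) || length(strength) != 1L || strength < 0)
    hf_invalid("`strength` must be a single number >= 0")
  structure(list(strength = strength, seed = seed),
            class = "deformation_state")
}

#' Apply fiber deformation to a transmission matrix
#'
#' Multimode regime: right-multiplication by a seeded random unitary whose
#' distance from the identity grows with `strength` (the matrix stays
#' unitary; focusing solutions computed before the deformation degrade).
#' Multicore regime: a diagonal phase perturbation only, so per-channel
#' power is exactly preserved -- the deformation-resilience contract of the
#' corelet channels.
#'
#' @param tm a `transmission_matrix`.
#' @param state a [deformation_state()].
#' @return the deformed `transmission_matrix`.
#' @export
apply_deformation <- function(tm, state) {
  if (!inherits(tm, "transmission_matrix"))
    hf_invalid("`tm` must be a transmission_matrix")
  if (!inherits(state, "deformation_state"))
    hf_invalid("`state` must be a deformation_state")
  if (state$strength == 0) return(tm)
  n <- ncol(tm$matrix)
  if (tm$regime == "multicore") {
    dphi <- with_seed(state$seed, stats::runif(n, -pi, pi))
    tm$matrix <- tm$matrix * rep(exp(1i * state$strength * dphi), each = nrow(tm$matrix))
  } else {
    ## scale = 1: strength is approximately the rms modal phase (rad)
    u <- interp_unitary(n, state$strength, state$seed, scale = 1)
    tm$matrix <- tm$matrix %*% u
  }
  tm
}

#' Mating state of two fiber ferrules
#'
#' @param lateral_offset 2-vector lateral misalignment (um); its norm is
#'   bounded by the ferrule bore clearance.
#' @param rotation relative ferrule rotation (degrees, reduced to
#'   `[0, 360)`).
#' @param axial_gap end-face gap (um); the default 0.5 um reflects that two
#'   ferrule-flush end-faces are never perfectly flush.
#' @param bore_clearance maximum admissible `|lateral_offset|` (um).
#' @return an object of class `mating_state`.
#' @export
mating_state <- function(lateral_offset = c(0, 0), rotation = 0,
                         axial_gap = 0.5, bore_clearance = 3) {
  if (length(lateral_offset) != 2L || !is.numeric(lateral_offset))
    hf_invalid("`lateral_offset` must be a numeric 2-vector")
  if (sqrt(sum(lateral_offset^2)) > bore_clearance + 1e-12)
    hf_invalid("`lateral_offset` exceeds the bore clearance")
  if (axial_gap < 0) hf_invalid("`axial_gap` must be >= 0")
  structure(list(lateral_offset = as.numeric(lateral_offset),
                 rotation = rotation %% 360, axial_gap = axial_gap,
                 bore_clearance = bore_clearance),
            class = "mating_state")
}

## Rotate 2-column coordinates by `deg` degrees counter-clockwise.
rotate_xy <- function(xy, deg) {
  th <- deg * pi / 180
  cbind(cos(th) * xy[, 1] - sin(th) * xy[, 2],
        sin(th) * xy[, 1] + cos(th) * xy[, 2])
}

## Corelet-to-corelet coupling matrix C (fiber 2 rows x fiber 1 columns).
## Fiber-1 mode positions are rotated and offset; the axial gap is crossed
## with the angular-spectrum propagator applied to the (shared) prototype
## corelet mode; each entry is a discrete overlap integral evaluated on a
## local grid.  Entries below `trunc` in magnitude are set to zero, and only
## site pairs within a displacement cutoff are evaluated at all.
mating_coupling <- function(lattice, spec, state, n = 96, trunc = 1e-4,
                            lattice2 = lattice) {
  cm <- corelet_mode(spec)
  w <- cm$waist
  ## displacement beyond which |overlap| = exp(-d^2 / (4 w^2)) < trunc / 10
  cutoff <- 2 * w * sqrt(log(10 / trunc))
  pitch_g <- 8 * w / n * 2
  p1 <- rotate_xy(cbind(lattice$x, lattice$y), state$rotation)
  p1 <- sweep(p1, 2, -state$lateral_offset)    # adds the offset
  p2 <- cbind(lattice2$x, lattice2$y)
  ## prototype fiber-1 mode after crossing the gap, centered on its axis
  proto <- gaussian_mode_field(corelet_mode(spec), n, pitch_g)
  if (state$axial_gap > 0) proto <- propagate(proto, state$axial_gap)
  nc <- nrow(lattice)
  cmat <- matrix(0 + 0i, nc, nc)
  for (k in seq_len(nc)) {
    d2 <- (p2[, 1] - p1[k, 1])^2 + (p2[, 2] - p1[k, 2])^2
    for (j in which(d2 < cutoff^2)) {
      ## fiber-2 mode j relative to the (propagated) fiber-1 mode k
      g2 <- gaussian_field(n, pitch_g,
                           center = c(p2[j, 1] - p1[k, 1],
                                      p2[j, 2] - p1[k, 2]),
                           waist = w, wavelength = spec$wavelength)
      cmat[j, k] <- overlap(g2, proto)
    }
  }
  cmat[Mod(cmat) < trunc] <- 0 + 0i
  cmat
}

#' Mate two multicore fibers
#'
#' Composite transport of a reconnected fiber pair:
#' `T = tm2 %*% C(state) %*% tm1`, where `C` couples each corelet mode of
#' fiber 1 (after lateral offset, rotation and axial-gap propagation) into
#' the corelet modes of fiber 2 by overlap integrals.
#'
#' @param tm1,tm2 multicore `transmission_matrix` objects over `lattice`.
#' @param lattice the [hex_lattice()] of fiber 1.
#' @param spec the [fiber_spec()] (corelet mode model).
#' @param state a [mating_state()].
#' @param lattice2 lattice of fiber 2 (default: same as fiber 1); a
#'   pre-rotated copy emulates a physically rotated second ferrule.
#' @return a `transmission_matrix` (regime `"multicore"`) for the mated
#'   pair, with the coupling matrix in attribute `"coupling"`.
#' @export
mate_fibers <- function(tm1, tm2, lattice, spec, state = mating_state(),
                        lattice2 = lattice) {
  for (tm in list(tm1, tm2))
    if (!inherits(tm, "transmission_matrix") || tm$regime != "multicore")
      hf_invalid("`tm1` and `tm2` must be multicore transmission matrices")
  if (ncol(tm1$matrix) != nrow(lattice) || ncol(tm2$matrix) != nrow(lattice))
    hf_invalid("transmission matrices and lattice disagree in size")
  cmat <- mating_coupling(lattice, spec, state, lattice2 = lattice2)
  out <- transmission_matrix(tm2$matrix %*% cmat %*% tm1$matrix, "multicore",
                             input_basis = "corelets",
                             output_basis = "corelets", seed = tm1$seed)
  attr(out, "coupling") <- cmat
  out
}

#' Per-corelet output power fractions
#'
#' For unit power launched into corelet `j`, the fraction of the launched
#' power that arrives inside corelet `j`'s addressing disk (radius half the
#' corelet pitch) on the output facet.  Light lost at a mating interface or
#' redirected into other corelets lowers the fraction; for an ideal single
#' fiber every fraction is close to 1 (bounded only by the Gaussian-tail
#' power outside the disk).
#'
#' @param tm a multicore `transmission_matrix` (single fiber or mated pair).
#' @param lattice the [hex_lattice()].
#' @param spec the [fiber_spec()].
#' @param disk_radius integration disk radius (um); default
#'   `corelet_pitch / 2`.
#' @param n local integration grid size.
#' @return list with `fraction` (per-corelet, spiral order) and `mean`.
#' @export
corelet_power_fractions <- function(tm, lattice, spec,
                                    disk_radius = NULL, n = 64) {
  if (!inherits(tm, "transmission_matrix") || tm$regime != "multicore")
    hf_invalid("`tm` must be a multicore transmission_matrix")
  if (is.null(disk_radius)) disk_radius <- spec$corelet_pitch / 2
  w <- corelet_mode(spec)$waist
  pos <- cbind(lattice$x, lattice$y)
  nc <- nrow(lattice)
  pitch_g <- 2 * disk_radius / n * 1.1
  xs <- grid_axis(n, pitch_g)
  rr2 <- outer(xs^2, xs^2, `+`)
  disk <- rr2 < disk_radius^2
  frac <- numeric(nc)
  for (j in seq_len(nc)) {
    cvec <- tm$matrix[, j]
    ## output field on a local window centered on corelet j
    fld <- matrix(0 + 0i, n, n)
    contrib <- which(Mod(cvec) > 1e-8)
    for (k in contrib) {
      d <- pos[k, ] - pos[j, ]
      if (sqrt(sum(d^2)) > disk_radius + 6 * w) next
      g <- gaussian_field(n, pitch_g, center = d, waist = w,
                          wavelength = spec$wavelength)
      fld <- fld + cvec[k] * g$amplitude
    }
    frac[j] <- sum(Mod(fld[disk])^2) * pitch_g^2    # launched power is 1
  }
  list(fraction = frac, mean = mean(frac))
}

#' Rotational alignment search for fiber mating
#'
#' Emulates rotating the first ferrule until light couples into all corelets
#' of the second fiber: a coarse scan of the total coupled power over one
#' 60-degree symmetry sector followed by golden-section refinement.
#'
#' @param tm1,tm2 multicore `transmission_matrix` objects.
#' @param lattice the [hex_lattice()].
#' @param spec the [fiber_spec()].
#' @param offset lateral offset (um, 2-vector) held fixed during the search.
#' @param gap axial gap (um).
#' @param step coarse scan step (degrees).
#' @param objective function(coupling_matrix) -> scalar to maximize; the
#'   default is the total coupled power `sum(|C|^2)`.
#' @param lattice2 lattice of fiber 2 (a rotated copy emulates the unknown
#'   true ferrule rotation the search has to recover).
#' @return list with `angle` (degrees, modulo 60), `objective` at the
#'   optimum, and `trace` (data frame of the coarse scan).
#' @export
rotation_search <- function(tm1, tm2, lattice, spec, offset = c(0, 0),
                            gap = 0.5, step = 0.5, objective = NULL,
                            lattice2 = lattice) {
  if (is.null(objective)) objective <- function(cmat) sum(Mod(cmat)^2)
  eval_angle <- function(theta) {
    st <- mating_state(lateral_offset = offset, rotation = theta,
                       axial_gap = gap)
    objective(mating_coupling(lattice, spec, st, lattice2 = lattice2))
  }
  angles <- seq(0, 60 - step, by = step)
  vals <- vapply(angles, eval_angle, numeric(1))
  if (max(vals) <= 0)
    hf_stop("flat objective: no corelets couple at any rotation",
            "holofiber_search_failure")
  i <- which.max(vals)
  ## bracket one coarse step either side; angles wrap through mating_state
  lo <- angles[i] - step
  hi <- angles[i] + step
  opt <- stats::optimize(eval_angle, c(lo, hi), maximum = TRUE,
                         tol = 1e-4)
  list(angle = opt$maximum %% 60, objective = opt$objective,
       trace = data.frame(angle = angles, objective = vals))
}

#' Marker-image similarity score
#'
#' Zero-normalized cross-correlation at zero lag between two images of the
#' ferrule marker region: 1 for identical images up to an affine intensity
#' change, near 0 for unrelated images.  Used to verify that a reconnection
#' reproduces the initially recorded ferrule orientation.
#'
#' @param image_a,image_b equal-shape numeric matrices with non-zero
#'   variance.
#' @return similarity score in `[-1, 1]`.
#' @export
marker_similarity <- function(image_a, image_b) {
  if (!is.matrix(image_a) || !is.matrix(image_b) ||
      !identical(dim(image_a), dim(image_b)))
    hf_invalid("`image_a` and `image_b` must be matrices of equal shape")
  zncc(image_a, image_b)
}
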