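## Fiber geometry: specifications, the hexagonal corelet lattice and its
## spiral addressing order, aperture masks, and mode-count estimates.
##
## Length convention: all transverse lengths are in micrometers (um),
## wavelengths in nanometers (nm) at the user-facing surface.  Coordinates are
## axis-centered, x right / y up; grids are indexed row-major with row 1 at
## the most negative y.

#' Fiber specification
#'
#' Describes a (possibly hybrid) fiber: a step-index multimode waveguide of
#' given pulp diameter and NA, optionally carrying a centered hexagonal
#' lattice of single-mode corelets.
#'
#' @param cladding_diameter outer cladding diameter (um).
#' @param pulp_diameter diameter of the inner region acting as the multimode
#'   core (um); must be smaller than `cladding_diameter`.
#' @param na_multimode numerical aperture of the multimode waveguide.
#' @param corelet_rings number of hexagonal corelet rings around the axis
#'   (`0` = a single on-axis corelet).
#' @param corelet_pitch center-to-center corelet spacing (um).
#' @param corelet_core_diameter corelet core diameter (um).
#' @param corelet_na corelet numerical aperture.
#' @param wavelength operating wavelength (nm).
#' @param label free-text identifier.
#'
#' @return An object of class `fiber_spec`.
#' @export
#' @examples
#' fiber_preset("m3cf")
fiber_spec <- function(cladding_diameter, pulp_diameter, na_multimode,
                       corelet_rings = 0L, corelet_pitch = 25,
                       corelet_core_diameter = 2, corelet_na = 0.13,
                       wavelength = 488, label = "custom") {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      hf_invalid(sprintf("`%s` must be a single finite number", nm))
    x
  }
  for (nm in c("cladding_diameter", "pulp_diameter", "corelet_pitch",
               "corelet_core_diameter", "wavelength"))
    if (num1(get(nm), nm) <= 0) hf_invalid(sprintf("`%s` must be > 0", nm))
  for (nm in c("na_multimode", "corelet_na")) {
    v <- num1(get(nm), nm)
    if (v <= 0 || v >= 1) hf_invalid(sprintf("`%s` must lie in (0, 1)", nm))
  }
  if (pulp_diameter >= cladding_diameter)
    hf_invalid("`pulp_diameter` must be smaller than `cladding_diameter`")
  corelet_rings <- as.integer(num1(corelet_rings, "corelet_rings"))
  if (corelet_rings < 0) hf_invalid("`corelet_rings` must be >= 0")
  lattice_extent <- corelet_rings * corelet_pitch + corelet_core_diameter / 2
  if (lattice_extent > pulp_diameter / 2)
    hf_invalid("corelet lattice (pitch x rings) does not fit inside the pulp")
  structure(list(cladding_diameter = cladding_diameter,
                 pulp_diameter = pulp_diameter,
                 na_multimode = na_multimode,
                 corelet_rings = corelet_rings,
                 corelet_pitch = corelet_pitch,
                 corelet_core_diameter = corelet_core_diameter,
                 corelet_na = corelet_na,
                 wavelength = wavelength,
                 label = label),
            class = "fiber_spec")
}

#' @export
print.fiber_spec <- function(x, ...) {
  cat(sprintf("<fiber_spec '%s'>\n", x$label))
  cat(sprintf("  cladding / pulp: %g / %g um, NA %g, lambda %g nm\n",
              x$cladding_diameter, x$pulp_diameter, x$na_multimode,
              x$wavelength))
  cat(sprintf("  corelets: %d rings (n = %d), pitch %g um, core %g um, NA %g\n",
              x$corelet_rings, hex_count(x$corelet_rings), x$corelet_pitch,
              x$corelet_core_diameter, x$corelet_na))
  invisible(x)
}

#' Shipped fiber presets
#'
#' Three presets cover the fibers studied: `"m3cf"`, the 61-corelet hybrid
#' multimode-multicore fiber (278 um cladding, 232 um pulp, NA 0.1);
#' `"gi_na029"`, a 100 um core / NA 0.29 comparison fiber; and
#' `"dcf_na020"`, a double-clad fiber with a 9 um single-mode core inside a
#' 105 um / NA 0.20 multimode inner cladding.
#'
#' The corelet pitch, core diameter and NA of the `m3cf` preset are design
#' defaults (25 um / 2 um / 0.13): they fit four rings inside the 232 um pulp
#' with margin and keep each corelet single-mode at 488 nm.
#'
#' @param name preset name.
#' @return A [fiber_spec()].
#' @export
#' @examples
#' fiber_preset("gi_na029")
fiber_preset <- function(name = c("m3cf", "gi_na029", "dcf_na020")) {
  name <- match.arg(name)
  switch(name,
    m3cf = fiber_spec(278, 232, 0.1, corelet_rings = 4L, corelet_pitch = 25,
                      corelet_core_diameter = 2, corelet_na = 0.13,
                      wavelength = 488, label = "m3cf"),
    gi_na029 = fiber_spec(125, 100, 0.29, corelet_rings = 0L,
                          corelet_core_diameter = 2, corelet_na = 0.13,
                          wavelength = 488, label = "gi_na029"),
    dcf_na020 = fiber_spec(125, 105, 0.20, corelet_rings = 0L,
                           corelet_core_diameter = 9, corelet_na = 0.04,
                           wavelength = 488, label = "dcf_na020"))
}

hex_count <- function(rings) as.integer(3 * rings * (rings + 1) + 1)

#' Centered hexagonal corelet lattice
#'
#' Generates the positions of a centered hexagonal lattice of `rings` rings at
#' the given pitch.  One lattice axis is aligned with +x.  The number of
#' positions is the centered-hexagonal number `3 r (r + 1) + 1`.
#'
#' @param rings number of rings (>= 0).
#' @param pitch nearest-neighbor spacing (um).
#' @return An object of class `corelet_lattice`: a data frame with columns
#'   `x`, `y` (um), `ring` and `spiral_rank` (filled by [spiral_order()],
#'   which is applied by default).
#' @export
#' @examples
#' lat <- hex_lattice(4, 25)   # the 61-corelet layout
#' nrow(lat)
hex_lattice <- function(rings, pitch) {
  if (!is.numeric(rings) || length(rings) != 1L || !is.finite(rings) ||
      rings < 0 || rings != round(rings))
    hf_invalid("`rings` must be a non-negative integer")
  if (!is.numeric(pitch) || length(pitch) != 1L || !is.finite(pitch) ||
      pitch <= 0)
    hf_invalid("`pitch` must be > 0")
  rings <- as.integer(rings)
  ## axial coordinates: a1 = (1, 0), a2 = (1/2, sqrt(3)/2); hex distance
  ## max(|i|, |j|, |i + j|) <= rings enumerates the centered hexagon.
  ij <- expand.grid(i = -rings:rings, j = -rings:rings)
  ring <- pmax(abs(ij$i), abs(ij$j), abs(ij$i + ij$j))
  keep <- ring <= rings
  ij <- ij[keep, , drop = FALSE]
  ring <- ring[keep]
  lat <- data.frame(x = pitch * (ij$i + ij$j / 2),
                    y = pitch * ij$j * sqrt(3) / 2,
                    ring = as.integer(ring),
                    spiral_rank = NA_integer_)
  class(lat) <- c("corelet_lattice", "data.frame")
  spiral_order(lat)
}

#' Spiral addressing order over a corelet lattice
#'
#' Assigns `spiral_rank`: rank 0 at the center, then ring by ring outward;
#' within a ring the walk starts at the site with the smallest non-negative
#' angle from +x and proceeds counter-clockwise, so consecutive same-ring
#' ranks are nearest neighbors (one pitch apart).
#'
#' @param lattice a `corelet_lattice` with complete rings.
#' @return The lattice with `spiral_rank` filled (a bijection onto
#'   `0 .. n - 1`), rows sorted by rank.
#' @export
spiral_order <- function(lattice) {
  if (!inherits(lattice, "corelet_lattice"))
    hf_invalid("`lattice` must be a corelet_lattice")
  rings <- max(lattice$ring)
  counts <- tabulate(lattice$ring + 1L, nbins = rings + 1L)
  expected <- c(1L, 6L * seq_len(rings))
  if (length(counts) != length(expected) || any(counts != expected))
    hf_stop("lattice does not consist of complete hexagonal rings",
            "holofiber_unsupported_layout")
  ang <- atan2(lattice$y, lattice$x) %% (2 * pi)
  ang[abs(ang - 2 * pi) < 1e-12] <- 0
  ord <- order(lattice$ring, ang)
  out <- lattice[ord, , drop = FALSE]
  out$spiral_rank <- seq_len(nrow(out)) - 1L
  rownames(out) <- NULL
  class(out) <- c("corelet_lattice", "data.frame")
  out
}

#' Circular aperture mask on a centered grid
#'
#' Marks the grid points whose centers lie strictly inside a circle of the
#' given diameter centered on the fiber axis.  Strict inequality on point
#' centers makes the count reproducible with no area weighting.
#'
#' @param grid_shape integer pair `(nrow, ncol)` (a scalar is squared).
#' @param pitch grid pitch (um).
#' @param diameter circle diameter (um); `0` gives an empty mask.
#' @return A logical matrix of dimension `grid_shape` with attribute `count`
#'   (number of `TRUE` cells).
#' @export
#' @examples
#' m <- aperture_mask(c(352, 352), 0.7, 232)
#' attr(m, "count")   # ~87000 scan points inside the pulp circle
aperture_mask <- function(grid_shape, pitch, diameter) {
  if (length(grid_shape) == 1L) grid_shape <- c(grid_shape, grid_shape)
  if (!is.numeric(grid_shape) || length(grid_shape) != 2L ||
      any(grid_shape < 1) || any(grid_shape != round(grid_shape)))
    hf_invalid("`grid_shape` must be one or two positive integers")
  if (!is.numeric(pitch) || pitch <= 0) hf_invalid("`pitch` must be > 0")
  if (!is.numeric(diameter) || diameter < 0)
    hf_invalid("`diameter` must be >= 0")
  y <- grid_axis(grid_shape[1], pitch)
  x <- grid_axis(grid_shape[2], pitch)
  mask <- outer(y^2, x^2, `+`) < (diameter / 2)^2
  attr(mask, "count") <- sum(mask)
  mask
}

#' Normalized frequency (V-number) of a step-index waveguide
#'
#' `V = pi * d * NA / lambda` with the core diameter `d` in um and the
#' wavelength in nm.
#'
#' @param core_diameter core diameter (um).
#' @param na numerical aperture.
#' @param wavelength wavelength (nm).
#' @return V (dimensionless).
#' @export
#' @examples
#' v_number(232, 0.1, 488)    # the multimode pulp: V ~ 149
v_number <- function(core_diameter, na, wavelength) {
  ok <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
  if (!ok(core_diameter) || !ok(na) || !ok(wavelength))
    hf_invalid("all arguments of v_number() must be single positive numbers")
  pi * core_diameter * na / (wavelength * 1e-3)
}

#' Guided-mode capacity estimate of the multimode waveguide
#'
#' Large-V estimate `round(polarizations * V^2 / 4)` for the step-index
#' multimode waveguide defined by the pulp diameter and multimode NA.
#'
#' @param spec a [fiber_spec()].
#' @param polarizations `1` (scalar modes) or `2` (both polarizations).
#' @return integer mode count estimate.
#' @export
#' @examples
#' estimate_mode_count(fiber_preset("m3cf"), polarizations = 2)
estimate_mode_count <- function(spec, polarizations = 2L) {
  if (!inherits(spec, "fiber_spec")) hf_invalid("`spec` must be a fiber_spec")
  if (!polarizations %in% c(1L, 2L))
    hf_invalid("`polarizations` must be 1 or 2")
  v <- v_number(spec$pulp_diameter, spec$na_multimode, spec$wavelength)
  as.integer(round(polarizations * v^2 / 4))
}
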