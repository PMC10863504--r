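## Seeded synthetic phantoms: fluorescent beads, Purkinje-like somata layers
## with dendrites, and dark vessels.  A phantom is a 2-D fluorophore density
## map at the working-distance plane; labels record every placed object so
## ground truth can be reconstructed in tests.

new_phantom <- function(density, pitch, labels, seed, kind) {
  structure(list(density = density, pitch = pitch, labels = labels,
                 seed = seed, kind = kind),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom '%s' %d x %d @ %g um, %d objects, seed %s>\n",
              x$kind, nrow(x$density), ncol(x$density), x$pitch,
              nrow(x$labels), format(x$seed)))
  invisible(x)
}

phantom_grid <- function(field_diameter, pitch) {
  n <- ceiling(field_diameter / pitch)
  if (n %% 2 == 1) n <- n + 1
  n
}

#' Fluorescent bead phantom
#'
#' `n` non-overlapping uniform disks of the given diameter, centers drawn
#' uniformly in the field circle by rejection sampling.
#'
#' @param n number of beads (>= 0).
#' @param diameter bead diameter (um); 6 um models the reference beads.
#' @param field_diameter field-of-view diameter (um).
#' @param pitch grid pitch (um).
#' @param seed integer seed.
#' @param max_tries rejection-sampling budget per bead.
#' @return a `phantom`; `labels` has one row per bead (`kind`, `x`, `y`,
#'   `size`).
#' @export
#' @examples
#' ph <- make_bead_phantom(10, seed = 1, pitch = 1.4)
#' nrow(ph$labels)
make_bead_phantom <- function(n, diameter = 6, field_diameter = 230,
                              pitch = 0.7, seed = 1L, max_tries = 2000L) {
  if (n < 0 || n != round(n)) hf_invalid("`n` must be a non-negative integer")
  if (diameter <= 0 || diameter > field_diameter)
    hf_invalid("beads must fit in the field")
  ng <- phantom_grid(field_diameter, pitch)
  dens <- matrix(0, ng, ng)
  centers <- matrix(numeric(0), 0, 2)
  rmax <- field_diameter / 2 - diameter / 2
  with_seed(seed, {
    for (i in seq_len(n)) {
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        c0 <- stats::runif(2, -rmax, rmax)
        if (sum(c0^2) > rmax^2) next
        if (nrow(centers) > 0 &&
            min((centers[, 1] - c0[1])^2 + (centers[, 2] - c0[2])^2) <
              diameter^2) next
        centers <- rbind(centers, c0)
        placed <- TRUE
        break
      }
      if (!placed)
        hf_stop(sprintf("could not place bead %d of %d without overlap", i, n),
                "holofiber_packing_failure")
    }
  })
  xs <- grid_axis(ng, pitch)
  for (i in seq_len(nrow(centers))) {
    dens <- dens + (outer((xs - centers[i, 2])^2, (xs - centers[i, 1])^2,
                          `+`) < (diameter / 2)^2)
  }
  labels <- data.frame(kind = rep("bead", nrow(centers)),
                       x = centers[, 1], y = centers[, 2],
                       size = rep(diameter, nrow(centers)))
  new_phantom(dens, pitch, labels, seed, "beads")
}

## Soft-edged disk: 1 inside (radius - edge), cosine roll-off over `edge`.
soft_disk <- function(r2, radius, edge) {
  r <- sqrt(r2)
  v <- numeric(length(r))
  v[r <= radius - edge] <- 1
  tr <- r > radius - edge & r < radius
  v[tr] <- 0.5 * (1 + cos(pi * (r[tr] - radius + edge) / edge))
  v
}

## Distance from grid points to a segment p0-p1.
seg_dist <- function(px, py, p0, p1) {
  vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]
  l2 <- vx^2 + vy^2
  t <- pmin(pmax(((px - p0[1]) * vx + (py - p0[2]) * vy) / l2, 0), 1)
  sqrt((px - (p0[1] + t * vx))^2 + (py - (p0[2] + t * vy))^2)
}

#' Purkinje-layer tissue phantom
#'
#' Emulates a single layer of large somata within diffusely labeled tissue:
#' soft-edged somata (diameters drawn in `soma_diameter_range`) centered on
#' a layer curve with jitter, optional thin dendrite processes extending
#' perpendicular to the layer, and dark vessels -- zero-density ribbons
#' multiplying a diffuse background (default 5% of soma density, so vessel
#' contrast is testable).
#'
#' @param n_somata number of somata.
#' @param soma_diameter_range 2-vector (um); diameters drawn uniformly.
#' @param layer layer curve: list with `amplitude` and `period` (um) of a
#'   horizontal sinusoid `y = amplitude * sin(2 pi x / period)`.
#' @param dendrites add dendrite segments (1.5 um wide) perpendicular to
#'   the layer.
#' @param vessels number of dark vessel ribbons.
#' @param background diffuse background density (fraction of soma density).
#' @param field_diameter,pitch field geometry (um).
#' @param seed integer seed.
#' @return a `phantom`; labels record every soma, dendrite and vessel.
#' @export
make_purkinje_phantom <- function(n_somata = 8,
                                  soma_diameter_range = c(15, 25),
                                  layer = list(amplitude = 25, period = 220),
                                  dendrites = TRUE, vessels = 0,
                                  background = 0.05,
                                  field_diameter = 230, pitch = 0.7,
                                  seed = 1L) {
  ng <- phantom_grid(field_diameter, pitch)
  xs <- grid_axis(ng, pitch)
  px <- matrix(xs, ng, ng, byrow = TRUE)
  py <- matrix(xs, ng, ng)
  rmax <- field_diameter / 2
  infield <- px^2 + py^2 < rmax^2
  dens <- matrix(0, ng, ng)
  labels <- list()
  layer_y <- function(x) layer$amplitude * sin(2 * pi * x / layer$period)
  with_seed(seed, {
    ## somata along the layer curve
    placed <- matrix(numeric(0), 0, 3)    # x, y, radius
    for (i in seq_len(n_somata)) {
      ok <- FALSE
      for (t in seq_len(2000)) {
        d <- stats::runif(1, soma_diameter_range[1], soma_diameter_range[2])
        x0 <- stats::runif(1, -rmax + d / 2, rmax - d / 2)
        y0 <- layer_y(x0) + stats::rnorm(1, 0, 3)
        if (x0^2 + y0^2 > (rmax - d / 2)^2) next
        if (nrow(placed) > 0 &&
            min(sqrt((placed[, 1] - x0)^2 + (placed[, 2] - y0)^2) -
                  placed[, 3] - d / 2) < 0) next
        placed <- rbind(placed, c(x0, y0, d / 2))
        labels[[length(labels) + 1L]] <-
          data.frame(kind = "soma", x = x0, y = y0, size = d)
        ok <- TRUE
        break
      }
      if (!ok) hf_stop("could not place all somata without overlap",
                       "holofiber_packing_failure")
    }
    for (i in seq_len(nrow(placed))) {
      r2 <- (px - placed[i, 1])^2 + (py - placed[i, 2])^2
      dens <- pmax(dens, matrix(soft_disk(as.vector(r2), placed[i, 3], 2),
                                ng, ng))
    }
    ## dendrites: thin processes perpendicular to the (locally flat) layer
    if (dendrites) {
      for (i in seq_len(nrow(placed))) {
        len <- stats::runif(1, 25, 45)
        x0 <- placed[i, 1]; y0 <- placed[i, 2]
        p1 <- c(x0 + stats::rnorm(1, 0, 4), y0 + len)   # towards +y
        dd <- seg_dist(px, py, c(x0, y0), p1)
        dens <- pmax(dens, 0.6 * matrix(soft_disk(as.vector(dd^2), 1.5, 0.7),
                                        ng, ng))
        labels[[length(labels) + 1L]] <-
          data.frame(kind = "dendrite", x = x0, y = y0, size = len)
      }
    }
    ## diffuse background inside the field
    dens <- pmax(dens, background * infield)
    ## dark vessels: zero-density ribbons through the background
    for (i in seq_len(vessels)) {
      th <- stats::runif(1, 0, pi)
      off <- stats::runif(1, -rmax / 2, rmax / 2)
      p0 <- c(-rmax * cos(th) - off * sin(th), -rmax * sin(th) + off * cos(th))
      p1 <- c(rmax * cos(th) - off * sin(th), rmax * sin(th) + off * cos(th))
      wd <- stats::runif(1, 6, 10)
      dd <- seg_dist(px, py, p0, p1)
      factor <- matrix(1, ng, ng)
      factor[dd < wd / 2] <- 0
      edge <- dd >= wd / 2 & dd < wd
      factor[edge] <- (dd[edge] - wd / 2) / (wd / 2)
      dens <- dens * factor
      labels[[length(labels) + 1L]] <-
        data.frame(kind = "vessel", x = p0[1], y = p0[2], size = wd)
    }
  })
  labels <- if (length(labels)) do.call(rbind, labels)
            else data.frame(kind = character(), x = numeric(),
                            y = numeric(), size = numeric())
  new_phantom(dens, pitch, labels, seed, "purkinje")
}
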