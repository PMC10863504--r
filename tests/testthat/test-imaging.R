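# Image formation in both regimes and the quality metrics.

test_that("raster scan with ideal foci equals the brute-force convolution", {
  ph <- make_bead_phantom(4, diameter = 6, field_diameter = 56, pitch = 1.4,
                          seed = 3)
  n <- nrow(ph$density)
  plan <- scan_plan(n, 1.4, 50, working_distance = 15)
  psf <- Mod(gaussian_field(15, 1.4, waist = 2.5)$amplitude)^2
  img <- raster_scan_image(ph, plan, psf = psf)
  # brute-force direct-sum oracle
  bf <- matrix(NA_real_, n, n)
  for (idx in plan$index) {
    ij <- arrayInd(idx, c(n, n)); acc <- 0
    for (a in 1:15) for (b in 1:15) {
      ii <- ij[1] + a - 8; jj <- ij[2] + b - 8
      if (ii >= 1 && ii <= n && jj >= 1 && jj <= n)
        acc <- acc + psf[a, b] * ph$density[ii, jj]
    }
    bf[idx] <- acc * 1.4^2
  }
  expect_lt(max(abs(img$pixels - bf), na.rm = TRUE) / max(bf, na.rm = TRUE),
            1e-6)
  # out-of-mask pixels are invalid, not zero
  expect_true(all(is.na(img$pixels[!plan$mask])))
})

test_that("empty phantom and point emitter behave as definitions demand", {
  n <- 40
  plan <- scan_plan(n, 1.4, 50)
  psf <- Mod(gaussian_field(15, 1.4, waist = 2.5)$amplitude)^2
  empty <- make_bead_phantom(0, field_diameter = 56, pitch = 1.4)
  img0 <- raster_scan_image(empty, plan, psf = psf)
  expect_equal(max(img0$pixels, na.rm = TRUE), 0)
  # single point emitter: image reproduces the (flipped) focus pattern
  pt <- empty; pt$density[20, 20] <- 1
  img1 <- raster_scan_image(pt, plan, psf = psf)
  patch <- img1$pixels[14:26, 14:26] / 1.4^2
  expect_equal(patch[7, 7], psf[8, 8], tolerance = 1e-9)
  expect_equal(patch, psf[rev(2:14), rev(2:14)], tolerance = 1e-9)
})

test_that("measured-TM raster image matches the ground-truth-TM image", {
  ms <- test_modes()
  sys <- fiber_system(ms, seed = 8)
  mtm <- acquire_tm(sys, list(n = 9, extent = 11))
  gt <- acquire_tm(sys, list(n = 9, extent = 11), interferometry = FALSE)
  plan <- scan_plan(ms$n, ms$pitch, ms$core_diameter, working_distance = 4)
  ph <- structure(list(density = matrix(0, ms$n, ms$n), pitch = ms$pitch,
                       labels = data.frame(), seed = 1L, kind = "spots"),
                  class = "phantom")
  set.seed(2)
  ph$density[sample(which(plan$mask), 30)] <- 1
  im <- tm_raster_scan(mtm, sys, ph, plan)
  ig <- tm_raster_scan(gt, sys, ph, plan)
  rel <- sqrt(mean((im$pixels - ig$pixels)^2, na.rm = TRUE)) /
    sqrt(mean(ig$pixels^2, na.rm = TRUE))
  expect_lt(rel, 0.02)
})

test_that("corelet scan is uniform on uniform phantoms and deformation
           invariant", {
  lat <- test_lattice(); spec <- test_spec()
  tm <- build_mc_tm(lat, 1)
  un <- uniform_phantom()
  ci <- corelet_scan_image(tm, un, lat, spec)
  expect_lt(diff(range(ci$value)) / mean(ci$value), 1e-9)
  expect_identical(ci$spiral_rank, 0:60)
  # invariance under deformation (to double-precision rounding), and
  # correlation > 0.99 with detector noise at 1e4 photons
  td <- apply_deformation(tm, deformation_state(3, seed = 4))
  expect_equal(corelet_scan_image(td, un, lat, spec)$value, ci$value,
               tolerance = 1e-12)
  det <- detector_model(1e4, dark_rate = 5, seed = 11)
  phb <- make_bead_phantom(10, diameter = 8, field_diameter = 210,
                           pitch = 1, seed = 2)
  v1 <- corelet_scan_image(tm, phb, lat, spec, detector = det)$value
  v2 <- corelet_scan_image(td, phb, lat, spec, detector = det)$value
  expect_gt(stats::cor(v1, v2), 0.99)
  # a bead centered on corelet k lights up corelet k most
  bead <- uniform_phantom(240, 1)
  bead$density[] <- 0
  xs <- (seq_len(240) - 120.5) * 1
  k <- 17
  bead$density <- (outer((xs - lat$y[k])^2, (xs - lat$x[k])^2, `+`) < 9) * 1
  cib <- corelet_scan_image(tm, bead, lat, spec)
  expect_equal(which.max(cib$value), k)
  # regime guard
  expect_error(corelet_scan_image(build_mm_tm(test_modes()), un, lat, spec),
               class = "holofiber_invalid_argument")
})

test_that("Michelson contrast has the right fixed points", {
  v <- c(rep(4, 5), rep(4, 5))
  expect_equal(contrast_metric(v, 1:10 %in% 1:5, 1:10 %in% 6:10), 0)
  v2 <- c(rep(3, 5), rep(0, 5))
  expect_equal(contrast_metric(v2, 1:10 %in% 1:5, 1:10 %in% 6:10), 1)
  expect_error(contrast_metric(v, rep(FALSE, 10), 1:10 %in% 6:10),
               class = "holofiber_invalid_argument")
  expect_error(contrast_metric(v, 1:10 %in% 1:6, 1:10 %in% 6:10),
               class = "holofiber_invalid_argument")
})

test_that("radial FWHM recovers the closed form for Gaussian spots", {
  for (sig in c(2, 3.5)) {
    # field waist w gives intensity sd w/2
    I <- Mod(gaussian_field(128, 0.25, waist = 2 * sig)$amplitude)^2
    # intensity sd is sig: FWHM = 2.3548 sig
    expect_equal(radial_fwhm(I, 0.25, center = c(0, 0)), 2.3548 * sig,
                 tolerance = 0.01)
  }
  expect_warning(radial_fwhm(matrix(1, 16, 16) +
                               diag(16) * 0.01, 1, center = c(0, 0)),
                 "no half-maximum")
})

test_that("expected photon budget is conserved through the detector", {
  ph <- make_bead_phantom(3, diameter = 6, field_diameter = 56, pitch = 1.4,
                          seed = 5)
  plan <- scan_plan(nrow(ph$density), 1.4, 50)
  psf <- Mod(gaussian_field(15, 1.4, waist = 2.5)$amplitude)^2
  img <- raster_scan_image(ph, plan, psf = psf)
  # analytic total: sum over scan points of int I(r - rs) rho(r) dr
  direct <- 0
  for (idx in plan$index) {
    ij <- arrayInd(idx, dim(ph$density)); acc <- 0
    for (a in 1:15) for (b in 1:15) {
      ii <- ij[1] + a - 8; jj <- ij[2] + b - 8
      if (ii >= 1 && ii <= nrow(ph$density) && jj >= 1 && jj <= ncol(ph$density))
        acc <- acc + psf[a, b] * ph$density[ii, jj]
    }
    direct <- direct + acc * 1.4^2
  }
  expect_equal(sum(img$pixels, na.rm = TRUE), direct, tolerance = 1e-9)
  # Poisson detector: mean of counts tracks photons * signal
  det <- detector_model(1e3, dark_rate = 0, seed = 3)
  imgn <- raster_scan_image(ph, plan, psf = psf, detector = det)
  expect_equal(sum(imgn$pixels, na.rm = TRUE) / 1e3, direct, tolerance = 0.05)
  # detector determinism
  imgn2 <- raster_scan_image(ph, plan, psf = psf, detector = det)
  expect_identical(imgn$pixels, imgn2$pixels)
})

test_that("diffraction-limited PSF width approaches 0.51 lambda / NA", {
  fw <- suppressWarnings(psf_fwhm(40, 0.1, 488, n = 80, pitch = 0.21))
  expect_equal(fw, 0.51 * 0.488 / 0.1, tolerance = 0.15)
})
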