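# Binary hologram encoding, first-order isolation, interferometric
# calibration and focus synthesis.

test_that("Lee encoding produces the textbook limiting patterns", {
  # uniform unit-amplitude target: straight 50%-duty grating
  p <- encode_hologram(matrix(1 + 0i, 64, 64), carrier = c(1, 1) / 8)
  expect_equal(mean(p$frame), 0.5, tolerance = 1 / 64)
  # zero-amplitude regions are all-off
  tgt <- matrix(1 + 0i, 64, 64); tgt[1:16, ] <- 0
  p2 <- encode_hologram(tgt)
  expect_false(any(p2$frame[1:16, ]))
  # super-Nyquist carrier rejected
  expect_error(encode_hologram(tgt, carrier = c(0.6, 0.2)),
               class = "holofiber_invalid_argument")
})

test_that("first-order isolation is linear and exact on pure gratings", {
  p <- encode_hologram(matrix(1 + 0i, 96, 96), carrier = c(1, 1) / 8)
  u <- simulate_first_order(p)
  inner <- u[17:80, 17:80]
  expect_lt(stats::sd(Arg(inner * Conj(mean(inner)))), 1e-6)
  # linearity across disjoint supports: pattern of a two-region target
  # equals the sum of the single-region first orders
  t1 <- matrix(0i, 96, 96); t1[, 1:48] <- 1
  t2 <- matrix(0i, 96, 96); t2[, 49:96] <- 1
  f12 <- simulate_first_order(encode_hologram(t1 + t2, carrier = c(1, 1) / 8))
  f1 <- simulate_first_order(encode_hologram(t1, carrier = c(1, 1) / 8))
  f2 <- simulate_first_order(encode_hologram(t2, carrier = c(1, 1) / 8))
  expect_lt(max(Mod(f12 - f1 - f2)) / max(Mod(f12)), 0.05)
  # iris must keep the orders separate
  expect_error(simulate_first_order(p, iris_radius = 0.3),
               class = "holofiber_invalid_argument")
})

test_that("DMD round trip reproduces smooth targets", {
  tgt <- smooth_target(64, seed = 1)
  rec <- dmd_modulate(tgt)
  dphi <- as.vector(Arg(rec * Conj(tgt)))
  dphi <- Arg(exp(1i * (dphi - mean(dphi))))
  expect_lt(stats::sd(dphi), 0.1)       # rms phase error
  # relative phase between random point pairs
  set.seed(9)
  i <- sample(64^2, 400); j <- sample(64^2, 400)
  pair <- Arg(exp(1i * (dphi[i] - dphi[j])))
  expect_lt(sqrt(mean(pair^2)), 0.1)
  # amplitude-and-phase target: recovered amplitude tracks the target
  tga <- smooth_target(64, seed = 1, amplitude = TRUE)
  reca <- dmd_modulate(tga)
  expect_gt(stats::cor(as.vector(Mod(reca)), as.vector(Mod(tga))), 0.99)
})

test_that("four-step demodulation is exact, linear and null-preserving", {
  set.seed(2)
  S <- matrix(complex(real = stats::rnorm(32^2),
                      imaginary = stats::rnorm(32^2)), 32)
  R <- matrix(0.8 * exp(1i * 0.7), 32, 32)
  C <- psi_demodulate(make_interferograms(S, R))
  expect_lt(max(Mod(C / Conj(R) - S)), 1e-10)
  # zero signal -> zero estimate
  C0 <- psi_demodulate(make_interferograms(S * 0, R))
  expect_lt(max(Mod(C0)), 1e-12)
  # linearity in the signal
  S2 <- matrix(complex(real = stats::rnorm(32^2),
                       imaginary = stats::rnorm(32^2)), 32)
  Csum <- psi_demodulate(make_interferograms(S + S2, R))
  expect_lt(max(Mod(Csum - C - psi_demodulate(make_interferograms(S2, R)))),
            1e-10)
  expect_error(psi_demodulate(list(S, S, S)),
               class = "holofiber_invalid_argument")
})

test_that("demodulation error scales as one over sqrt(photons)", {
  set.seed(3)
  S <- matrix(complex(real = stats::rnorm(32^2, 0, 0.5),
                      imaginary = stats::rnorm(32^2, 0, 0.5)), 32)
  R <- matrix(1 + 0i, 32, 32)
  rms <- vapply(c(1e2, 1e4), function(np) {
    mean(vapply(1:20, function(s) {
      C <- psi_demodulate(make_interferograms(S, R, photons = np, seed = s))
      sqrt(mean(Mod(C - S * Conj(R))^2))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(rms[1] / rms[2], 10, tolerance = 0.2)
})

test_that("TM acquisition matches the ground truth after reference
           removal", {
  ms <- test_modes()
  sys <- fiber_system(ms, seed = 5)
  mtm <- remove_reference(acquire_tm(sys, list(n = 7, extent = 11)))
  gt <- acquire_tm(sys, list(n = 7, extent = 11), interferometry = FALSE)
  # noiseless PSI reproduces the exact responses column by column
  cs <- vapply(seq_len(ncol(mtm$matrix)), function(p) {
    a <- mtm$matrix[, p]; b <- gt$matrix[, p]
    Mod(sum(Conj(a) * b)) / sqrt(sum(Mod(a)^2) * sum(Mod(b)^2))
  }, numeric(1))
  expect_gt(min(cs), 0.999)
  # determinism
  expect_identical(acquire_tm(sys, list(n = 7, extent = 11))$matrix,
                   mtm_raw <- acquire_tm(sys, list(n = 7, extent = 11))$matrix)
  # zero-transmission medium: all-zero TM
  dead <- sys
  dead$tm$matrix <- dead$tm$matrix * 0
  expect_lt(max(Mod(acquire_tm(dead, list(n = 5, extent = 11))$matrix)), 1e-12)
})

test_that("input pruning keeps the in-aperture inputs", {
  # disk indicator map: kept count equals the disk point count
  n <- 21
  xs <- (seq_len(n) - (n + 1) / 2)
  inten <- as.numeric(outer(xs^2, xs^2, `+`) < 8^2)
  expect_identical(sort(prune_inputs(inten, 0.1)), which(inten > 0))
  # threshold near 1 keeps only the argmax ties
  inten2 <- c(0.2, 1, 0.999999999, 0.5)
  expect_identical(prune_inputs(inten2, 0.9999999), c(2L, 3L))
  expect_warning(out <- prune_inputs(rep(0, 5), 0.1), "no inputs")
  expect_identical(out, integer())
  expect_error(prune_inputs(inten, 0), class = "holofiber_invalid_argument")
  # aperture geometry on a scaled acquisition: every input well inside the
  # core is kept and every input beyond the core plus the spot tails is
  # dropped; the finite spot size softens the edge at this scale, so the
  # kept fraction brackets the asymptotic pi/4 (d/window)^2 from above
  ms <- test_modes()
  sys <- fiber_system(ms, seed = 1)
  mtm <- acquire_tm(sys, list(n = 15, extent = 1.1 * ms$core_diameter))
  kept <- prune_inputs(mtm$integrated, 0.1)
  r_in <- sqrt(rowSums(mtm$inputs^2))
  w0 <- 0.488 / (pi * 0.1)
  a <- ms$core_diameter / 2
  expect_true(all(which(r_in < a - w0) %in% kept))
  expect_true(all(r_in[kept] < a + 3 * w0))
  ratio <- length(kept) / ncol(mtm$matrix)
  expect_gte(ratio, pi / 4 / 1.1^2)
  expect_lt(ratio, pi / 4 / 1.1^2 * ((a + 3 * w0) / a)^2)
})

test_that("phase-conjugate synthesis focuses at the requested target", {
  ms <- test_modes()
  sys <- fiber_system(ms, seed = 4)
  mtm <- acquire_tm(sys, list(n = 9, extent = 11))
  f <- synthesize_focus(mtm, c(1.5, -2), sys)
  # intensity argmax lands on the target pixel (within one pixel)
  idx <- which.max(f$intensity)
  ij <- arrayInd(idx, dim(f$intensity))
  xs <- (seq_len(ms$n) - (ms$n + 1) / 2) * ms$pitch
  expect_lt(sqrt((xs[ij[2]] - f$target[1])^2 + (xs[ij[1]] - f$target[2])^2),
            1.5 * ms$pitch)
  expect_lte(f$metrics$power_ratio, 1)
  expect_gt(f$metrics$power_ratio, 0.5)
  expect_error(synthesize_focus(mtm, 10 * nrow(mtm$matrix), sys),
               class = "holofiber_invalid_argument")
})
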