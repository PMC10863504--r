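# Transmission-matrix transport, deformation and fiber mating.

test_that("multimode TM is unitary and interpolates from diagonal", {
  ms <- test_modes()
  tm <- build_mm_tm(ms, length = 1e5, seed = 3, coupling = 1)
  n <- ncol(tm$matrix)
  expect_lt(max(Mod(Conj(t(tm$matrix)) %*% tm$matrix - diag(n))), 1e-8)
  # coupling 0: diagonal with unit-modulus entries
  t0 <- build_mm_tm(ms, seed = 3, coupling = 0)$matrix
  expect_lt(max(Mod(t0 - diag(diag(t0)))), 1e-12)
  expect_equal(Mod(diag(t0)), rep(1, n), tolerance = 1e-12)
  # determinism: bit-identical under a fixed seed
  expect_identical(tm$matrix, build_mm_tm(ms, length = 1e5, seed = 3,
                                          coupling = 1)$matrix)
  expect_error(build_mm_tm(ms, coupling = 2),
               class = "holofiber_invalid_argument")
})

test_that("multicore TM is a 61-channel diagonal phase screen", {
  lat <- test_lattice()
  tm <- build_mc_tm(lat, seed = 1)
  expect_identical(dim(tm$matrix), c(61L, 61L))
  expect_lt(max(Mod(tm$matrix - diag(diag(tm$matrix)))), 1e-15)
  expect_equal(Mod(diag(tm$matrix)), rep(1, 61), tolerance = 1e-12)
  tm2 <- build_mc_tm(lat, seed = 2)
  expect_equal(Mod(diag(tm2$matrix)), Mod(diag(tm$matrix)))
  expect_gt(max(Mod(diag(tm2$matrix) - diag(tm$matrix))), 0.1)
})

test_that("deformation preserves multicore channel power exactly", {
  lat <- test_lattice()
  tm <- build_mc_tm(lat, seed = 1)
  expect_identical(apply_deformation(tm, deformation_state(0))$matrix,
                   tm$matrix)
  for (s in c(0.3, 1, 5)) {
    td <- apply_deformation(tm, deformation_state(s, seed = 7))
    expect_lt(max(abs(Mod(td$matrix) - Mod(tm$matrix))), 1e-12)
  }
  expect_error(deformation_state(-1), class = "holofiber_invalid_argument")
  # multimode deformation stays unitary and moves away from the original
  mm <- build_mm_tm(test_modes(), seed = 2)
  md <- apply_deformation(mm, deformation_state(0.5, seed = 3))
  n <- ncol(md$matrix)
  expect_lt(max(Mod(Conj(t(md$matrix)) %*% md$matrix - diag(n))), 1e-8)
  expect_gt(max(Mod(md$matrix - mm$matrix)), 0.01)
})

test_that("mating reduces to identity for perfect alignment", {
  lat <- test_lattice(); spec <- test_spec()
  tm1 <- build_mc_tm(lat, 1); tm2 <- build_mc_tm(lat, 2)
  m <- mate_fibers(tm1, tm2, lat, spec,
                   mating_state(axial_gap = 0))
  expect_lt(max(Mod(attr(m, "coupling") - diag(61))), 1e-6)
  expect_identical(m$regime, "multicore")
  # regime mismatch rejected
  mm <- build_mm_tm(test_modes(), seed = 1)
  expect_error(mate_fibers(mm, tm2, lat, spec),
               class = "holofiber_invalid_argument")
})

test_that("lateral offset couples with the closed-form Gaussian law", {
  lat <- test_lattice(); spec <- test_spec()
  w <- corelet_mode(spec)$waist
  tm1 <- build_mc_tm(lat, 1); tm2 <- build_mc_tm(lat, 2)
  for (d in c(0.5, 1.2, 2)) {
    m <- mate_fibers(tm1, tm2, lat, spec,
                     mating_state(lateral_offset = c(d, 0), axial_gap = 0))
    cp <- Mod(diag(attr(m, "coupling")))^2
    expect_lt(max(abs(cp - exp(-d^2 / w^2))), 1e-3)
  }
  # energy conservation: column squared norms never exceed 1
  m <- mate_fibers(tm1, tm2, lat, spec,
                   mating_state(lateral_offset = c(1.5, 1), rotation = 3))
  expect_lt(max(colSums(Mod(attr(m, "coupling"))^2)), 1 + 1e-6)
})

test_that("a 60-degree rotation maps the lattice onto itself", {
  lat <- test_lattice(); spec <- test_spec()
  tm1 <- build_mc_tm(lat, 1); tm2 <- build_mc_tm(lat, 2)
  m <- mate_fibers(tm1, tm2, lat, spec,
                   mating_state(rotation = 60, axial_gap = 0))
  cm <- Mod(attr(m, "coupling"))
  ok <- apply(cm, 1, function(r) sum(r > 1 - 1e-6) == 1 && sum(r > 1e-6) == 1)
  expect_true(all(ok))
})

test_that("gap coupling converges to identity as the gap closes", {
  lat <- hex_lattice(1, 25); spec <- test_spec()
  tm1 <- build_mc_tm(lat, 1); tm2 <- build_mc_tm(lat, 2)
  gaps <- c(4, 2, 1, 0.5, 0.1)
  self <- vapply(gaps, function(g) {
    m <- mate_fibers(tm1, tm2, lat, spec, mating_state(axial_gap = g))
    min(Mod(diag(attr(m, "coupling"))))
  }, numeric(1))
  expect_true(all(diff(self) > 0))          # monotone in shrinking gap
  expect_gt(self[length(self)], 0.999)
})

test_that("power fractions are near one for a single fiber and drop on
           misaligned mating, deterministically", {
  lat <- test_lattice(); spec <- test_spec()
  tm1 <- build_mc_tm(lat, 1)
  pf <- corelet_power_fractions(tm1, lat, spec)
  expect_gt(min(pf$fraction), 0.8)
  expect_equal(pf$mean, 1, tolerance = 1e-3)
  tm2 <- build_mc_tm(lat, 2)
  m <- mate_fibers(tm1, tm2, lat, spec,
                   mating_state(lateral_offset = c(1, 0.5)))
  pfm <- corelet_power_fractions(m, lat, spec)
  expect_lt(pfm$mean, pf$mean)
  # seeded reconnection draws reproduce bit-exactly
  draw <- function() {
    means <- numeric(3)
    for (s in 1:3) {
      off <- with_seed(split_seed(42, paste0("mate", s)),
                       stats::rnorm(2, 0, 0.3))
      mm <- mate_fibers(tm1, tm2, lat, spec,
                        mating_state(lateral_offset = off))
      means[s] <- corelet_power_fractions(mm, lat, spec)$mean
    }
    means
  }
  expect_identical(draw(), draw())
})

test_that("rotation search recovers the true ferrule angle", {
  lat <- test_lattice(); spec <- test_spec()
  tm1 <- build_mc_tm(lat, 1); tm2 <- build_mc_tm(lat, 2)
  # true angle 0
  rs0 <- rotation_search(tm1, tm2, lat, spec, gap = 0, step = 2)
  expect_lt(min(rs0$angle, 60 - rs0$angle), 0.1)
  # a random true angle, emulated by pre-rotating the second lattice
  rs <- rotation_search(tm1, tm2, lat, spec, gap = 0, step = 2,
                        lattice2 = rotated_lattice(lat, 17.3))
  expect_lt(abs(rs$angle - 17.3), 0.1)
  # the refined optimum is at least as good as every coarse sample
  expect_gte(rs$objective, max(rs$trace$objective))
})

test_that("marker similarity is affine-invariant and decorrelates", {
  set.seed(5)
  a <- matrix(stats::rnorm(64 * 64), 64)
  expect_equal(marker_similarity(a, a), 1, tolerance = 1e-12)
  expect_equal(marker_similarity(a, 3 * a + 7), 1, tolerance = 1e-12)
  for (s in 1:10) {
    set.seed(s)
    b <- matrix(sample(a), 64)
    expect_lt(abs(marker_similarity(a, b)), 0.1)
  }
  expect_error(marker_similarity(a, matrix(1, 64, 64)),
               class = "holofiber_undefined_similarity")
})
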