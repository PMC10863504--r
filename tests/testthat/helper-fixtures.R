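# Shared reduced-scale fixtures, built once per test run and cached.
# The physics of the full-size fiber is scale-free; a V ~ 6.4 test fiber
# (10 um core, NA 0.1) keeps every end-to-end check fast while exercising
# the same code paths as the 232 um device.

.hf_cache <- new.env(parent = emptyenv())

hf_cached <- function(key, expr) {
  if (!exists(key, envir = .hf_cache)) assign(key, expr, envir = .hf_cache)
  get(key, envir = .hf_cache)
}

# 12-scalar-mode test fiber on a 64 x 64 camera grid
test_modes <- function() hf_cached("modes_small", suppressWarnings(
  solve_lp_modes(10, 0.1, 488, n = 64, extent = 24)))

# ~100-mode fiber for speckle-statistics checks
test_modes_100 <- function() hf_cached("modes_100", suppressWarnings(
  solve_lp_modes(31, 0.1, 488, n = 96, extent = 70)))

test_lattice <- function() hf_cached("lattice", hex_lattice(4, 25))

test_spec <- function() fiber_preset("m3cf")

# smooth band-limited random complex target for hologram round trips
smooth_target <- function(n = 64, bw = 0.04, seed = 1, amplitude = FALSE) {
  set.seed(seed)
  lp <- function(s) {
    f <- stats::fft(matrix(stats::rnorm(n^2), n))
    fx <- c(seq.int(0, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1)) / n
    m <- outer(fx^2, fx^2, `+`) < bw^2
    Re(stats::fft(f * m, inverse = TRUE)) / n^2
  }
  phi <- lp(1); phi <- phi / stats::sd(phi)
  if (!amplitude) return(exp(1i * phi))
  set.seed(seed + 1)
  a <- abs(lp(1)); a <- 0.15 + 0.85 * a / max(a)
  a * exp(1i * phi)
}

# rotate a corelet lattice by `deg` degrees (emulates a rotated ferrule)
rotated_lattice <- function(lattice, deg) {
  th <- deg * pi / 180
  out <- lattice
  out$x <- cos(th) * lattice$x - sin(th) * lattice$y
  out$y <- sin(th) * lattice$x + cos(th) * lattice$y
  out
}

# uniform phantom on its own grid
uniform_phantom <- function(n = 480, pitch = 0.5) {
  structure(list(density = matrix(1, n, n), pitch = pitch,
                 labels = data.frame(), seed = 0L, kind = "uniform"),
            class = "phantom")
}
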