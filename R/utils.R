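#' @keywords internal
"_PACKAGE"

## Classed error conditions.  Every user-facing precondition failure raises a
## condition inheriting from "holofiber_error" plus a specific class, so
## callers (and tests) can discriminate failure modes.
hf_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "holofiber_error", "error"),
                      call = call))
}

hf_invalid <- function(msg) hf_stop(msg, "holofiber_invalid_argument",
                                    call = sys.call(-2))

#' Evaluate an expression with a local, restored RNG state
#'
#' All stochastic operations in the package take an explicit `seed` and are
#' pure functions of their arguments: the global RNG stream of the caller is
#' never disturbed.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    hf_invalid("`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage seed from one run seed
#'
#' One global run seed fans out deterministically to the pipeline stages
#' (phantom generation, transmission matrices, detector noise, ...), so any
#' stage can be reproduced in isolation.  The rule is a fixed multiplicative
#' hash of the stage label folded into 31 bits.
#'
#' @param seed integer run seed.
#' @param stage character stage label.
#' @return derived integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' split_seed(1, "phantom")
#' split_seed(1, "detector")
split_seed <- function(seed, stage) {
  if (!is.character(stage) || length(stage) != 1L)
    hf_invalid("`stage` must be a single character label")
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 69069 + h * 257) %% 2147483646)
}

## Centered grid axis: n points at the given pitch, axis-centered so that the
## centroid of the grid sits at `center`.  Row/column i (1-based) maps to
## coordinate (i - (n + 1) / 2) * pitch + center.  Rows run from -y to +y.
grid_axis <- function(n, pitch, center = 0) {
  (seq_len(n) - (n + 1) / 2) * pitch + center
}

## FFT frequency axis in cycles per unit length, in FFT (wrapped) order.
fft_freq <- function(n, pitch) {
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
  k / (n * pitch)
}

## Zero-normalized cross-correlation at zero lag of two equal-shape arrays.
zncc <- function(a, b) {
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0)
    hf_stop("constant image: similarity is undefined",
            "holofiber_undefined_similarity")
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb) *
    length(a) / (length(a) - 1)
}
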