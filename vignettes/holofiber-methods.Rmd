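---
title: "Models and numerical methods behind holofiber"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods behind holofiber}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holofiber)
```

`holofiber` is a forward model of holographic endoscopy through a hybrid
multimode–multicore fiber: a 232 µm step-index multimode "pulp" (NA 0.1)
inside a 278 µm cladding, carrying 61 single-mode corelets on a four-ring
hexagonal lattice of 25 µm pitch. This vignette describes the physical
models, the tunable parameters, the numerical choices, and what the
simulation does and does not capture.

## Scalar waveguide model

All optics is scalar and weakly guiding. Polarization enters only as an
integer multiplicity in the mode-capacity estimate
`round(p · V²/4)`, `V = π d NA / λ`; every quantity the simulator reports
is insensitive to vector corrections at NA ≤ 0.29. Guided LP(l, m) modes
solve

$$u\,J_{l+1}(u)\,K_l(w) \;=\; w\,K_{l+1}(w)\,J_l(u),
\qquad u^2 + w^2 = V^2 ,$$

with the Bessel-K ratio evaluated in exponentially scaled form and, where
even that overflows (high order near cutoff), replaced by its uniform
asymptotic limit — the affected roots are weakly guided modes whose exact
position is immaterial. Roots are bracketed by a fine scan of the
continuous residual (no poles) and polished with `uniroot` to 1e-12.
Propagation constants are stored as offsets from the cladding plane-wave
constant, `β − k n_clad = (w/a)² / (β + k n_clad)`, avoiding the
catastrophic cancellation of two numbers near `k n_clad ≈ 1.9·10⁷` rad/m.

Sampled mode sets are polished to exact discrete orthonormality by
symmetric (Löwdin) orthogonalization of the Gram matrix. The sampled basis
is the object every downstream computation uses, so orthonormality under
the *discrete* inner product — not approximate continuum orthogonality —
is the invariant that keeps transmission matrices unitary to 1e-8.

**Scale.** The full fiber supports ≈ 11 000 guided modes; its physics
(unitarity, speckle statistics, matched-filter focusing) is scale-free.
The test suite therefore runs on scaled fibers — 10 µm / NA 0.1 (12
scalar modes, 64² camera) for exactness checks and 31 µm / NA 0.1 (103
modes, 96² camera) for speckle statistics — chosen as the smallest systems
in which the asymptotic random-matrix expectations are visible. The
diffraction-limit study uses a 40 µm core, where the mode-projection
kernel's FWHM is within 3% of its asymptote (doubling the core moves it by
less than the measurement resolution).

## Transmission matrices and deformation

The lossless multimode fiber is `T = U(c, seed) · diag(e^{iβ_m L})`. The
mixing unitary `U(c) = V e^{i c s Λ} V†` is built from the
eigendecomposition of a seeded GUE matrix: its eigenvectors are exactly
Haar-distributed, so `c = 1` with the winding scale `s = π√N` is Haar-like
while `c → 0` approaches the identity smoothly. Deformation
right-multiplies by the same family at unit scale, so `strength` is
approximately the rms modal phase perturbation in radians; over
`strength ∈ [0, 1]` the expected focus fidelity decays monotonically
(characteristic function of the semicircle law), which is the regime the
resilience comparison uses. The multicore regime is a diagonal phase
screen over the 61 corelet channels; deformation perturbs only those
phases, so per-channel *power* is preserved algebraically — corelet-scan
images are intensity functionals and are invariant to double-precision
rounding (~1 ulp).

## Binary-amplitude holography

A micromirror frame encodes `A e^{iφ}` by switching a mirror on iff the
local carrier phase (reduced modulo one cycle *exactly*, before any
trigonometry) lies within the half-open window `[−πq, πq)`,
`q = asin(A)/π`. This is the classical Lee rule; the exact reduction and
half-open window make the pattern deterministic even on threshold
contours, and the first order then carries `sin(πq)/π · e^{iφ} = A/π·e^{iφ}`.
The isolated order sits at *minus* the carrier frequency (a sign
convention; physics is unchanged).

Two numerical parameters matter and both default to the high-fidelity
regime a physical system operates in:

* **carrier** — magnitude 1/24 cycles/mirror along the frame diagonal.
  Short fringe periods quantize the encoded phase (stripe positions snap
  to mirrors) and squeeze low-amplitude stripes below one mirror; at a
  24-mirror period the measured round-trip floor is ≈ 0.04 rad rms in
  phase and r > 0.99 in amplitude. The diagonal, pixel-incommensurate
  orientation makes edge quantization self-dithering.
* **oversampling** — `dmd_modulate()` renders targets at 8 mirrors per
  field sample (Fourier interpolation), mirroring the physical
  demagnification between the DMD and the fiber facet. Encoding targets
  1:1 at the field resolution raises the floor to ~0.15 rad.

The residual ~0.05 rad pairwise relative-phase error is a genuine property
of binary encoding at these parameters — it is flat in target smoothness,
so it is mirror quantization, not band truncation — and the test suite
asserts it at 0.1 rad.

## Interferometric calibration

Four-step phase-shift interferometry uses reference phases
{0, π/2, π, 3π/2} and the exact closed form
`C = [(I₀−I_π) + i(I_{π/2}−I_{3π/2})]/4 = S·R̄`. The reference beam is a
uniform tilted plane wave, constant across acquisitions (it arrives
through a separate fiber in the physical system), so its conjugate factor
per camera pixel is divided out once (`remove_reference()`); focusing is
invariant to that factor anyway because a TM *row* sees it as a global
phase. With a noiseless detector the measured TM equals the ground-truth
response exactly, which is why the calibration-fidelity check is exact
rather than approximate; Poisson noise enters only through the
interferogram counts and obeys the expected `1/√photons` error law.

Input foci are Gaussian spots of waist `λ/(π NA)` on a square grid spanning
a window 10% wider than the cladding; inputs whose integrated output falls
below 10% of the maximum are pruned. At full scale (201² inputs, 278 µm
cladding) this keeps ≈ 26 500 inputs; at test scale the spot size is not
negligible against the core, so the aperture edge is soft and the kept
fraction brackets the asymptotic `π/4 (d/window)²` from above — the unit
test asserts exactly that bracketing.

**Focus metrics.** `power_ratio` integrates the replayed intensity over a
disk of radius `2 × 0.51 λ/NA` (the window is otherwise unspecified in the
underlying experiments). `enhancement` is peak intensity over the *mean
intensity across the whole core mask*. For a unitary TM the spatial mean
equals the ensemble-average speckle intensity, so phase-only conjugation
over N modes gives the classical `π N/4`; a residual-background definition
(mean outside the focus disk) would instead measure `πN/4 / (1 − π/4)`
because focusing *depletes* the background of a unitary system, and would
not match the random-matrix expectation the simulator is tested against.
Measured enhancement runs ~9% below `πN/4` because conjugation happens in
the overcomplete input-spot frame rather than the mode basis, at the same
~3 spots/mode sampling ratio the full-scale instrument uses.

## Mating and reconnection

Corelet fundamental modes are Gaussians with the Marcuse waist
(`w ≈ 1.53 µm` for the 2 µm / NA 0.13 corelet defaults; those three corelet
parameters are not part of the fiber's printed geometry and are package
defaults chosen so four rings fit the pulp with margin and each corelet is
single-mode at 488 nm — all overridable in the config). The coupling
matrix entry between corelet k of fiber 1 (rotated, offset, propagated
across the axial gap with the angular-spectrum operator) and corelet j of
fiber 2 is a discrete overlap integral on a local grid; entries below 1e-4
are truncated and only site pairs within the Gaussian-tail cutoff are
evaluated at all, so a 61×61 coupling matrix costs ~0.3 s. The default
axial gap is 0.5 µm (ferrule-flush end faces are never perfectly flush)
and the default residual lateral offset is drawn with sd 0.3 µm, the
concentricity class of precision ceramic ferrules; the 3 µm bore clearance
is a hard cap. Under these defaults five seeded reconnection attempts lose
4–6% of the mean per-corelet power — the experimentally observed order —
but the misalignment distribution is configuration, not an assertion.

Rotational alignment scans one 60° symmetry sector coarsely (default 0.5°,
tests use 2°) and refines with `optimize()`; the bracket wraps across 0°
so true angles near the sector edge are still recovered to < 0.1°.

`corelet_power_fractions()` reports, per corelet, the power arriving
inside that corelet's addressing disk (radius = half the lattice pitch)
*per unit launched power*: light lost at the interface counts as loss.
Normalizing instead by the power that survives to the output facet would
hide coupling loss entirely in this model, because the multicore regime
transports no stray light.

## Imaging

Raster images integrate the focus intensity at the working-distance plane
(default 15 µm) against a 2-D fluorophore density; a thin-slab 3-D
extension is out of scope. Ideal-focus imaging is a cross-correlation
computed by zero-padded FFT and verified against a direct-sum oracle to
1e-6; measured-TM imaging synthesizes every scan focus through the batched
matrix path. Corelet images evaluate the analytic propagated Gaussian
beams, so mated-pair imaging keeps the coherent interference between
neighboring corelet beams. The detector is a Poisson photon counter with
dark rate; out-of-mask pixels are flagged invalid (NA) and only zero-filled
on TIFF export, with the mask recorded in the JSON sidecar so the file
round trip is exact.

The phantom generators emulate the imaging targets — 6 µm fluorescent
beads, a single layer of 15–25 µm somata with thin perpendicular
processes, and dark vessels as zero-density ribbons over a 5% diffuse
background (nonzero so that vessel contrast is measurable). They are pure
functions of (parameters, seed). They do *not* model tissue scattering,
axial structure, photobleaching or motion, so passing tests demonstrate
the correctness of the optical chain, not performance on real tissue.

## Degenerate inputs and edge cases

Zero-diameter apertures give empty masks; zero-amplitude hologram regions
give all-off mirrors; a zero-transmission medium yields an all-zero
measured TM; an all-zero intensity map prunes to nothing with a warning;
constant marker images make similarity undefined (a classed error rather
than NaN); packing failures in phantom generation raise a classed error
after a bounded retry budget. Every stochastic function takes an explicit
seed and restores the caller's RNG state; one run seed fans out to stages
via `split_seed()`.

## Known limitations

Scalar fields only (no polarization scrambling); no fiber-internal
bend model beyond the abstract unitary family; no Fresnel reflections at
the mating interface (only relative power is reported); corelet crosstalk
inside one fiber is zero by construction in the multicore regime; the
brighter appearance of corelets relative to pulp under multimode
illumination in real cascaded-index fibers is not modeled. The ~12 500
mode figure quoted for the physical device exceeds the standard
`2·V²/4 ≈ 11 150` estimate for the printed geometry; the package reports
the standard estimate and leaves the counting convention open.
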