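# holofiber

An in-silico model of lensless holographic endoscopy through a hybrid
**multimode–multicore fiber (M3CF)** — a 278 µm fiber whose 232 µm inner
"pulp" forms a step-index multimode waveguide (NA 0.1) that embeds 61
single-mode corelets on a hexagonal lattice. Such fibers are used as
hair-thin endoscopes for fluorescence imaging of neurons (e.g. eGFP-labeled
cerebellar Purkinje cells) deep in the living brain, and they support two
complementary regimes:

* **multimode** — the fiber's transmission matrix (TM) is calibrated
  interferometrically and its phase-conjugate rows synthesize
  diffraction-limited scanning foci: high-resolution raster imaging, but
  sensitive to fiber deformation;
* **multicore** — light is addressed corelet by corelet in a spiral scan:
  only 61 pixels, but transport phases are the only thing a deformation can
  change, so intensity imaging through the corelets is
  deformation-resilient.

The package simulates the full optical chain for both regimes and for the
quantitative fiber *reconnection* protocol (ferrule mating, rotational
alignment, per-corelet power budget) that chronic implantation requires.
For whom: researchers designing or analyzing TM-based fiber endoscopes who
want a controlled, seeded forward model to test calibration, imaging and
reconnection procedures against known ground truth.

## What is inside

| Layer | Functions |
|---|---|
| fiber geometry | `fiber_spec()`, `fiber_preset()`, `hex_lattice()`, `spiral_order()`, `aperture_mask()`, `v_number()`, `estimate_mode_count()` |
| scalar optics | `solve_lp_modes()`, `corelet_mode()`, `overlap()`, `propagate()`, `mode_projection_psf()` |
| transport | `build_mm_tm()`, `build_mc_tm()`, `apply_deformation()`, `mate_fibers()`, `corelet_power_fractions()`, `rotation_search()`, `marker_similarity()` |
| holographic calibration | `encode_hologram()`, `simulate_first_order()`, `dmd_modulate()`, `make_interferograms()`, `psi_demodulate()`, `acquire_tm()`, `prune_inputs()`, `synthesize_focus()` |
| imaging | `scan_plan()`, `raster_scan_image()`, `tm_raster_scan()`, `corelet_scan_image()`, `contrast_metric()`, `psf_fwhm()` |
| phantoms & I/O | `make_bead_phantom()`, `make_purkinje_phantom()`, `load_config()`, TIFF/JSON/container writers, CLI (`inst/cli/holofiber`) |

The core physics in standard notation: the fiber TM **T** maps input to
output mode coefficients, `b = T a`, with the lossless fiber idealized as
unitary on the guided subspace. Guided LP(l,m) modes of the step-index
waveguide are found from the weakly-guiding characteristic equation
`u J_{l+1}(u) K_l(w) = w K_{l+1}(w) J_l(u)`, `u² + w² = V²`,
`V = π d NA / λ`. Four-step phase-shift interferometry recovers a complex
field exactly as `C = [(I₀ − I_π) + i(I_{π/2} − I_{3π/2})]/4 = S·R̄`.
Binary-amplitude (Lee) holograms put `A e^{iφ}` on the first diffraction
order by switching a mirror on iff the local carrier phase falls within
`±π q`, `q = asin(A)/π`. Phase-conjugate focusing uses the conjugated TM
row as a matched filter; with phase-only control over N channels the focus
enhancement approaches `π N / 4`. Corelet coupling across a mated fiber
pair follows the Gaussian overlap law `|⟨g|g_d⟩|² = exp(−d²/w²)` with the
Marcuse waist `w = a(0.65 + 1.619 V^{−3/2} + 2.879 V^{−6})`.

## Worked example

```r
library(holofiber)

spec <- fiber_preset("m3cf")
lat  <- hex_lattice(spec$corelet_rings, spec$corelet_pitch)
nrow(lat)                                          # 61 corelets
attr(aperture_mask(352, 0.7, 232), "count")        # 86260 scan points
estimate_mode_count(spec, 2)                       # 11153 guided modes

## reduced-scale calibration + phase-conjugate focusing
modes <- solve_lp_modes(10, 0.1, 488, n = 64, extent = 24)  # V ~ 6.4
sys   <- fiber_system(modes, seed = 1)
mtm   <- remove_reference(acquire_tm(sys, list(n = 9, extent = 11)))
foc   <- synthesize_focus(mtm, c(1.5, -2), sys)
foc$metrics
#> focus: power ratio 0.932, enhancement 8.7, FWHM 2.79 um

## reconnect two fibers whose ferrules are rotated 23.4 degrees
tm1 <- build_mc_tm(lat, seed = 1); tm2 <- build_mc_tm(lat, seed = 2)
th <- 23.4 * pi / 180
lat2 <- lat
lat2$x <- cos(th) * lat$x - sin(th) * lat$y
lat2$y <- sin(th) * lat$x + cos(th) * lat$y
rs <- rotation_search(tm1, tm2, lat, spec, offset = c(0.25, -0.1),
                      gap = 0.5, step = 2, lattice2 = lat2)
rs$angle
#> recovered ferrule rotation: 23.400 deg (true 23.400)
mated <- mate_fibers(tm1, tm2, lat, spec,
                     mating_state(c(0.25, -0.1), rs$angle, 0.5),
                     lattice2 = lat2)
corelet_power_fractions(mated, lat, spec)$mean
#> mean corelet power fraction after reconnection: 0.969
```

The focus metrics say that 93% of the output power lands inside the focus
disk of a 12-mode test fiber, and the recovered 2.8 µm FWHM sits at the
NA-0.1 diffraction limit (0.51 λ/NA ≈ 2.5 µm at full modal control). After
reconnecting the rotated fiber pair, each corelet still delivers ~97% of
its launched power — the basis of the chronic-implant protocol.

A thin command-line front end with `phantom` / `simulate` / `calibrate` /
`image` / `reconnect` / `report` subcommands ships in
`inst/cli/holofiber`; see `vignettes/holofiber-methods.Rmd` for the model
assumptions and numerical choices.

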