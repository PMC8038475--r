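# fringeftp

Simulation and one-shot reconstruction for monochromatic structured-light
surface measurement of face-scale biological targets.

## The problem

Measuring the 3D shape of a human face with projected fringes fails in
ordinary conditions for three reasons: the direct reflection from skin is
only a few percent of the incident light while most of it re-emerges,
depolarized, after multiple scattering below the surface; ambient light
buries the fringe contrast; and faces move, which breaks multi-frame
phase-shifting methods. A laser-based projector addresses all three: its
fringes are **monochromatic** (so a 532 nm / 10 nm FWHM bandpass filter
rejects broadband ambient light), **linearly polarized** (so a camera
polarizer halves the unpolarized scatter while passing the direct signal),
and **truly sinusoidal** with unit contrast (so a single frame suffices for
Fourier-transform profilometry, FTP).

`fringeftp` is a self-contained simulate-and-reconstruct toolkit for this
measurement principle:

* **Fringe projector** (`fringe_optics`): scalar Fresnel diffraction through
  point source → binary grating → Fourier lens → ±1-order spatial filter →
  observation plane, plus the closed-form two-beam result
  `I ∝ cos²(2πf·x₃/(d·Z₃))` inside a disc of radius `H·Z₃/(2f)`, and
  cross-validation of the two routes.
* **Scene synthesis** (`scene_synthesis`): spherical-cap and face phantoms
  with closed-form / deterministic ground truth, and a three-component
  photometric renderer (polarized direct reflection, unpolarized Gaussian-
  blurred subsurface scatter, broadband background) with switchable filter,
  polarizer, auto-exposure, saturation, photon noise and quantization.
* **Reconstruction** (`ftp_core`): one-shot FTP — carrier estimation, Hann
  band-pass phase extraction, quality-guided 2D phase unwrapping (C++),
  reference subtraction, and exact phase-to-height inversion
  `h = L·Δφ/(Δφ − 2πf₀D)` of the triangulation model
  `Δφ = −2πf₀·D·h/(L−h)`.
* **Evaluation** (`metrics_eval`): Michelson contrast, offset-free height
  RMSE, qualitative grading, and an experiment matrix over carrier frequency
  × background illuminance × filter/polarizer × static/moving subject.

## Worked example

Render a one-shot frame of the classical silicone spherical-cap target
(base radius 40 mm, apex 10 mm) under 50 Lux-equivalent background with
filter and polarizer mounted, then reconstruct it from that single frame:

```r
library(fringeftp)

geom   <- projection_geometry(L = 1000, D = 300, f0 = 1.0)
cap    <- make_spherical_cap(40, 10, pitch = 0.25)
scene  <- photometric_scene(background_lux = 50)
camera <- camera_model(filter_on = TRUE, polarizer_on = TRUE)

frame <- render_frame(cap, geom, scene, camera, rng_seed = 1)
flat  <- surface_map(matrix(0, cap$nrow, cap$ncol), cap$pitch,
                     mask = matrix(TRUE, cap$nrow, cap$ncol))
reference <- render_frame(flat, geom, scene, camera, rng_seed = 2)

rec <- reconstruct(frame, geom, reference = reference)
err <- surface_rmse(rec$surface, cap)
c(rmse_mm = err$rmse_mm, rmse_pct = err$rmse_pct)
#>    rmse_mm   rmse_pct
#> 0.01841784 0.18418175
grade_accuracy(err$rmse_pct)
#> [1] "High"
```

The reconstruction recovers the 10 mm cap with an RMS height error of
0.018 mm (0.18% of the peak height) — grade "High" under the declared
thresholds (≤ 5% High, ≤ 10% Moderate, ≤ 25% Low, else Unable). Without the
filter and polarizer at 200 Lux-equivalent the frame saturates, carrier
detection fails, and the same scene grades "Unable" — the rescue effect the
optical design exists for.

The fringe projector itself:

```r
setup <- optical_setup()      # 532 nm, 50 lp/mm grating, f = 150 mm
setup$fringe_frequency        # 1 fringe/mm on the target at z3 = 15 m
closed <- closed_form_fringe(setup)          # analytic pattern
bench  <- bench_setup(z3 = 100)              # reduced-scale geometry
numeric <- simulate_fringe_numeric(bench)    # full diffraction chain
fringe_correlation(numeric,
                   closed_form_fringe(bench, n = numeric$n,
                                      pitch = numeric$pitch))
#> 0.9995
```

A command-line entry point wrapping the same functions ships in
`inst/cli/fringeftp` (subcommands `simulate`, `render`, `reconstruct`,
`evaluate`, with `--config`, `--seed`, `--out`).

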