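---
title: "Monochromatic fringe projection and one-shot FTP: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monochromatic fringe projection and one-shot FTP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 4)
library(fringeftp)
```

## The measurement problem

Structured-light profilometry projects a sinusoidal fringe pattern onto a
surface and recovers height from the phase of the observed fringes. For
biological targets such as a human face three things make this hard in
practice: the direct surface reflection is weak (a few percent of the
incident light) while most of the light re-emerges diffusely after multiple
scattering below the skin surface; ambient illumination washes out the fringe
contrast; and the subject moves, which rules out multi-frame phase-shifting
methods. The system modelled here counters all three at once: a *laser-based*
projector produces monochromatic, linearly polarized, truly sinusoidal
fringes, so a narrow bandpass filter on the camera rejects broadband ambient
light, a polarizer rejects the (depolarized) multiply-scattered component,
and a single frame suffices because the reconstruction is Fourier-transform
profilometry (FTP).

The package is a simulate-and-reconstruct toolkit: a scalar-diffraction
simulator of the fringe projector, a photometric renderer of one-shot camera
frames on synthetic surfaces, the FTP reconstructor, and an evaluation layer.
No external data is needed; every input is generated in code.

## The fringe projector

The projector is a point/collimated laser source, a binary transmission
grating (period $d$, slit width $a$, spatial frequency $1/d$ = 50 lp/mm by
default), a Fourier-transform lens of focal length $f$ = 150 mm, and a
spatial-frequency filter in the plane where the grating orders focus. The
filter passes only the $\pm 1$ orders; the two beams then interfere on the
observation plane at distance $Z_3$, giving the intensity

$$ I(x_3) \propto \cos^2\!\left(\frac{2\pi f\, x_3}{d\, Z_3}\right)
   \quad \text{inside a disc of radius } \frac{H Z_3}{2 f}, $$

where $H$ is the illuminated spot diameter on the grating. Two consequences
matter for measurement: the pattern is an ideal two-beam interference
pattern, so its Michelson contrast on zero background is exactly 1; and the
fringe frequency $2f/(dZ_3)$ scales inversely with the projection distance,
so the carrier on the target is adjustable (the product frequency
$\times\, Z_3$ is constant).

`closed_form_fringe()` evaluates this closed form. `simulate_fringe_numeric()`
independently chains the discrete physics — `grating_transmission()`,
`fresnel_propagate()`, `lens_transmit()`, `spatial_filter()` — and the two
routes are compared in the test suite (correlation $\ge 0.99$ over the
central half-radius, fringe period within one grid pitch, for $Z_3$ ratios
1:2:4).

### Where the filter must sit (Fourier-plane condition)

A ray analysis, confirmed by the numeric chain, shows the closed form is
exact when the grating is one focal length in front of the lens ($Z_1 = f$,
which makes the order positions $\pm m\lambda f/d$ independent of the source
distance) and the filter sits in the *image plane of the source*
$Z_2 = f(Z_0+Z_1)/Z_0$ — the back focal plane only for collimated
illumination ($Z_0 = \infty$, the default here, matching a collimated CW
laser). `optical_setup()` records whether this condition holds; the closed
form refuses to run when it does not.

### Numerical design of the propagator

`fresnel_propagate()` uses the Fresnel transfer function (angular-spectrum
kernel $e^{-i\pi\lambda z f^2}$). On an $N$-point grid of pitch $p$ the
sampled kernel phase is alias-free only for $|f| \le Np/(2\lambda z)$; for
$z \le Np^2/\lambda$ that covers the whole grid and the propagator is exactly
unitary. Beyond that the kernel is band-limited to the alias-free region
(out-of-band spectral energy corresponds to rays that leave the grid and is
removed); if the clipped fraction exceeds `band_tol` the call errors,
naming the maximal safe distance. This makes long-distance propagation
accurate for band-limited fields instead of silently aliasing.

One consequence: the experimental geometry itself (50 lp/mm grating with
$f=150$ mm needs a pitch of $d/8 = 2.5\,\mu$m to resolve the grating *and* an
extent over 10 mm to hold the $\pm 4$ mm order separation, and metre-scale
$Z_3$ before the two order beams overlap) cannot be held on one affordable
grid. The package therefore carries `bench_setup()`, a reduced-scale
validation geometry (20 lp/mm, $f=25$ mm, $H=1$ mm, $Z_3 = 50\ldots200$ mm)
with identical physics that fits a $2048^2$ grid alias-free; all numeric
oracle-equivalence checks run there, while the full-scale defaults of
`optical_setup()` are served by the closed form. The binary grating is
sampled with per-pixel area weighting (each sample holds the slit coverage of
its cell), which suppresses aliasing of high grating harmonics; with a 50%
duty cycle the even orders vanish identically and the $\pm 1$ orders carry
$2/\pi^2 \approx 0.203$ of the incident power ($0.405$ of the transmitted
power), which the chain reproduces.

## The photometric scene model

`render_frame()` composes three irradiance components, in units of the
nominal peak projected irradiance:

* **direct** — the surface reflection of the projected pattern,
  `direct_albedo` (default 0.04: direct reflection from skin is a few
  percent) times the phase-modulated carrier; fully linearly polarized at
  the projector angle;
* **scatter** — `scatter_fraction` (default 0.4) times the projected
  pattern blurred by a Gaussian of `scatter_sigma` = 2.5 mm, the penetration
  depth of green light into skin; unpolarized. (A full radiative-transfer
  treatment is deliberately out of scope; the Gaussian lateral spread is the
  simplest model that destroys fringe modulation the way subsurface
  scattering does.)
* **background** — spatially uniform, unpolarized, spectrally flat over
  400–700 nm. Illuminance is calibrated so 200 Lux-equivalent equals the
  nominal peak fringe irradiance; absolute radiometry is not recoverable
  from a physical setup description, so this single constant anchors the
  Lux scale.

The camera applies an ideal polarizer (gain $\cos^2\theta$ on the
co-polarized direct term, exactly $1/2$ on unpolarized terms) and a 532 nm
bandpass filter of 10 nm FWHM, modelled as a top-hat: unit transmission at
the laser line, $10/300$ on the flat background. Exposure is set on the
fringe signal (full scale = 1.15 times the peak of direct + scatter), so
strong ambient light saturates the sensor — this, not added noise, is what
buries the fringes at high illuminance, reproducing the
"unable to reconstruct" regime. Photon noise (sd 1% of full scale at full
scale), read noise (0.2%) and 8-bit quantization complete the model. A
multiplicative albedo texture (15% sd, 15 mm correlation length) emulates
skin reflectance variation. Every frame is a pure function of
(configuration, seed).

At the 1.0 cycles/mm carrier the projector power is raised five-fold,
following the experimental protocol at the higher spatial frequency.

## Synthetic surfaces

`make_spherical_cap()` reproduces the classical silicone test object (base
radius 40 mm, apex 10 mm by default; the implied sphere radius is
$(r^2+h^2)/2h$ = 85 mm), giving a closed-form ground truth.
`make_face_phantom()` builds a deterministic, seed-jittered face-scale
surface (150 mm extent, 30 mm peak) from Gaussian features (brow, nose
ridge, cheeks, chin, eye sockets) on a windowed dome, smoothed so the local
slope stays below ~0.6. That keeps the instantaneous frequency of the
modulated carrier within $\pm f_0/3$ of the carrier — the condition for the
FTP band filter to separate signal from the DC term. Rigid in-plane motion
(`shift_surface()`) stands in for a moving subject: one-shot reconstruction
sees each frame independently, so motion only changes the per-frame ground
truth.

What the generator does **not** emulate: laser speckle, perspective and lens
distortion (the rendering is telecentric, per the small-angle triangulation
model), a realistic skin BRDF, camera MTF, and inter-reflections. Rendered
frames are therefore cleaner than real measurements at equal settings; the
evaluation layer reproduces the *orderings* (degradation with background,
rescue by filter+polarizer, advantage of the higher carrier), while absolute
accuracy grades at favourable settings come out better than the visual
judgments of a physical experiment. In particular the 0.3 cycles/mm cells
grade High here where a real system was judged Moderate/Low.

## Height model and reconstruction

The standard crossed-optical-axes triangulation model is the single source
of truth shared by renderer and reconstructor (validated in tests against a
brute-force ray intersection, not shared code):

$$ \Delta\phi = -\,\frac{2\pi f_0 D\, h}{L - h}, \qquad
   h = \frac{L\,\Delta\phi}{\Delta\phi - 2\pi f_0 D}, $$

with $L$ the camera distance (default 1000 mm), $D$ the projector–camera
baseline (default 300 mm), $f_0$ the carrier on the reference plane. The
defaults are declared configuration, not measured values. For
$L=1000$, $D=300$, $f_0=1$, $h=10$ mm: $\Delta\phi = -2\pi\cdot 3000/990
\approx -19.04$ rad, and the inverse recovers 10 mm to $10^{-10}$ relative.

`reconstruct()` composes the pipeline:

1. **Carrier**: strongest non-DC FFT peak, centroid-refined (or the known
   geometry carrier).
2. **Band extraction**: separable raised-cosine (Hann) window centred on the
   +1 lobe, half-width $f_0/2$ along and across the carrier (no shape is
   canonical; Hann keeps spatial ringing short). A window reaching DC is
   refused.
3. **Reference subtraction**: when a reference-plane frame is available its
   analytic signal is conjugate-multiplied in, cancelling the carrier and
   systematic window phase; otherwise the carrier ramp is subtracted and a
   plane fitted to the border ring absorbs the residual carrier error.
4. **Unwrapping**: quality-guided flood fill (analytic amplitude as
   quality), written in C++; deterministic with index tie-breaking;
   `rewrap(unwrap(x)) = x` on every unmasked pixel by construction. Pixels
   below 5% of the median quality are masked; if 2×2 loop residues exceed
   10% of pixels the affected region is masked with a warning. A row-wise
   Itoh unwrapper is available as a benchmark fallback.
5. **Offset convention**: the border ring of the image (4% of the side) is
   declared reference plane; its median phase is forced to zero.
6. **Height conversion** and mask erosion by two carrier periods, limiting
   the influence of the band filter's spatial ringing at object boundaries
   on error statistics.

## Evaluation

`michelson_contrast()` uses robust (1st/99th percentile) extrema by default;
`surface_rmse()` removes the global offset implied by the reference
convention and reports mm and percent-of-peak. `run_matrix()` crosses
carrier frequency × background × filter/polarizer × static/dynamic, renders
and reconstructs each cell (dynamic cells: five moved frames, worst
single-frame result kept), and grades by declared thresholds: High ≤ 5% of
peak height, Moderate ≤ 10%, Low ≤ 25%, else Unable (including carrier
detection failure). The thresholds are conventions standing in for visual
accuracy judgments, and are documented as such.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: $2048^2$ grids at $d/8$
pitch for the diffraction chain (the bench geometry is alias-free there);
384–440 px frames at 0.25–0.3 mm pitch for rendering and reconstruction;
100 seeded random fields for the unwrapper property. Degenerate inputs are
defined: a constant image has contrast 0 (not an error); a fully saturated
frame fails carrier detection with a clear error and grades Unable; a zero
amplitude phantom is the flat reference plane; `phase_to_height` masks
pixels where the denominator vanishes. All FFTs use one layout convention:
the carrier runs along image columns, grid origin at index $n/2+1$.

## Known limitations

* The scene model's realism gap (no speckle, ideal optics) compresses the
  dynamic range of accuracy grades at favourable settings, as noted above.
* Only carriers along the image x-axis are supported; transpose otherwise.
* The numeric diffraction chain at the full experimental scale needs grids
  beyond a desktop FFT; the bench preset validates the physics at reduced
  scale instead.
* The polarizer is ideal (infinite extinction); partial extinction would
  only interpolate the scatter gain between 1/2 and 1.

## A worked example

```{r example}
geom <- projection_geometry(L = 1000, D = 300, f0 = 1.0)
cap <- make_spherical_cap(40, 10, pitch = 0.25)
scene <- photometric_scene(background_lux = 50)
camera <- camera_model(filter_on = TRUE, polarizer_on = TRUE)
frame <- render_frame(cap, geom, scene, camera, rng_seed = 1)
flat <- surface_map(matrix(0, cap$nrow, cap$ncol), cap$pitch,
                    mask = matrix(TRUE, cap$nrow, cap$ncol))
reference <- render_frame(flat, geom, scene, camera, rng_seed = 2)
rec <- reconstruct(frame, geom, reference = reference)
err <- surface_rmse(rec$surface, cap)
c(rmse_mm = err$rmse_mm, rmse_pct = err$rmse_pct)
grade_accuracy(err$rmse_pct)
```
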