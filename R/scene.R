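#' Triangulation geometry of the projector-camera pair
#'
#' The crossed-optical-axes geometry standard in fringe-projection
#' profilometry: a camera at distance `L` from the reference plane, a
#' projector displaced by baseline `D`, and a carrier of spatial frequency
#' `f0` on the reference plane. Height modulates the phase of the observed
#' carrier by `dphi = -2 pi f0 D h / (L - h)`.
#'
#' @param L Camera-to-reference-plane distance in mm.
#' @param D Projector-camera baseline in mm.
#' @param f0 Carrier frequency on the reference plane, cycles/mm.
#' @param axis Image axis along which the carrier varies (`"x"`, i.e.
#'   columns; the only supported value).
#' @return An object of class `projection_geometry`.
#' @export
projection_geometry <- function(L = 1000, D = 300, f0 = 1.0, axis = "x") {
  stopifnot(is.numeric(L), L > 0, is.numeric(D), D > 0,
            is.numeric(f0), f0 > 0)
  axis <- match.arg(axis, "x")
  structure(list(L = L, D = D, f0 = f0, axis = axis),
            class = "projection_geometry")
}

#' Ground-truth phase modulation of a surface
#'
#' Forward model of the triangulation framework:
#' `dphi(x, y) = -2 pi f0 D h(x, y) / (L - h(x, y))`. Its exact inverse is
#' implemented by [phase_to_height()].
#'
#' @param surface A [surface_map()].
#' @param geom A [projection_geometry()].
#' @return A [phase_map()] (unwrapped) holding the ground-truth phase
#'   deviation in radians.
#' @export
phase_modulation <- function(surface, geom) {
  stopifnot(inherits(surface, "surface_map"),
            inherits(geom, "projection_geometry"))
  h <- surface$heights
  if (any(h >= geom$L)) {
    stop("surface height reaches the camera plane (h >= L)", call. = FALSE)
  }
  dphi <- -2 * pi * geom$f0 * geom$D * h / (geom$L - h)
  phase_map(dphi, state = "unwrapped", f0 = geom$f0, pitch = surface$pitch)
}

#' Three-component photometric scene
#'
#' Per-component radiometry of a skin-like target under projected fringes,
#' in units of the nominal peak projected irradiance (laser power 1):
#' a weak, linearly polarized direct surface reflection; a strong,
#' unpolarized, laterally blurred subsurface-scattering component; and an
#' unpolarized broadband background. The background calibration maps an
#' illuminance of 200 Lux to a background irradiance equal to the nominal
#' peak fringe irradiance.
#'
#' @param direct_albedo Fraction of incident light reflected directly at the
#'   surface (default 0.04; direct reflection from skin is a few percent).
#' @param scatter_fraction Fraction re-emerging after subsurface multiple
#'   scattering (default 0.4).
#' @param scatter_sigma Lateral spread of the re-emerging light in mm
#'   (default 2.5, the penetration depth of green light into skin).
#' @param background_lux Background illuminance in Lux-equivalent.
#' @param laser_power Relative projector power (default 1).
#' @param texture_amp Relative amplitude of the multiplicative albedo
#'   texture (default 0.15); 0 disables texture.
#' @param texture_scale Correlation length of the texture in mm (default 15).
#' @param texture_seed Seed of the texture field (default 1).
#' @return An object of class `photometric_scene`.
#' @export
photometric_scene <- function(direct_albedo = 0.04,
                              scatter_fraction = 0.4,
                              scatter_sigma = 2.5,
                              background_lux = 0,
                              laser_power = 1,
                              texture_amp = 0.15,
                              texture_scale = 15,
                              texture_seed = 1) {
  stopifnot(direct_albedo >= 0, scatter_fraction >= 0, scatter_sigma > 0,
            background_lux >= 0, laser_power > 0, texture_amp >= 0)
  if (direct_albedo + scatter_fraction > 1) {
    stop("direct_albedo + scatter_fraction must not exceed 1", call. = FALSE)
  }
  structure(list(direct_albedo = direct_albedo,
                 scatter_fraction = scatter_fraction,
                 scatter_sigma = scatter_sigma,
                 background_lux = background_lux,
                 laser_power = laser_power,
                 texture_amp = texture_amp,
                 texture_scale = texture_scale,
                 texture_seed = texture_seed,
                 lux_per_peak = 200),
            class = "photometric_scene")
}

#' Camera model
#'
#' A monochrome camera with an optional narrow bandpass filter matched to the
#' laser line and an optional linear polarizer. The filter passes the laser
#' line at unit transmission and attenuates the flat 400-700 nm background
#' spectrum by `fwhm / 300`. The ideal polarizer transmits the co-aligned
#' polarized direct component with gain `cos^2(polarizer_angle)` and any
#' unpolarized component with gain 1/2. Exposure is set on the fringe signal
#' (direct + scatter): full scale is `exposure_headroom` times its maximum,
#' so strong ambient light saturates the sensor.
#'
#' @param filter_on Logical; bandpass filter mounted?
#' @param filter_center Filter centre in nm (532).
#' @param filter_fwhm Filter FWHM in nm (10).
#' @param polarizer_on Logical; polarizer mounted?
#' @param polarizer_angle Polarizer angle relative to the projector
#'   polarization, radians (0 = co-aligned).
#' @param shot_noise Photon-noise scale: noise sd at full scale as a fraction
#'   of full scale (default 0.01).
#' @param read_noise Additive read-noise sd as a fraction of full scale
#'   (default 0.002).
#' @param bit_depth Quantization depth of the exported frame (default 8);
#'   `NA` for an unquantized floating-point frame.
#' @param exposure_headroom Full scale relative to the peak fringe signal
#'   (default 1.15).
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(filter_on = FALSE,
                         filter_center = 532,
                         filter_fwhm = 10,
                         polarizer_on = FALSE,
                         polarizer_angle = 0,
                         shot_noise = 0.01,
                         read_noise = 0.002,
                         bit_depth = 8,
                         exposure_headroom = 1.15) {
  stopifnot(filter_fwhm > 0, shot_noise >= 0, read_noise >= 0,
            exposure_headroom > 0)
  structure(list(filter_on = isTRUE(filter_on),
                 filter_center = filter_center,
                 filter_fwhm = filter_fwhm,
                 polarizer_on = isTRUE(polarizer_on),
                 polarizer_angle = polarizer_angle,
                 shot_noise = shot_noise,
                 read_noise = read_noise,
                 bit_depth = bit_depth,
                 exposure_headroom = exposure_headroom,
                 band_nm = 300),
            class = "camera_model")
}

#' Polarizer and filter gains of a camera
#'
#' @param camera A [camera_model()].
#' @return Named list: `direct` (gain on the co-polarized direct component),
#'   `unpolarized` (gain on unpolarized components), `background_band`
#'   (filter transmission of the flat broadband background), `laser_line`
#'   (filter transmission at the laser wavelength, 1).
#' @export
camera_gains <- function(camera) {
  stopifnot(inherits(camera, "camera_model"))
  list(
    direct = if (camera$polarizer_on) cos(camera$polarizer_angle)^2 else 1,
    unpolarized = if (camera$polarizer_on) 0.5 else 1,
    background_band = if (camera$filter_on) camera$filter_fwhm / camera$band_nm else 1,
    laser_line = 1
  )
}

#' Band-limited multiplicative albedo texture
#' @keywords internal
texture_field <- function(n_row, n_col, pitch, amp, scale_mm, seed) {
  if (amp <= 0) return(matrix(1, n_row, n_col))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  z <- matrix(stats::rnorm(n_row * n_col), n_row, n_col)
  sig_px <- scale_mm / pitch / 2
  z <- EBImage::gblur(z, sigma = sig_px)
  z <- z / stats::sd(z)
  pmax(1 + amp * z, 0.05)
}

#' Radiometric components of a rendered frame
#'
#' Computes the three irradiance components at the camera, before polarizer
#' and filter gains, noise and quantization. Used by [render_frame()] and
#' directly when analysing the photometric model.
#'
#' @param surface A [surface_map()].
#' @param geom A [projection_geometry()].
#' @param scene A [photometric_scene()].
#' @return List of matrices `direct`, `scatter`, `background` (the latter a
#'   scalar irradiance level replicated on demand), plus the ground-truth
#'   phase `dphi`.
#' @export
render_components <- function(surface, geom, scene) {
  stopifnot(inherits(surface, "surface_map"),
            inherits(geom, "projection_geometry"),
            inherits(scene, "photometric_scene"))
  n <- surface$nrow
  m <- surface$ncol
  pitch <- surface$pitch
  x <- (seq_len(m) - (m + 1) / 2) * pitch
  dphi <- phase_modulation(surface, geom)$values
  carrier <- matrix(rep(2 * pi * geom$f0 * x, each = n), n, m)
  proj <- scene$laser_power * (0.5 + 0.5 * cos(carrier + dphi))
  tex <- texture_field(n, m, pitch, scene$texture_amp, scene$texture_scale,
                       scene$texture_seed)
  direct <- scene$direct_albedo * tex * proj
  scat <- scene$scatter_fraction * tex *
    EBImage::gblur(proj, sigma = scene$scatter_sigma / pitch)
  bg <- scene$background_lux / scene$lux_per_peak
  list(direct = direct, scatter = scat, background = bg, dphi = dphi)
}

#' Render a one-shot camera frame of projected fringes
#'
#' Applies the three-component photometric model: the polarized direct
#' reflection of the sinusoidal carrier phase-modulated by the surface, the
#' unpolarized blurred subsurface-scatter component, and the unpolarized
#' broadband background, each weighted by the camera's polarizer and filter
#' gains; then auto-exposure on the fringe signal, photon and read noise, and
#' quantization. Saturated pixels are clipped and their fraction reported.
#'
#' @param surface A [surface_map()].
#' @param geom A [projection_geometry()].
#' @param scene A [photometric_scene()].
#' @param camera A [camera_model()].
#' @param rng_seed Integer seed for the noise realization (default 1).
#' @return An object of class `camera_frame`: `pixels` (matrix in `[0, 1]`,
#'   quantized to `bit_depth` levels unless `bit_depth` is `NA`), `pitch`,
#'   and `meta` (full-scale irradiance, clipped fraction, seed, gains).
#' @export
render_frame <- function(surface, geom, scene, camera = camera_model(),
                         rng_seed = 1) {
  comp <- render_components(surface, geom, scene)
  g <- camera_gains(camera)
  signal <- g$direct * comp$direct + g$unpolarized * comp$scatter
  total <- signal + g$unpolarized * g$background_band * comp$background
  full_scale <- camera$exposure_headroom * max(signal)
  if (camera$shot_noise > 0 || camera$read_noise > 0) {
    set.seed(as.integer(rng_seed) %% .Machine$integer.max)
    sd_mat <- sqrt(camera$shot_noise^2 * pmax(total, 0) * full_scale +
                     (camera$read_noise * full_scale)^2)
    total <- total + matrix(stats::rnorm(length(total), sd = 1), nrow(total)) *
      sd_mat
  }
  rel <- total / full_scale
  clipped <- mean(rel > 1)
  rel <- pmin(pmax(rel, 0), 1)
  if (!is.na(camera$bit_depth)) {
    levels <- 2^camera$bit_depth - 1
    rel <- round(rel * levels) / levels
  }
  structure(list(pixels = rel, pitch = surface$pitch,
                 meta = list(full_scale = full_scale,
                             clipped_fraction = clipped,
                             rng_seed = rng_seed,
                             gains = g,
                             f0 = geom$f0,
                             bit_depth = camera$bit_depth)),
            class = "camera_frame")
}

#' @export
print.camera_frame <- function(x, ...) {
  cat(sprintf("<camera_frame> %d x %d, pitch %g mm, carrier %.3g /mm, %.2f%% clipped\n",
              nrow(x$pixels), ncol(x$pixels), x$pitch, x$meta$f0,
              100 * x$meta$clipped_fraction))
  invisible(x)
}
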