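#' Optical setup of the sinusoidal fringe projector
#'
#' Describes the projector train: a monochromatic point/collimated laser
#' source, a binary (rectangular) transmission grating at plane P0, a
#' Fourier-transform lens at P1, a spatial-frequency filter at P2 and the
#' observation plane P3. All lengths are in millimetres, the wavelength in
#' nanometres.
#'
#' The defaults describe the experimental projector: a 532 nm laser, a
#' 50 lp/mm grating (period 0.02 mm, 50% duty), a 150 mm Fourier lens and a
#' 0.5 mm slit filter passing the first diffraction orders. `z3` defaults to
#' the projection distance at which the fringe pattern on the reference plane
#' has a spatial frequency of 1.0 lp/mm.
#'
#' The closed-form fringe pattern (see [closed_form_fringe()]) is exact when
#' the filter sits in the plane where the grating orders focus, i.e. the image
#' plane of the source: `z2 = f * (z0 + z1) / z0`, which reduces to the back
#' focal plane `z2 = f` for collimated illumination (`z0 = Inf`), together
#' with `z1 = f` (which makes the order positions `m * lambda * f / d`
#' independent of the source distance). The returned object records whether
#' this Fourier-plane condition holds in `$fourier_plane`.
#'
#' @param wavelength Laser wavelength in nm.
#' @param grating_period Grating period `d` in mm (default 0.02 mm = 50 lp/mm).
#' @param grating_slit Grating slit (transmitting) width `a` in mm,
#'   `0 < a < d`; default `d/2` (50% duty cycle).
#' @param focal_length Focal length `f` of the Fourier lens in mm.
#' @param illum_diameter Diameter `H` of the laser spot on the grating in mm.
#' @param z0 Source-to-grating distance in mm; `Inf` for collimated
#'   illumination (the default).
#' @param z1 Grating-to-lens distance in mm; default `f`.
#' @param z2 Lens-to-filter distance in mm; default `f * (z0 + z1) / z0`,
#'   the source image plane (so the Fourier-plane condition holds).
#' @param z3 Filter-to-observation distance in mm.
#' @param filter_order Diffraction order `m` selected by the filter.
#' @param filter_slit_width Width of each filter slit in mm.
#'
#' @return An object of class `optical_setup`.
#' @examples
#' setup <- optical_setup()
#' setup$fringe_frequency  # intensity fringes on the observation plane, 1/mm
#' @export
optical_setup <- function(wavelength = 532,
                          grating_period = 0.02,
                          grating_slit = grating_period / 2,
                          focal_length = 150,
                          illum_diameter = 2,
                          z0 = Inf,
                          z1 = focal_length,
                          z2 = focal_length * (z0 + z1) / z0,
                          z3 = 2 * focal_length / (grating_period * 1.0),
                          filter_order = 1L,
                          filter_slit_width = 0.5) {
  if (is.infinite(z0)) z2 <- if (missing(z2)) focal_length else z2
  num_pos <- function(x, name, allow_inf = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
        x <= 0 || (!allow_inf && !is.finite(x))) {
      stop("`", name, "` must be a single positive finite number", call. = FALSE)
    }
  }
  num_pos(wavelength, "wavelength")
  num_pos(grating_period, "grating_period")
  num_pos(grating_slit, "grating_slit")
  num_pos(focal_length, "focal_length")
  num_pos(illum_diameter, "illum_diameter")
  num_pos(z0, "z0", allow_inf = TRUE)
  num_pos(z1, "z1")
  num_pos(z2, "z2")
  num_pos(z3, "z3")
  num_pos(filter_slit_width, "filter_slit_width")
  if (grating_slit >= grating_period) {
    stop("`grating_slit` must be smaller than `grating_period` (a < d)",
         call. = FALSE)
  }
  filter_order <- as.integer(filter_order)
  if (filter_order < 1L) stop("`filter_order` must be >= 1", call. = FALSE)

  lambda_mm <- wavelength * 1e-6
  # source image plane behind the lens (order focus plane); = f when z0 = Inf
  z2_fourier <- if (is.infinite(z0)) focal_length else {
    focal_length * (z0 + z1) / z0
  }
  fourier_plane <- isTRUE(abs(z1 - focal_length) <= 1e-9 * focal_length &&
                            abs(z2 - z2_fourier) <= 1e-6 * z2_fourier)

  out <- list(
    wavelength = wavelength,
    lambda_mm = lambda_mm,
    k = 2 * pi / lambda_mm,
    grating_period = grating_period,
    grating_slit = grating_slit,
    duty = grating_slit / grating_period,
    focal_length = focal_length,
    illum_diameter = illum_diameter,
    z0 = z0, z1 = z1, z2 = z2, z3 = z3,
    z2_fourier = z2_fourier,
    fourier_plane = fourier_plane,
    filter_order = filter_order,
    filter_slit_width = filter_slit_width,
    # positions of the +/-m order foci in the filter plane (mm)
    order_position = filter_order * lambda_mm * focal_length / grating_period,
    # intensity fringe frequency on the observation plane (cycles/mm):
    # the squared cosine doubles the field-cosine frequency f/(d*Z3)
    fringe_frequency = 2 * focal_length / (grating_period * z3),
    # radius of the projected fringe disc on the observation plane (mm)
    fringe_radius = illum_diameter * z3 / (2 * focal_length)
  )
  class(out) <- "optical_setup"
  out
}

#' Reduced-scale projector geometry for numerical validation
#'
#' The experimental projector (50 lp/mm grating, 150 mm lens) separates the
#' first diffraction orders by ~4 mm in the Fourier plane and needs a
#' metre-scale projection distance before the two order beams overlap, which
#' cannot be held on a single FFT grid that also resolves the 0.02 mm grating
#' period. This preset keeps the same physics at bench scale (20 lp/mm,
#' f = 25 mm, collimated 1 mm spot) so the full numeric diffraction chain fits
#' a 2048 x 2048 grid alias-free and can be compared against the closed form.
#'
#' @param z3 Filter-to-observation distance in mm (default 100).
#' @param ... Overrides passed to [optical_setup()].
#' @return An `optical_setup` object.
#' @export
bench_setup <- function(z3 = 100, ...) {
  optical_setup(wavelength = 532,
                grating_period = 0.05,
                grating_slit = 0.025,
                focal_length = 25,
                illum_diameter = 1,
                z0 = Inf,
                z3 = z3,
                filter_slit_width = 0.1,
                ...)
}

#' @export
print.optical_setup <- function(x, ...) {
  cat("<optical_setup>\n")
  cat(sprintf("  wavelength    : %g nm\n", x$wavelength))
  cat(sprintf("  grating       : period %g mm (%.4g lp/mm), slit %g mm (duty %.2f)\n",
              x$grating_period, 1 / x$grating_period, x$grating_slit, x$duty))
  cat(sprintf("  lens          : f = %g mm\n", x$focal_length))
  cat(sprintf("  illumination  : diameter %g mm, z0 = %g mm\n",
              x$illum_diameter, x$z0))
  cat(sprintf("  planes        : z1 = %g, z2 = %g, z3 = %g mm\n",
              x$z1, x$z2, x$z3))
  cat(sprintf("  filter        : +/-%d orders at +/-%.4g mm, slit width %g mm\n",
              x$filter_order, x$order_position, x$filter_slit_width))
  cat(sprintf("  Fourier plane : %s (source image at z2 = %.4g mm)\n",
              if (x$fourier_plane) "asserted" else "NOT asserted", x$z2_fourier))
  cat(sprintf("  output        : %.4g fringes/mm over radius %.4g mm at P3\n",
              x$fringe_frequency, x$fringe_radius))
  invisible(x)
}
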