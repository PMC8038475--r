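#' Optical field right behind the grating (plane P0)
#'
#' Builds the illumination field (a spherical wave from a point source at
#' distance `z0`, or a unit plane wave for collimated illumination) multiplied
#' by the binary grating transmission and windowed by the circular laser spot
#' of diameter `H`. The grating is a rect-comb with period `d` and slit width
#' `a` (duty `a/d`), slits centred on `x = 0`; each sample holds the exact
#' area fraction of the sample cell covered by a slit, which suppresses
#' aliasing of the high grating harmonics.
#'
#' @param setup An [optical_setup()].
#' @param n Grid side (power of two), default 2048.
#' @param pitch Sample spacing in mm; default `grating_period / 8`, the
#'   coarsest spacing accepted.
#' @return A [sampled_field()] at plane `"P0"`.
#' @export
grating_transmission <- function(setup, n = 2048,
                                 pitch = setup$grating_period / 8) {
  stopifnot(inherits(setup, "optical_setup"))
  d <- setup$grating_period
  a <- setup$grating_slit
  H <- setup$illum_diameter
  if (pitch > d / 8 + 1e-12) {
    stop(sprintf(paste0("sampling too coarse for the grating: pitch %g mm ",
                        "gives %.2f samples per period d = %g mm; ",
                        "at least 8 are required (pitch <= %g mm)"),
                 pitch, d / pitch, d, d / 8), call. = FALSE)
  }
  if (H >= n * pitch) {
    stop(sprintf("illumination spot H = %g mm does not fit the grid extent %g mm",
                 H, n * pitch), call. = FALSE)
  }
  x <- grid_axis(n, pitch)
  # area-weighted binary grating: fraction of [x - pitch/2, x + pitch/2]
  # covered by slits of width a centred at multiples of d
  slit_measure <- function(x) {
    y <- x + a / 2
    per <- floor(y / d)
    a * per + pmin(a, pmax(0, y - d * per))
  }
  t_x <- (slit_measure(x + pitch / 2) - slit_measure(x - pitch / 2)) / pitch

  amp <- matrix(complex(real = rep(t_x, each = n)), n, n)
  r2 <- outer(x^2, x^2, "+")  # rows y, cols x
  if (is.finite(setup$z0)) {
    illum <- exp(1i * setup$k * setup$z0) / setup$z0 *
      exp(1i * setup$k * r2 / (2 * setup$z0))
    amp <- amp * illum
  }
  amp[r2 > (H / 2)^2] <- 0
  sampled_field(amp, pitch, "P0")
}

#' Fresnel propagation of a sampled field
#'
#' Propagates the field by `distance` with the Fresnel transfer function
#' (angular-spectrum kernel `exp(-i pi lambda z f^2)`), applied in the
#' frequency domain. The kernel is band-limited to the region where its
#' discretely sampled phase is alias-free, `|fx|, |fy| <= n*pitch/(2*lambda*z)`
#' (for `z <= n*pitch^2/lambda` this is the whole grid and the propagator is
#' exactly unitary). Spectral power falling outside the alias-free band is
#' removed; if that clipped fraction exceeds `band_tol` the propagation is
#' rejected with an error naming the maximal safe distance for the field's
#' occupied bandwidth.
#'
#' @param field A [sampled_field()].
#' @param distance Propagation distance in mm (> 0).
#' @param wavelength Wavelength in nm.
#' @param band_tol Maximal tolerated out-of-band power fraction (default
#'   0.01).
#' @param plane_label Label for the output plane (default kept).
#' @return A [sampled_field()] with attribute `"clipped_power"` holding the
#'   removed power fraction.
#' @export
fresnel_propagate <- function(field, distance, wavelength,
                              band_tol = 0.01, plane_label = field$plane_label) {
  stopifnot(inherits(field, "sampled_field"))
  if (!is.numeric(distance) || length(distance) != 1L || !is.finite(distance) ||
      distance <= 0) {
    stop("`distance` must be a single positive number (mm)", call. = FALSE)
  }
  lam <- wavelength * 1e-6
  n <- field$n
  pitch <- field$pitch
  f <- freq_axis(n, pitch)
  F2 <- outer(f^2, f^2, "+")  # rows fy, cols fx

  spec <- stats::fft(field$amplitude)
  f_lim <- n * pitch / (2 * lam * distance)  # alias-free kernel half-band
  clipped <- 0
  if (f_lim < max(abs(f))) {
    inband <- outer(abs(f) <= f_lim, abs(f) <= f_lim, "&")
    p_tot <- sum(Mod(spec)^2)
    p_out <- sum(Mod(spec[!inband])^2)
    clipped <- if (p_tot > 0) p_out / p_tot else 0
    if (clipped > band_tol) {
      # largest |f| needed to keep all but band_tol of the power
      mx <- as.vector(outer(abs(f), abs(f), pmax))
      o <- order(mx)
      cum <- cumsum((Mod(spec)^2)[o])
      f_need <- mx[o][which(cum >= (1 - band_tol) * p_tot)[1]]
      z_max <- n * pitch / (2 * lam * f_need)
      stop(sprintf(paste0("Fresnel propagation over %g mm would alias: %.3g%% ",
                          "of the spectral power lies outside the alias-free ",
                          "band (tolerance %g%%). Maximal safe distance for ",
                          "this field and grid: %.4g mm"),
                   distance, 100 * clipped, 100 * band_tol, z_max),
           call. = FALSE)
    }
    spec[!inband] <- 0
  }
  kernel <- exp(1i * 2 * pi * distance / lam) *
    exp(-1i * pi * lam * distance * F2)
  out <- stats::fft(spec * kernel, inverse = TRUE) / n^2
  res <- sampled_field(out, pitch, plane_label)
  attr(res, "clipped_power") <- clipped
  res
}

#' Thin-lens transmission
#'
#' Pointwise multiplication by the lens phase
#' `exp(-i k (x^2 + y^2) / (2 f))`; the amplitude is unchanged.
#'
#' @param field A [sampled_field()] at the lens plane.
#' @param focal_length Focal length in mm.
#' @param wavelength Wavelength in nm.
#' @return A [sampled_field()].
#' @export
lens_transmit <- function(field, focal_length, wavelength) {
  stopifnot(inherits(field, "sampled_field"))
  lam <- wavelength * 1e-6
  k <- 2 * pi / lam
  x <- grid_axis(field$n, field$pitch)
  r2 <- outer(x^2, x^2, "+")
  sampled_field(field$amplitude * exp(-1i * k * r2 / (2 * focal_length)),
                field$pitch, field$plane_label)
}

#' Closed-form spectrum in the filter plane
#'
#' Evaluates the analytic field profile along the x axis of the Fourier
#' (filter) plane: a sum over grating orders m of `sinc(a m / d)`-weighted
#' Airy-type lobes `J1(pi H (fx - m/d)) / (fx - m/d)` centred at spatial
#' frequency `fx = m/d`, i.e. at physical positions `x2 = m lambda f / d`.
#' The overall complex constant is not tracked; only relative magnitudes are
#' meaningful.
#'
#' @param setup An [optical_setup()]; the Fourier-plane condition must be
#'   asserted.
#' @param x2 Positions in the filter plane (mm) at which to evaluate.
#' @param max_order Highest order included in the sum (default 25).
#' @return Complex vector of relative field values.
#' @export
closed_form_spectrum <- function(setup, x2, max_order = 25) {
  stopifnot(inherits(setup, "optical_setup"))
  if (!setup$fourier_plane) {
    stop("closed-form spectrum requires the Fourier-plane condition ",
         "(z1 = f and z2 at the source image plane)", call. = FALSE)
  }
  d <- setup$grating_period
  H <- setup$illum_diameter
  fx <- x2 / (setup$lambda_mm * setup$focal_length)
  out <- complex(length.out = length(fx))
  sinc <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))
  for (m in -max_order:max_order) {
    w <- sinc(setup$duty * m)
    if (abs(w) < 1e-12) next
    u <- fx - m / d
    # J1 is odd, so J1(pi H u)/u is even in u; evaluate on |u|
    lobe <- ifelse(abs(u) < 1e-9, pi * H / 2,
                   besselJ(pi * H * abs(u), 1) / abs(u))
    out <- out + w * lobe
  }
  out
}

#' Spatial-frequency filtering at plane P2
#'
#' Zeroes the field outside two vertical slit windows of width
#' `filter_slit_width` centred on the `+m` and `-m` order positions
#' `x2 = +/- m lambda f / d`; everything else, including the strong zero
#' order, is removed.
#'
#' @param field A [sampled_field()] at the filter plane.
#' @param setup An [optical_setup()].
#' @param orders Which of the two selected orders to pass: a subset of
#'   `c(-1, 1)` (in units of the filter order `m`); default both.
#' @return A [sampled_field()].
#' @export
spatial_filter <- function(field, setup, orders = c(-1, 1)) {
  stopifnot(inherits(field, "sampled_field"),
            inherits(setup, "optical_setup"))
  if (!all(orders %in% c(-1, 1)) || length(orders) < 1) {
    stop("`orders` must be a non-empty subset of c(-1, 1)", call. = FALSE)
  }
  xm <- setup$order_position
  w <- setup$filter_slit_width
  if (xm - w / 2 <= w / 2) {
    stop(sprintf(paste0("filter slits of width %g mm at +/-%.4g mm overlap the ",
                        "zero order; orders are not separable at this geometry"),
                 w, xm), call. = FALSE)
  }
  x <- grid_axis(field$n, field$pitch)
  keep <- rep(FALSE, field$n)
  for (s in orders) keep <- keep | abs(x - s * xm) <= w / 2
  amp <- field$amplitude
  amp[, !keep] <- 0
  sampled_field(amp, field$pitch, field$plane_label)
}

#' Fringe pattern container
#' @keywords internal
fringe_pattern <- function(intensity, pitch, setup, source) {
  structure(list(intensity = intensity,
                 pitch = pitch,
                 n = nrow(intensity),
                 predicted_intensity_frequency = setup$fringe_frequency,
                 predicted_radius = setup$fringe_radius,
                 source = source,
                 setup = setup),
            class = "fringe_pattern")
}

#' @export
print.fringe_pattern <- function(x, ...) {
  cat(sprintf("<fringe_pattern> %d x %d (%s), pitch %g mm; predicted %.4g fringes/mm over radius %.4g mm\n",
              x$n, x$n, x$source, x$pitch,
              x$predicted_intensity_frequency, x$predicted_radius))
  invisible(x)
}

#' Closed-form projected fringe pattern
#'
#' Evaluates the analytic two-beam output pattern on the observation plane:
#' intensity `Ca^2 cos^2(2 pi f x3 / (d z3))` inside the circle of radius
#' `H z3 / (2 f)` and zero outside, where
#' `Ca = 2 f / (z0 z3 pi) * sin(a pi / d)` (the `1/z0` factor is dropped for
#' collimated illumination, where the incident amplitude is taken as unity).
#'
#' @param setup An [optical_setup()] with the Fourier-plane condition
#'   asserted.
#' @param n Grid side, default 2048.
#' @param pitch Sample spacing in mm; default sized so the fringe disc spans
#'   ~70% of the grid.
#' @return A `fringe_pattern` with fields `intensity`, `pitch`,
#'   `predicted_intensity_frequency` (`2 f / (d z3)`, cycles/mm) and
#'   `predicted_radius` (mm).
#' @export
closed_form_fringe <- function(setup, n = 2048,
                               pitch = 2 * setup$fringe_radius / (0.7 * n)) {
  stopifnot(inherits(setup, "optical_setup"))
  if (!setup$fourier_plane) {
    stop("closed-form fringe requires the Fourier-plane condition ",
         "(z1 = f and z2 at the source image plane)", call. = FALSE)
  }
  ca <- 2 * setup$focal_length / (setup$z3 * pi) *
    sin(setup$grating_slit * pi / setup$grating_period)
  if (is.finite(setup$z0)) ca <- ca / setup$z0
  x <- grid_axis(n, pitch)
  fcos <- setup$focal_length / (setup$grating_period * setup$z3)  # field cosine
  prof <- ca^2 * cos(2 * pi * fcos * x)^2
  intens <- matrix(rep(prof, each = n), n, n)
  r2 <- outer(x^2, x^2, "+")
  intens[r2 > setup$fringe_radius^2] <- 0
  fringe_pattern(intens, pitch, setup, "closed_form")
}

#' Simulate the projected fringe pattern by the full diffraction chain
#'
#' Runs the numeric scalar-diffraction chain
#' grating (P0) -> Fresnel z1 -> lens -> Fresnel z2 -> spatial filter (P2)
#' -> Fresnel z3 -> observation plane (P3) and returns the output intensity.
#' Per-step power and band-clipping diagnostics are recorded in
#' `$diagnostics`.
#'
#' @param setup An [optical_setup()].
#' @param n Grid side, default 2048.
#' @param pitch Sample spacing in mm, default `grating_period / 8`.
#' @param band_tol Out-of-band power tolerance per propagation step; the
#'   default 0.05 accommodates the high grating harmonics that the filter
#'   plane discards anyway.
#' @param orders Orders passed by the filter, see [spatial_filter()].
#' @return A `fringe_pattern` (source `"numeric"`) with `$diagnostics`.
#' @export
simulate_fringe_numeric <- function(setup, n = 2048,
                                    pitch = setup$grating_period / 8,
                                    band_tol = 0.05, orders = c(-1, 1)) {
  stopifnot(inherits(setup, "optical_setup"))
  lam_nm <- setup$wavelength
  diag <- list()
  u0 <- grating_transmission(setup, n = n, pitch = pitch)
  diag$power_P0 <- field_power(u0)
  u1p <- fresnel_propagate(u0, setup$z1, lam_nm, band_tol, "P1")
  diag$clip_z1 <- attr(u1p, "clipped_power")
  u1 <- lens_transmit(u1p, setup$focal_length, lam_nm)
  u2p <- fresnel_propagate(u1, setup$z2, lam_nm, band_tol, "P2")
  diag$clip_z2 <- attr(u2p, "clipped_power")
  diag$power_P2_prefilter <- field_power(u2p)
  u2 <- spatial_filter(u2p, setup, orders = orders)
  diag$power_P2_postfilter <- field_power(u2)
  diag$filter_pass_fraction <- diag$power_P2_postfilter / diag$power_P2_prefilter
  u3 <- fresnel_propagate(u2, setup$z3, lam_nm, band_tol, "P3")
  diag$clip_z3 <- attr(u3, "clipped_power")
  diag$power_P3 <- field_power(u3)
  out <- fringe_pattern(field_intensity(u3), pitch, setup, "numeric")
  out$diagnostics <- diag
  out
}

#' Measure the fringe frequency of an intensity pattern
#'
#' Averages the intensity over rows near the pattern centre, subtracts the
#' mean, applies a Hann window and locates the dominant non-DC peak of the
#' FFT magnitude, refined to sub-bin accuracy by a local centroid.
#'
#' @param pattern A `fringe_pattern`, or an intensity matrix (then `pitch`
#'   must be given).
#' @param pitch Sample spacing in mm (taken from the pattern if missing).
#' @param band_rows Half-width of the row band averaged, as a fraction of the
#'   grid (default 0.05).
#' @return Measured intensity-fringe frequency in cycles/mm.
#' @export
measure_fringe_frequency <- function(pattern, pitch = NULL, band_rows = 0.05) {
  if (inherits(pattern, "fringe_pattern")) {
    intens <- pattern$intensity
    pitch <- pattern$pitch
  } else {
    intens <- pattern
    if (is.null(pitch)) stop("`pitch` required for a bare matrix", call. = FALSE)
  }
  n <- nrow(intens)
  mid <- n / 2 + 1
  hw <- max(1L, round(band_rows * n))
  prof <- colMeans(intens[(mid - hw):(mid + hw), , drop = FALSE])
  # keep only the illuminated part of the profile so the disc envelope does
  # not dominate the spectrum
  nz <- which(prof > 0.01 * max(prof))
  prof <- prof[min(nz):max(nz)]
  m <- length(prof)
  prof <- prof - mean(prof)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(m) - 1) / (m - 1))
  sp <- Mod(stats::fft(prof * w))[1:(m %/% 2)]
  sp[1:2] <- 0
  pk <- which.max(sp)
  # centroid refinement over +/-2 bins
  idx <- max(2, pk - 2):min(length(sp), pk + 2)
  centroid <- sum((idx - 1) * sp[idx]) / sum(sp[idx])
  centroid / (m * pitch)
}

#' Normalized cross-correlation of two fringe patterns over the central disc
#'
#' Pearson correlation of the two intensity grids over the region within
#' `fraction` of the predicted fringe radius of the pattern centre.
#'
#' @param a,b `fringe_pattern`s on identical grids.
#' @param fraction Radius fraction defining the comparison disc (default 0.5,
#'   the central half-radius).
#' @return Correlation in `[-1, 1]`.
#' @export
fringe_correlation <- function(a, b, fraction = 0.5) {
  stopifnot(inherits(a, "fringe_pattern"), inherits(b, "fringe_pattern"),
            a$n == b$n)
  if (abs(a$pitch - b$pitch) > 1e-12 * a$pitch) {
    stop("patterns are on different grids", call. = FALSE)
  }
  x <- grid_axis(a$n, a$pitch)
  r2 <- outer(x^2, x^2, "+")
  sel <- r2 <= (fraction * a$predicted_radius)^2
  stats::cor(a$intensity[sel], b$intensity[sel])
}
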