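#' Surface heightmap container
#'
#' Heights in mm relative to the flat reference plane, on a uniform grid.
#' Rows index y, columns index x; `mask` marks the object region (heights are
#' zero on the reference plane outside it).
#'
#' @param heights Numeric matrix of heights (mm).
#' @param pitch Pixel pitch in mm.
#' @param mask Logical matrix of the same shape; default `heights != 0`.
#' @return An object of class `surface_map`.
#' @export
surface_map <- function(heights, pitch, mask = heights != 0) {
  if (!is.matrix(heights) || !all(is.finite(heights))) {
    stop("`heights` must be a finite numeric matrix", call. = FALSE)
  }
  if (!is.numeric(pitch) || length(pitch) != 1L || pitch <= 0) {
    stop("`pitch` must be a single positive number (mm)", call. = FALSE)
  }
  stopifnot(is.logical(mask), all(dim(mask) == dim(heights)))
  structure(list(heights = heights, pitch = pitch, mask = mask,
                 nrow = nrow(heights), ncol = ncol(heights)),
            class = "surface_map")
}

#' @export
print.surface_map <- function(x, ...) {
  cat(sprintf("<surface_map> %d x %d, pitch %g mm, peak height %.3g mm, %.1f%% masked in\n",
              x$nrow, x$ncol, x$pitch, max(x$heights), 100 * mean(x$mask)))
  invisible(x)
}

#' Spherical-cap phantom surface
#'
#' A spherical cap of base radius `base_radius` and apex height `cap_height`
#' above the reference plane, the geometry of a skin-mimicking silicone test
#' object: the cap belongs to a sphere of radius
#' `R = (base_radius^2 + cap_height^2) / (2 cap_height)`.
#'
#' @param base_radius Radius of the base circle in mm.
#' @param cap_height Apex height in mm (`0 < cap_height <= R`).
#' @param pitch Pixel pitch in mm.
#' @param extent Physical side length of the grid in mm; default 2.4x the
#'   base radius (the cap surrounded by reference plane).
#' @return A [surface_map()].
#' @examples
#' cap <- make_spherical_cap(40, 10, pitch = 0.25)
#' max(cap$heights)  # 10
#' @export
make_spherical_cap <- function(base_radius, cap_height, pitch,
                               extent = 2.4 * base_radius) {
  if (!is.numeric(cap_height) || cap_height <= 0) {
    stop("nonphysical geometry: `cap_height` must be positive", call. = FALSE)
  }
  if (!is.numeric(base_radius) || base_radius <= 0) {
    stop("nonphysical geometry: `base_radius` must be positive", call. = FALSE)
  }
  R <- (base_radius^2 + cap_height^2) / (2 * cap_height)
  if (cap_height > R) {
    stop("nonphysical geometry: cap higher than its sphere radius", call. = FALSE)
  }
  n <- max(16L, round(extent / pitch))
  ax <- (seq_len(n) - (n + 1) / 2) * pitch
  r2 <- outer(ax^2, ax^2, "+")
  h <- sqrt(pmax(R^2 - r2, 0)) - (R - cap_height)
  inside <- r2 < base_radius^2
  h[!inside | h < 0] <- 0
  surface_map(h, pitch, mask = inside & h > 0)
}

#' Procedural face-like phantom surface
#'
#' A deterministic, C1-smooth heightmap with face-scale features (brow,
#' cheeks, nose ridge, chin, shallow eye sockets) built from Gaussian bumps
#' on a raised-cosine dome, with seed-controlled jitter of feature positions
#' and widths. Feature widths are chosen so local surface slopes stay below
#' ~0.7, keeping the phase modulation of a projected carrier inside the
#' spectral band that one-shot Fourier-transform profilometry can separate.
#'
#' @param seed Integer seed; the surface is a pure function of
#'   `(seed, pitch, extent, amplitude)`.
#' @param pitch Pixel pitch in mm.
#' @param extent Physical side length in mm (default 150, face scale).
#' @param amplitude Peak height in mm (default 30; 0 gives the flat
#'   reference plane).
#' @return A [surface_map()].
#' @export
make_face_phantom <- function(seed, pitch, extent = 150, amplitude = 30) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  n <- max(16L, round(extent / pitch))
  ax <- (seq_len(n) - (n + 1) / 2) * pitch
  X <- matrix(rep(ax, each = n), n, n)     # x along columns
  Y <- matrix(rep(rev(ax), times = n), n, n)
  if (amplitude == 0) {
    return(surface_map(matrix(0, n, n), pitch,
                       mask = matrix(FALSE, n, n)))
  }
  rng <- local({ set.seed(as.integer(seed) %% .Machine$integer.max)
    stats::runif(40, -1, 1) })
  j <- function(i, scale) rng[i] * scale

  gauss <- function(x0, y0, sx, sy, a, theta = 0) {
    xr <- (X - x0) * cos(theta) + (Y - y0) * sin(theta)
    yr <- -(X - x0) * sin(theta) + (Y - y0) * cos(theta)
    a * exp(-0.5 * (xr / sx)^2 - 0.5 * (yr / sy)^2)
  }
  w <- extent / 150  # feature scale relative to a 150 mm face
  h <- gauss(0, j(1, 3) * w, 38 * w * (1 + 0.1 * j(2, 1)),
             50 * w * (1 + 0.1 * j(3, 1)), 0.55)            # head dome
  h <- h + gauss(j(4, 2) * w, -8 * w, 7 * w, 22 * w * (1 + 0.1 * j(5, 1)),
                 0.45)                                       # nose ridge
  h <- h + gauss(j(6, 2) * w, -26 * w, 9 * w, 6 * w, 0.18)   # nose tip
  h <- h + gauss(0, 28 * w + j(7, 2) * w, 30 * w, 9 * w, 0.22)  # brow
  h <- h + gauss(-24 * w + j(8, 2) * w, -18 * w, 14 * w, 16 * w, 0.28)  # cheek L
  h <- h + gauss(24 * w + j(9, 2) * w, -18 * w, 14 * w, 16 * w, 0.28)   # cheek R
  h <- h + gauss(j(10, 2) * w, -52 * w, 12 * w, 9 * w, 0.25)  # chin
  h <- h - gauss(-16 * w, 12 * w + j(11, 2) * w, 8 * w, 5 * w, 0.12)  # socket L
  h <- h - gauss(16 * w, 12 * w + j(12, 2) * w, 8 * w, 5 * w, 0.12)   # socket R

  # raised-cosine window confining the face to an ellipse on the plane
  rx <- 0.42 * extent
  ry <- 0.48 * extent
  rho <- sqrt((X / rx)^2 + (Y / ry)^2)
  win <- ifelse(rho >= 1, 0, 0.5 + 0.5 * cos(pi * pmin(rho, 1)))
  h <- h * win
  # final smoothing keeps local slopes below ~0.6 so the phase modulation of
  # a projected carrier stays inside the separable spectral band
  h <- EBImage::gblur(h, sigma = max(1, (extent / 25) / pitch))
  h <- pmax(h, 0)
  h <- h * (amplitude / max(h))
  surface_map(h, pitch, mask = h > 1e-3 * amplitude)
}

#' Rigid in-plane motion of a surface
#'
#' Translates and rotates the heightmap in its plane (bilinear resampling;
#' points sampled from outside the grid take the reference-plane height 0).
#' Used to emulate a moving subject between one-shot frames.
#'
#' @param surface A [surface_map()].
#' @param dx,dy Translation in mm.
#' @param angle Rotation about the grid centre in radians.
#' @return A [surface_map()].
#' @export
shift_surface <- function(surface, dx = 0, dy = 0, angle = 0) {
  stopifnot(inherits(surface, "surface_map"))
  n <- surface$nrow
  m <- surface$ncol
  ax_x <- (seq_len(m) - (m + 1) / 2) * surface$pitch
  ax_y <- (seq_len(n) - (n + 1) / 2) * surface$pitch
  X <- matrix(rep(ax_x, each = n), n, m)
  Y <- matrix(rep(ax_y, times = m), n, m)
  # source coordinates (inverse transform)
  Xs <- cos(angle) * (X - dx) + sin(angle) * (Y - dy)
  Ys <- -sin(angle) * (X - dx) + cos(angle) * (Y - dy)
  ci <- (Xs - ax_x[1]) / surface$pitch + 1
  ri <- (Ys - ax_y[1]) / surface$pitch + 1
  bilinear <- function(z, ri, ci) {
    r0 <- floor(ri); c0 <- floor(ci)
    fr <- ri - r0; fc <- ci - c0
    val <- function(r, c) {
      ok <- r >= 1 & r <= n & c >= 1 & c <= m
      out <- numeric(length(r))
      out[ok] <- z[cbind(r[ok], c[ok])]
      out
    }
    val(r0, c0) * (1 - fr) * (1 - fc) + val(r0 + 1, c0) * fr * (1 - fc) +
      val(r0, c0 + 1) * (1 - fr) * fc + val(r0 + 1, c0 + 1) * fr * fc
  }
  h <- matrix(bilinear(surface$heights, as.vector(ri), as.vector(ci)), n, m)
  surface_map(h, surface$pitch, mask = h > 1e-6 * max(abs(h) + 1e-12))
}
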