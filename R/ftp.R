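#' Phase map container
#'
#' A 2D phase field in radians with carrier metadata. Wrapped maps have
#' values in `(-pi, pi]`.
#'
#' @param values Numeric matrix of phases (radians).
#' @param state `"wrapped"` or `"unwrapped"`.
#' @param f0 Carrier frequency in cycles/mm.
#' @param pitch Pixel pitch in mm.
#' @param axis Carrier axis (`"x"` = columns).
#' @param mask Logical matrix of valid pixels (default all).
#' @return An object of class `phase_map`.
#' @export
phase_map <- function(values, state = c("wrapped", "unwrapped"), f0, pitch,
                      axis = "x", mask = NULL) {
  state <- match.arg(state)
  stopifnot(is.matrix(values))
  if (state == "wrapped" &&
      any(values[is.finite(values)] > pi + 1e-9 |
            values[is.finite(values)] <= -pi - 1e-9)) {
    stop("wrapped phase values must lie in (-pi, pi]", call. = FALSE)
  }
  if (is.null(mask)) mask <- is.finite(values)
  structure(list(values = values, state = state, f0 = f0, pitch = pitch,
                 axis = axis, mask = mask),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map> %d x %d (%s), carrier %.3g /mm along %s, pitch %g mm\n",
              nrow(x$values), ncol(x$values), x$state, x$f0, x$axis, x$pitch))
  invisible(x)
}

#' Wrap phases to (-pi, pi]
#' @param x Numeric vector or matrix of phases (radians).
#' @return Same shape, values in `(-pi, pi]`.
#' @export
wrap_phase <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Estimate the carrier frequency of a fringe image
#'
#' Locates the strongest non-DC peak of the 2D FFT magnitude, refined to
#' sub-bin accuracy by a local centroid, and reports it as a spatial
#' frequency plus carrier axis. Invariant to constant offsets (DC excluded).
#'
#' @param image Numeric matrix (a rendered frame's `pixels`) or a
#'   `camera_frame`.
#' @param pitch Pixel pitch in mm (taken from a `camera_frame`).
#' @param min_peak_ratio Detection threshold: the peak must exceed this
#'   multiple of the median non-DC spectral magnitude (default 3).
#' @return List `f0` (cycles/mm), `axis` (`"x"` or `"y"`), `peak_ratio`.
#' @export
estimate_carrier <- function(image, pitch = NULL, min_peak_ratio = 3) {
  if (inherits(image, "camera_frame")) {
    pitch <- image$pitch
    image <- image$pixels
  }
  if (is.null(pitch)) stop("`pitch` required", call. = FALSE)
  n <- nrow(image); m <- ncol(image)
  sp <- Mod(stats::fft(image - mean(image)))
  fr <- freq_axis_any(n, pitch)
  fc <- freq_axis_any(m, pitch)
  # exclude a small DC disc (3 bins)
  dc <- outer(abs(fr) * n * pitch <= 3, abs(fc) * m * pitch <= 3, "&")
  spx <- sp
  spx[dc] <- 0
  med <- stats::median(sp[!dc])
  pk <- arrayInd(which.max(spx), dim(spx))
  ratio <- spx[pk] / med   # Inf for a noiseless pure carrier
  if (is.nan(ratio) || ratio < min_peak_ratio) {
    stop("no carrier detected: strongest non-DC spectral peak is only ",
         sprintf("%.2f", ratio), "x the median magnitude", call. = FALSE)
  }
  # centroid over a 3x3 neighbourhood (indices clamped to the grid)
  ri <- pmin(pmax(pk[1] + (-1:1), 1), n)
  ci <- pmin(pmax(pk[2] + (-1:1), 1), m)
  w <- spx[ri, ci]
  f_row <- sum(outer(fr[ri], rep(1, 3)) * w) / sum(w)
  f_col <- sum(outer(rep(1, 3), fc[ci]) * w) / sum(w)
  if (abs(f_col) >= abs(f_row)) {
    list(f0 = abs(f_col), axis = "x", peak_ratio = unname(ratio))
  } else {
    list(f0 = abs(f_row), axis = "y", peak_ratio = unname(ratio))
  }
}

#' FFT frequency axis for any length
#' @keywords internal
freq_axis_any <- function(n, pitch) {
  k <- c(seq.int(0L, ceiling(n / 2) - 1L), seq.int(-floor(n / 2), -1L))
  k / (n * pitch)
}

#' Extract the wrapped phase of a fringe image
#'
#' The Fourier-transform profilometry core: 2D FFT of the image, a smooth
#' raised-cosine (Hann) window centred on the +1 carrier lobe, inverse FFT to
#' the complex analytic image, and the wrapped phase of the analytic image
#' with the carrier ramp removed. The analytic amplitude (half the local
#' fringe amplitude) is returned as a quality map.
#'
#' @param image Numeric matrix or `camera_frame`.
#' @param carrier List with `f0` (cycles/mm) and `axis`, as returned by
#'   [estimate_carrier()], or a single number taken as `f0` along x.
#' @param pitch Pixel pitch in mm (taken from a `camera_frame`).
#' @param half_width Window half-width along the carrier axis in cycles/mm
#'   (default `f0 / 2`).
#' @param half_width_transverse Window half-width across the carrier axis
#'   (default `f0 / 2`).
#' @param keep_carrier If `TRUE` the carrier ramp is not subtracted and the
#'   wrapped phase of the raw analytic image is returned (used when a
#'   reference frame will be subtracted instead).
#' @return A [phase_map()] (wrapped) with attributes `"amplitude"` (quality
#'   map) and `"analytic"` (the complex analytic image).
#' @export
extract_wrapped_phase <- function(image, carrier, pitch = NULL,
                                  half_width = NULL,
                                  half_width_transverse = NULL,
                                  keep_carrier = FALSE) {
  if (inherits(image, "camera_frame")) {
    pitch <- image$pitch
    image <- image$pixels
  }
  if (is.null(pitch)) stop("`pitch` required", call. = FALSE)
  if (is.numeric(carrier)) carrier <- list(f0 = carrier, axis = "x")
  if (!identical(carrier$axis, "x")) {
    stop("only carriers along the x (column) axis are supported; ",
         "transpose the image first", call. = FALSE)
  }
  f0 <- carrier$f0
  if (is.null(half_width)) half_width <- f0 / 2
  if (is.null(half_width_transverse)) half_width_transverse <- f0 / 2
  if (half_width >= f0) {
    stop("band overlap: window half-width ", half_width,
         " reaches the DC lobe; reduce the window or raise f0", call. = FALSE)
  }
  n <- nrow(image); m <- ncol(image)
  fr <- freq_axis_any(n, pitch)
  fc <- freq_axis_any(m, pitch)
  hann <- function(u, hw) ifelse(abs(u) < hw, 0.5 + 0.5 * cos(pi * u / hw), 0)
  W <- outer(hann(fr, half_width_transverse), hann(fc - f0, half_width))
  analytic <- stats::fft(stats::fft(image) * W, inverse = TRUE) / (n * m)
  if (!keep_carrier) {
    x <- (seq_len(m) - 1) * pitch
    ramp <- matrix(rep(exp(-2i * pi * f0 * x), each = n), n, m)
    analytic_d <- analytic * ramp
  } else {
    analytic_d <- analytic
  }
  pm <- phase_map(Arg(analytic_d), "wrapped", f0, pitch)
  attr(pm, "amplitude") <- 2 * Mod(analytic)
  attr(pm, "analytic") <- analytic
  pm
}

#' Unwrap a wrapped phase map
#'
#' Quality-guided flood-fill unwrapping: pixels are admitted in decreasing
#' quality order from the highest-quality seed, each unwrapped against the
#' neighbour through which it was reached. Deterministic (quality ties broken
#' by pixel index). Pixels with quality below `mask_threshold` times the
#' median in-mask quality are masked out. The rewrap of the output equals the
#' input at every unmasked pixel by construction.
#'
#' @param wrapped A [phase_map()] in wrapped state.
#' @param quality Quality map (matrix); defaults to the `"amplitude"`
#'   attribute of `wrapped`.
#' @param mask_threshold Quality cutoff relative to the median quality
#'   (default 0.05).
#' @param method `"quality"` (default) or `"itoh"` (row-wise Itoh benchmark
#'   fallback, which ignores the quality map but honours the mask).
#' @return A [phase_map()] in unwrapped state; masked pixels are `NA`.
#'   Attribute `"residues"` counts the 2x2 loop residues of the input inside
#'   the mask (a diagnostic of unwrappability).
#' @export
unwrap_phase <- function(wrapped, quality = NULL, mask_threshold = 0.05,
                         method = c("quality", "itoh")) {
  stopifnot(inherits(wrapped, "phase_map"))
  if (wrapped$state != "wrapped") stop("phase map is not wrapped", call. = FALSE)
  method <- match.arg(method)
  w <- wrapped$values
  if (is.null(quality)) quality <- attr(wrapped, "amplitude")
  if (is.null(quality)) quality <- matrix(1, nrow(w), ncol(w))
  mask <- wrapped$mask & is.finite(w)
  qmed <- stats::median(quality[mask])
  mask <- mask & quality >= mask_threshold * qmed

  res <- count_residues(w, mask)
  if (res$density > 0.10) {
    warning(sprintf("residue density %.1f%% exceeds 10%%; affected region masked",
                    100 * res$density))
    mask <- mask & !res$residue_px
  }
  if (method == "quality") {
    out <- .unwrap_quality_cpp(w, quality, mask)
  } else {
    out <- itoh_unwrap(w, mask)
  }
  pm <- phase_map(out, "unwrapped", wrapped$f0, wrapped$pitch,
                  axis = wrapped$axis, mask = mask & is.finite(out))
  attr(pm, "amplitude") <- quality
  attr(pm, "residues") <- res$count
  pm
}

#' 2x2 loop residues of a wrapped phase field
#' @keywords internal
count_residues <- function(w, mask) {
  n <- nrow(w); m <- ncol(w)
  d1 <- wrap_phase(w[-1, -m] - w[-n, -m])     # down
  d2 <- wrap_phase(w[-1, -1] - w[-1, -m])     # right (bottom)
  d3 <- wrap_phase(w[-n, -1] - w[-1, -1])     # up
  d4 <- wrap_phase(w[-n, -m] - w[-n, -1])     # left (top)
  loop <- d1 + d2 + d3 + d4
  core <- mask[-n, -m] & mask[-1, -m] & mask[-1, -1] & mask[-n, -1]
  resid <- abs(loop) > pi & core
  px <- matrix(FALSE, n, m)
  if (any(resid)) {
    idx <- which(resid, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      r <- idx[k, 1]; c <- idx[k, 2]
      px[r:(r + 1), c:(c + 1)] <- TRUE
    }
  }
  list(count = sum(resid),
       density = if (any(core)) sum(resid) / sum(core) else 0,
       residue_px = px)
}

#' Row-wise Itoh unwrapping (benchmark fallback)
#' @keywords internal
itoh_unwrap <- function(w, mask = NULL) {
  n <- nrow(w); m <- ncol(w)
  out <- w
  # unwrap the middle column, then each row from it
  mid <- (m + 1) %/% 2
  col <- w[, mid]
  col <- col[1] + c(0, cumsum(wrap_phase(diff(col))))
  for (r in seq_len(n)) {
    row <- w[r, ]
    right <- cumsum(c(0, wrap_phase(diff(row))))
    out[r, ] <- col[r] + (right - right[mid])
  }
  if (!is.null(mask)) out[!mask] <- NA_real_
  out
}

#' Convert unwrapped phase deviation to surface height
#'
#' The exact inverse of [phase_modulation()]:
#' `h = L dphi / (dphi - 2 pi f0 D)`. Pixels where the denominator vanishes
#' are masked.
#'
#' @param phase A [phase_map()] in unwrapped state (reference-subtracted
#'   phase deviation).
#' @param geom A [projection_geometry()].
#' @return A [surface_map()] (masked pixels hold height 0 and are excluded
#'   from the mask).
#' @export
phase_to_height <- function(phase, geom) {
  stopifnot(inherits(phase, "phase_map"),
            inherits(geom, "projection_geometry"))
  if (phase$state != "unwrapped") {
    stop("phase must be unwrapped before height conversion", call. = FALSE)
  }
  dphi <- phase$values
  den <- dphi - 2 * pi * geom$f0 * geom$D
  bad <- !is.finite(dphi) | abs(den) < 1e-9 * 2 * pi * geom$f0 * geom$D
  h <- geom$L * dphi / den
  h[bad] <- 0
  surface_map(h, phase$pitch, mask = phase$mask & !bad)
}

#' One-shot Fourier-transform-profilometry reconstruction
#'
#' Composes the full pipeline: carrier estimation (or the known geometry
#' carrier), band-pass phase extraction, reference subtraction, 2D
#' quality-guided unwrapping, border-ring offset removal and phase-to-height
#' conversion. Deterministic given its inputs.
#'
#' @param image Numeric matrix or `camera_frame`: the measured one-shot
#'   fringe frame.
#' @param geom A [projection_geometry()].
#' @param pitch Pixel pitch in mm (taken from a `camera_frame`).
#' @param reference Optional reference-plane frame (matrix or
#'   `camera_frame`) measured with the same optics; its analytic phase is
#'   subtracted, cancelling the carrier and systematic window phase. When
#'   absent the carrier ramp fitted from the geometry carrier is subtracted.
#' @param carrier `"estimate"` (default) to detect the carrier from the
#'   image, `"geometry"` to trust `geom$f0`, or a numeric frequency.
#' @param half_width,half_width_transverse Band window half-widths in
#'   cycles/mm (default `f0/2`).
#' @param mask_threshold Quality cutoff for unwrapping, see
#'   [unwrap_phase()].
#' @param border_margin Width of the border reference ring as a fraction of
#'   the image side (default 0.04); the median unwrapped phase there is
#'   forced to zero.
#' @param edge_erode Pixels eroded from the quality mask boundary before
#'   height statistics, as a number of carrier periods (default 2); limits
#'   the influence of the band filter's spatial ringing at object edges.
#' @return An object of class `reconstruction_result`: `surface`
#'   (a [surface_map()]), `phase` (the unwrapped [phase_map()]) and
#'   `diagnostics` (carrier estimate, window, residue count, masked
#'   fraction, clipped fraction of the input frame if known).
#' @export
reconstruct <- function(image, geom, pitch = NULL, reference = NULL,
                        carrier = c("estimate", "geometry"),
                        half_width = NULL, half_width_transverse = NULL,
                        mask_threshold = 0.05, border_margin = 0.04,
                        edge_erode = 2) {
  clipped <- NA_real_
  if (inherits(image, "camera_frame")) {
    pitch <- image$pitch
    clipped <- image$meta$clipped_fraction
    image <- image$pixels
  }
  if (is.null(pitch)) stop("`pitch` required", call. = FALSE)
  if (is.character(carrier)) {
    carrier <- match.arg(carrier)
    car <- if (carrier == "estimate") {
      estimate_carrier(image, pitch)
    } else {
      list(f0 = geom$f0, axis = "x", peak_ratio = NA_real_)
    }
  } else {
    car <- list(f0 = carrier, axis = "x", peak_ratio = NA_real_)
  }

  wp <- extract_wrapped_phase(image, car, pitch,
                              half_width = half_width,
                              half_width_transverse = half_width_transverse,
                              keep_carrier = !is.null(reference))
  if (!is.null(reference)) {
    if (inherits(reference, "camera_frame")) reference <- reference$pixels
    wr <- extract_wrapped_phase(reference, car, pitch,
                                half_width = half_width,
                                half_width_transverse = half_width_transverse,
                                keep_carrier = TRUE)
    diffc <- attr(wp, "analytic") * Conj(attr(wr, "analytic"))
    amp <- attr(wp, "amplitude")
    wp <- phase_map(Arg(diffc), "wrapped", car$f0, pitch)
    attr(wp, "amplitude") <- amp
  }
  up <- unwrap_phase(wp, mask_threshold = mask_threshold)

  # reference convention: the border ring lies on the reference plane.
  # With a reference frame the carrier cancelled exactly, so only a global
  # offset (median over the ring) remains; without one, the residual of the
  # estimated carrier leaves a tilt as well, so a plane is fitted to the
  # ring and subtracted.
  n <- nrow(up$values); m <- ncol(up$values)
  bw <- max(2L, round(border_margin * min(n, m)))
  ring <- matrix(FALSE, n, m)
  ring[c(seq_len(bw), n - seq_len(bw) + 1L), ] <- TRUE
  ring[, c(seq_len(bw), m - seq_len(bw) + 1L)] <- TRUE
  ring_ok <- ring & up$mask
  if (!is.null(reference)) {
    offset <- if (any(ring_ok)) stats::median(up$values[ring_ok]) else 0
    vals <- up$values - offset
  } else if (sum(ring_ok) > 10) {
    ridx <- which(ring_ok, arr.ind = TRUE)
    X <- cbind(1, ridx[, 2], ridx[, 1])
    beta <- solve(crossprod(X), crossprod(X, up$values[ring_ok]))
    cc <- matrix(rep(seq_len(m), each = n), n, m)
    rr <- matrix(rep(seq_len(n), times = m), n, m)
    vals <- up$values - (beta[1] + beta[2] * cc + beta[3] * rr)
    offset <- beta[1]
  } else {
    offset <- 0
    vals <- up$values
  }
  up2 <- phase_map(vals, "unwrapped", up$f0, up$pitch, mask = up$mask)

  surf <- phase_to_height(up2, geom)
  if (edge_erode > 0) {
    er_px <- max(1L, round(edge_erode / (car$f0 * pitch)))
    surf$mask <- erode_mask(surf$mask, er_px)
  }
  structure(list(
    surface = surf,
    phase = up2,
    diagnostics = list(carrier = car,
                       half_width = if (is.null(half_width)) car$f0 / 2 else half_width,
                       residues = attr(up, "residues"),
                       masked_fraction = 1 - mean(surf$mask),
                       phase_offset = offset,
                       clipped_fraction = clipped)),
    class = "reconstruction_result")
}

#' @export
print.reconstruction_result <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("<reconstruction_result> %d x %d; carrier %.3g /mm, residues %d, %.1f%% masked\n",
              x$surface$nrow, x$surface$ncol, d$carrier$f0, d$residues,
              100 * d$masked_fraction))
  invisible(x)
}

#' Binary erosion of a mask by a square structuring element
#' @keywords internal
erode_mask <- function(mask, px) {
  if (px < 1) return(mask)
  m <- mask
  for (i in seq_len(px)) {
    n <- nrow(m); c <- ncol(m)
    shifted <- m
    shifted <- shifted & rbind(m[-1, , drop = FALSE], FALSE)
    shifted <- shifted & rbind(FALSE, m[-n, , drop = FALSE])
    shifted <- shifted & cbind(m[, -1, drop = FALSE], FALSE)
    shifted <- shifted & cbind(FALSE, m[, -c, drop = FALSE])
    m <- shifted
  }
  m
}
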