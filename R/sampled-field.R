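#' Complex scalar field sampled on a uniform square grid
#'
#' The currency of the diffraction simulation: a square complex matrix with a
#' physical pixel pitch. Rows index y, columns index x; the grid origin
#' (x = y = 0) sits at index `n/2 + 1` on both axes, matching the FFT
#' convention used throughout.
#'
#' @param amplitude Square complex (or numeric) matrix; side must be a power
#'   of two.
#' @param pitch Sample spacing in mm (same on both axes).
#' @param plane_label One of `"P0"`, `"P1"`, `"P2"`, `"P3"` (or other label).
#' @return An object of class `sampled_field`.
#' @export
sampled_field <- function(amplitude, pitch, plane_label = "P0") {
  if (!is.matrix(amplitude) || nrow(amplitude) != ncol(amplitude)) {
    stop("`amplitude` must be a square matrix", call. = FALSE)
  }
  n <- nrow(amplitude)
  if (n < 2 || bitwAnd(n, n - 1L) != 0L) {
    stop("grid side must be a power of two, got ", n, call. = FALSE)
  }
  if (!is.numeric(pitch) || length(pitch) != 1L || !is.finite(pitch) ||
      pitch <= 0) {
    stop("`pitch` must be a single positive number (mm)", call. = FALSE)
  }
  storage.mode(amplitude) <- "complex"
  structure(list(amplitude = amplitude, pitch = pitch, n = n,
                 extent = n * pitch, plane_label = plane_label),
            class = "sampled_field")
}

#' Physical coordinates of the samples of a grid
#'
#' @param n Grid side (power of two).
#' @param pitch Sample spacing in mm.
#' @return Numeric vector of length `n`, zero at index `n/2 + 1`.
#' @keywords internal
grid_axis <- function(n, pitch) (seq_len(n) - (n / 2 + 1)) * pitch

#' FFT frequency axis for a grid
#' @keywords internal
freq_axis <- function(n, pitch) {
  c(seq.int(0L, n / 2 - 1L), seq.int(-n / 2, -1L)) / (n * pitch)
}

#' Total optical power carried by a sampled field
#'
#' Discrete approximation of the integral of `|U|^2` over the plane:
#' `sum(|amplitude|^2) * pitch^2`.
#'
#' @param field A [sampled_field()].
#' @return Power in arbitrary (consistent) units.
#' @export
field_power <- function(field) {
  stopifnot(inherits(field, "sampled_field"))
  sum(Mod(field$amplitude)^2) * field$pitch^2
}

#' Intensity of a sampled field
#' @param field A [sampled_field()].
#' @return Numeric matrix `|amplitude|^2`.
#' @export
field_intensity <- function(field) {
  stopifnot(inherits(field, "sampled_field"))
  Mod(field$amplitude)^2
}

#' @export
print.sampled_field <- function(x, ...) {
  cat(sprintf("<sampled_field> %d x %d at plane %s, pitch %g mm (extent %g mm), power %.4g\n",
              x$n, x$n, x$plane_label, x$pitch, x$extent, field_power(x)))
  invisible(x)
}
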