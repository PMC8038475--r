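# Shared fixtures, built in code.

# flat reference surface matching another surface's grid
flat_like <- function(surface) {
  surface_map(matrix(0, surface$nrow, surface$ncol), surface$pitch,
              mask = matrix(TRUE, surface$nrow, surface$ncol))
}

# noise-free floating-point camera
clean_camera <- function(...) {
  camera_model(shot_noise = 0, read_noise = 0, bit_depth = NA, ...)
}

# clean photometric scene: pure direct reflection of the carrier
clean_scene <- function(...) {
  photometric_scene(direct_albedo = 0.9, scatter_fraction = 0,
                    background_lux = 0, texture_amp = 0, ...)
}

# smooth random field: Gaussian noise blurred with a separable kernel,
# scaled to a given max amplitude (used for synthetic phase fields)
smooth_field <- function(n, amplitude, sigma_px = n / 8, seed = 1) {
  set.seed(seed)
  z <- matrix(stats::rnorm(n * n), n, n)
  half <- min(ceiling(3 * sigma_px), floor((n - 1) / 2))
  g <- stats::dnorm(seq(-half, half), sd = sigma_px)
  g <- g / sum(g)
  z <- apply(z, 2, function(col) stats::filter(col, g, circular = TRUE))
  z <- t(apply(z, 1, function(row) stats::filter(row, g, circular = TRUE)))
  amplitude * z / max(abs(z))
}

# Fourier coefficients of the rect-comb (binary) grating, by brute-force
# quadrature over one period: c_m = (1/d) int t(x) exp(-2 pi i m x / d) dx
grating_fourier_coeff <- function(duty, m, n_quad = 20000) {
  x <- (seq_len(n_quad) - 0.5) / n_quad        # one period, d = 1
  t <- as.numeric(pmin(x, 1 - x) <= duty / 2)  # slit centred at x = 0
  vapply(m, function(mm) sum(t * exp(-2i * pi * mm * x)) / n_quad,
         complex(1))
}
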