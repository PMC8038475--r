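# Scalar-diffraction fringe projector: grating, propagation, filtering,
# closed form vs numeric chain.

test_that("binary grating transmission has the right duty cycle, period and values", {
  setup <- optical_setup()  # 50 lp/mm grating
  u0 <- grating_transmission(setup, n = 2048, pitch = setup$grating_period / 16)
  x <- fringeftp:::grid_axis(u0$n, u0$pitch)
  mid <- u0$n / 2 + 1
  t_row <- Mod(u0$amplitude[mid, ])
  # slit centre (x = 0) transmits fully; mid-gap transmits nothing
  expect_equal(t_row[mid], 1)
  gap_idx <- which.min(abs(x - setup$grating_period / 2))
  expect_equal(t_row[gap_idx], 0)
  # fraction of transmitting area inside the spot ~ duty a/d (the mean
  # area-weighted transmission is exactly the duty cycle)
  r2 <- outer(x^2, x^2, "+")
  spot <- r2 <= (setup$illum_diameter / 2)^2
  expect_equal(mean(Mod(u0$amplitude[spot])), setup$duty, tolerance = 0.01)
  # exactly 50 periods per mm along x: spectral peak of the profile at 1/d
  prof <- t_row - mean(t_row)
  sp <- Mod(stats::fft(prof))[1:(u0$n / 2)]
  f <- (which.max(sp[-1])) / (u0$n * u0$pitch)
  expect_equal(f, 1 / setup$grating_period, tolerance = 1e-6)
})

test_that("grating sampling and spot-size preconditions are enforced", {
  setup <- optical_setup()
  expect_error(grating_transmission(setup, n = 256, pitch = setup$grating_period / 4),
               "sampling too coarse")
  expect_error(grating_transmission(setup, n = 64, pitch = setup$grating_period / 8),
               "does not fit")
})

test_that("Fresnel propagation is unitary and has the semigroup property", {
  # a Gaussian beam well contained in the central half of the grid
  n <- 512
  pitch <- 0.01
  x <- fringeftp:::grid_axis(n, pitch)
  r2 <- outer(x^2, x^2, "+")
  u <- sampled_field(exp(-r2 / (2 * 0.3^2)) + 0i, pitch)
  p0 <- field_power(u)
  # z within the alias-free regime z <= n * pitch^2 / lambda ~ 96 mm
  u1 <- fresnel_propagate(u, 40, 532)
  expect_equal(field_power(u1), p0, tolerance = 1e-6)
  # two half steps equal one full step
  u_half <- fresnel_propagate(fresnel_propagate(u, 20, 532), 20, 532)
  expect_lt(max(Mod(u_half$amplitude - u1$amplitude)) /
              max(Mod(u1$amplitude)), 1e-8)
})

test_that("aliasing-condition violation is rejected naming a safe distance", {
  n <- 256
  pitch <- 0.002
  x <- fringeftp:::grid_axis(n, pitch)
  # a fine grating-like field with substantial high-frequency content
  amp <- outer(rep(1, n), cos(2 * pi * 100 * x)) + 0i
  u <- sampled_field(amp, pitch)
  expect_error(fresnel_propagate(u, 500, 532), "alias")
  expect_error(fresnel_propagate(u, 500, 532), "safe distance")
})

test_that("circular aperture far field matches a brute-force Fraunhofer oracle", {
  lam <- 532e-6
  D_ap <- 0.5
  z <- 2000
  n <- 512
  pitch <- 0.012
  x <- fringeftp:::grid_axis(n, pitch)
  r2 <- outer(x^2, x^2, "+")
  u <- sampled_field((r2 <= (D_ap / 2)^2) + 0i, pitch)
  # a hard-edged aperture carries ~13% of its power in slowly-decaying
  # spectral tails; those correspond to edge detail that leaves the grid
  # during propagation, so a generous band tolerance is appropriate here
  prop <- fresnel_propagate(u, z, 532, band_tol = 0.2)
  mid <- n / 2 + 1
  prof <- Mod(prop$amplitude[mid, ])^2

  # oracle: direct Fraunhofer integral by quadrature over the aperture
  nq <- 101
  aq <- fringeftp:::grid_axis(nq, D_ap / nq)
  keep <- outer(aq^2, aq^2, "+") <= (D_ap / 2)^2
  X <- matrix(rep(aq, each = nq), nq)[keep]
  xs <- x[abs(x) <= 2]
  oracle <- vapply(xs, function(xi) {
    Mod(sum(exp(-2i * pi * X * xi / (lam * z))))^2
  }, numeric(1))
  sim <- prof[abs(x) <= 2]
  expect_gt(stats::cor(sim, oracle), 0.995)
  # first zero near 1.22 lambda z / D
  x0 <- 1.22 * lam * z / D_ap
  zero_region <- xs > 0.8 * x0 & xs < 1.2 * x0
  expect_equal(xs[zero_region][which.min(sim[zero_region])],
               xs[zero_region][which.min(oracle[zero_region])],
               tolerance = 2 * pitch)
})

test_that("the lens is a pure phase element that focuses a collimated beam at z = f", {
  n <- 512
  pitch <- 0.01
  x <- fringeftp:::grid_axis(n, pitch)
  r2 <- outer(x^2, x^2, "+")
  u <- sampled_field((r2 <= 1) + 0i, pitch)   # 2 mm collimated beam
  f <- 40
  ul <- lens_transmit(u, f, 532)
  expect_equal(Mod(ul$amplitude), Mod(u$amplitude))
  mid <- n / 2 + 1
  expect_equal(Arg(ul$amplitude[mid, mid]), 0)
  # scan propagation distance; on-axis intensity peaks at z = f
  zs <- seq(30, 50, by = 1)
  on_axis <- vapply(zs, function(z) {
    Mod(fresnel_propagate(ul, z, 532)$amplitude[mid, mid])^2
  }, numeric(1))
  expect_equal(zs[which.max(on_axis)], f, tolerance = 1)
})

test_that("closed-form Fourier-plane spectrum has the grating-order structure", {
  su <- bench_setup()
  x2 <- seq(-1, 1, by = 1e-4)
  sp <- Mod(closed_form_spectrum(su, x2))
  # even orders vanish at 50% duty: no lobe near x2 = 2 lambda f / d
  x_m <- function(m) m * su$lambda_mm * su$focal_length / su$grating_period
  # absent even-order lobe: only neighbouring Airy tails remain there
  expect_lt(sp[which.min(abs(x2 - x_m(2)))], 0.01 * max(sp))
  # lobe centres at x2 = m lambda f / d for m = 0, 1, 3
  for (m in c(0, 1, 3)) {
    reg <- abs(x2 - x_m(m)) < 0.05
    expect_lt(abs(x2[reg][which.max(sp[reg])] - x_m(m)), 5e-4)
  }
  # numeric chain: field magnitude at P2 peaks at the same positions
  u0 <- grating_transmission(su, n = 2048, pitch = su$grating_period / 8)
  u1 <- lens_transmit(fresnel_propagate(u0, su$z1, su$wavelength, 0.05),
                      su$focal_length, su$wavelength)
  u2 <- fresnel_propagate(u1, su$z2, su$wavelength, 0.05)
  mid <- u2$n / 2 + 1
  prof <- Mod(u2$amplitude[mid, ])
  xg <- fringeftp:::grid_axis(u2$n, u2$pitch)
  for (m in c(-1, 0, 1)) {
    reg <- abs(xg - x_m(m)) < 0.05
    expect_lt(abs(xg[reg][which.max(prof[reg])] - x_m(m)), u2$pitch + 1e-12)
  }
})

test_that("spatial filter passes exactly the +/-1-order power of the binary grating", {
  su <- bench_setup()
  u0 <- grating_transmission(su, n = 2048, pitch = su$grating_period / 8)
  u1 <- lens_transmit(fresnel_propagate(u0, su$z1, su$wavelength, 0.05),
                      su$focal_length, su$wavelength)
  u2p <- fresnel_propagate(u1, su$z2, su$wavelength, 0.05)
  u2 <- spatial_filter(u2p, su)
  pass <- field_power(u2) / field_power(u2p)
  # oracle: Fourier-series coefficients of the 50% duty rect-comb grating
  p_inc <- 2 * Mod(grating_fourier_coeff(su$duty, 1))^2        # of incident
  p_trans <- p_inc / su$duty                                    # of transmitted
  expect_equal(p_inc, 2 * (1 / pi)^2, tolerance = 1e-6)
  expect_equal(pass, p_trans, tolerance = 0.02)
  # power outside the two slit windows is zero after filtering
  x <- fringeftp:::grid_axis(u2$n, u2$pitch)
  outside <- abs(abs(x) - su$order_position) > su$filter_slit_width / 2
  expect_equal(sum(Mod(u2$amplitude[, outside])^2), 0)
  # even orders vanish at 50% duty: the field intensity at the +/-2 order
  # centre is below 1e-3 of the +/-1 lobe peak ...
  xg <- fringeftp:::grid_axis(u2p$n, u2p$pitch)
  mid <- u2p$n / 2 + 1
  i_at <- function(x0) Mod(u2p$amplitude[mid, which.min(abs(xg - x0))])^2
  expect_lt(i_at(2 * su$order_position), 1e-3 * i_at(su$order_position))
  # ... and slits displaced to the +/-2 positions pass only the slowly
  # decaying Airy tails of the hard-edged illumination spot (a few 1e-3)
  su2 <- su
  su2$order_position <- 2 * su$order_position
  u2_even <- spatial_filter(u2p, su2)
  expect_lt(field_power(u2_even) / field_power(u2), 5e-3)
})

test_that("filter slits overlapping the zero order are rejected", {
  su <- bench_setup()
  su$filter_slit_width <- 3 * su$order_position
  u <- sampled_field(matrix(1 + 0i, 256, 256), 0.05)
  expect_error(spatial_filter(u, su), "not separable")
})

test_that("closed-form fringe pattern is an ideal one-dimensional cosine-squared disc", {
  su <- bench_setup(z3 = 100)
  fp <- closed_form_fringe(su, n = 512)
  x <- fringeftp:::grid_axis(fp$n, fp$pitch)
  r2 <- outer(x^2, x^2, "+")
  inside <- r2 <= (0.95 * su$fringe_radius)^2
  # unit Michelson contrast inside the disc
  expect_equal(michelson_contrast(fp$intensity, inside, robust = FALSE), 1)
  # maximal intensity on the axis (cos(0) = 1)
  mid <- fp$n / 2 + 1
  expect_equal(fp$intensity[mid, mid], max(fp$intensity))
  # constant along y inside the disc: one variable only
  col_ok <- which(abs(x) < 0.3 * su$fringe_radius)
  for (j in col_ok[c(1, round(length(col_ok) / 2), length(col_ok))]) {
    vals <- fp$intensity[inside[, j], j]
    expect_lt(diff(range(vals)), 1e-12 * max(fp$intensity))
  }
  # pattern vanishes outside the predicted radius
  expect_equal(max(fp$intensity[r2 > su$fringe_radius^2]), 0)
  # doubling Z3 halves the predicted intensity frequency
  su2 <- bench_setup(z3 = 200)
  expect_equal(su2$fringe_frequency, su$fringe_frequency / 2)
})

test_that("numeric diffraction chain reproduces the closed form (oracle equivalence)", {
  results <- lapply(c(50, 100, 200), function(z3) {
    su <- bench_setup(z3 = z3)
    num <- simulate_fringe_numeric(su)
    cf <- closed_form_fringe(su, n = num$n, pitch = num$pitch)
    x <- fringeftp:::grid_axis(num$n, num$pitch)
    sel <- outer(x^2, x^2, "+") <= (0.5 * su$fringe_radius)^2
    list(su = su,
         corr = fringe_correlation(num, cf),
         f_meas = measure_fringe_frequency(num),
         contrast = michelson_contrast(num$intensity, sel))
  })
  for (r in results) {
    expect_gt(r$corr, 0.99)
    # measured fringe period within one grid pitch of d Z3 / (2 f)
    period_pred <- 1 / r$su$fringe_frequency
    expect_lt(abs(1 / r$f_meas - period_pred), r$su$grating_period / 8)
    expect_gt(r$contrast, 0.95)
  }
  # scaling law: intensity-fringe frequency x Z3 constant within 1%
  fz <- vapply(results, function(r) r$f_meas * r$su$z3, numeric(1))
  expect_lt((max(fz) - min(fz)) / mean(fz), 0.01)
})

test_that("a single passed order yields a flat (fringe-free) intensity", {
  su <- bench_setup(z3 = 100)
  num <- simulate_fringe_numeric(su, orders = 1)
  both <- simulate_fringe_numeric(su)
  x <- fringeftp:::grid_axis(num$n, num$pitch)
  sel <- outer(x^2, x^2, "+") <= (0.5 * su$fringe_radius)^2
  # a single plane-wave component has no fringes; the residual few-percent
  # ripple is Fresnel edge diffraction of the hard illumination spot
  expect_lt(michelson_contrast(num$intensity, sel), 0.1)
  expect_gt(michelson_contrast(both$intensity, sel), 0.95)
  # and no spectral line at the fringe frequency: the carrier peak of the
  # two-order pattern exceeds the single-order residual by >100x
  prof_amp <- function(fp) {
    pr <- colMeans(fp$intensity[(fp$n/2 - 20):(fp$n/2 + 20), ])
    sp <- Mod(stats::fft(pr - mean(pr)))
    kf <- round(fp$predicted_intensity_frequency * fp$n * fp$pitch) + 1
    max(sp[(kf - 2):(kf + 2)])
  }
  expect_gt(prof_amp(both) / prof_amp(num), 100)
})
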