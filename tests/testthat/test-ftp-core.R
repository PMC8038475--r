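# Fourier-transform-profilometry reconstruction: carrier estimation, phase
# extraction, 2D unwrapping, height conversion and the composed pipeline.

test_that("carrier estimation finds a pure cosine and ignores offsets", {
  n <- 256
  pitch <- 0.25
  x <- (seq_len(n) - 1) * pitch
  f0 <- 0.8
  img <- matrix(rep(cos(2 * pi * f0 * x), each = n), n, n)
  est <- estimate_carrier(img, pitch)
  expect_equal(est$axis, "x")
  expect_lt(abs(est$f0 - f0), 1 / (n * pitch))       # within one bin
  est2 <- estimate_carrier(img + 7, pitch)
  expect_equal(est2$f0, est$f0)                      # DC excluded
  # no carrier in a constant (e.g. fully saturated) image
  expect_error(estimate_carrier(matrix(5, n, n), pitch), "no carrier detected")
})

test_that("carrier estimate on a rendered frame is within 2% of the geometry", {
  geom <- projection_geometry(f0 = 1.0)
  cap <- make_spherical_cap(40, 10, pitch = 0.25)
  fr <- render_frame(cap, geom, photometric_scene(), camera_model(),
                     rng_seed = 3)
  est <- estimate_carrier(fr)
  expect_lt(abs(est$f0 - 1.0) / 1.0, 0.02)
})

test_that("wrapped-phase extraction recovers a known synthetic phase field", {
  n <- 256
  pitch <- 0.25
  f0 <- 1.0
  x <- (seq_len(n) - 1) * pitch
  carrier <- matrix(rep(2 * pi * f0 * x, each = n), n, n)
  # flat reference: recovered phase is ~0 away from edges
  g_flat <- 0.5 + 0.4 * cos(carrier)
  wp_flat <- extract_wrapped_phase(g_flat, f0, pitch)
  core <- (n / 4):(3 * n / 4)
  expect_lt(max(abs(wp_flat$values[core, core])), 0.05)

  # smooth synthetic modulation within the band
  dphi <- smooth_field(n, amplitude = 6, sigma_px = 40, seed = 2)
  g <- 0.5 + 0.4 * cos(carrier + dphi)
  wp <- extract_wrapped_phase(g, f0, pitch)
  err <- wrap_phase(wp$values[core, core] - dphi[core, core])
  expect_lt(sqrt(mean(err^2)), 0.05)
  # phase is invariant to image brightness
  wp2 <- extract_wrapped_phase(2 * g, f0, pitch)
  expect_equal(wp2$values, wp$values, tolerance = 1e-9)
  # window reaching DC is rejected
  expect_error(extract_wrapped_phase(g, f0, pitch, half_width = 1.2),
               "band overlap")
})

test_that("quality-guided unwrapping is exact, deterministic and rewraps to its input", {
  # canonical ramp: 0 -> 6 pi across the image
  n <- 128
  ramp <- matrix(rep(seq(0, 6 * pi, length.out = n), each = n), n, n)
  w <- wrap_phase(ramp)
  pm <- phase_map(w, "wrapped", f0 = 1, pitch = 1)
  un <- unwrap_phase(pm)
  d <- un$values - ramp
  expect_lt(diff(range(d)), 1e-9)                       # up to a 2 pi k offset
  expect_equal(d[1, 1] %% (2 * pi), 0, tolerance = 1e-9)

  # property: rewrap(unwrap(x)) == x on all unmasked pixels, 100 seeded fields
  for (seed in 1:100) {
    nn <- 48
    set.seed(seed)
    sig <- stats::runif(1, 4, 12)
    # slope-limited so neighbouring samples never differ by more than pi
    # (the fundamental unwrappability condition)
    amp <- stats::runif(1, 2, 2 * sig)
    field <- smooth_field(nn, amplitude = amp, sigma_px = sig, seed = seed)
    wf <- wrap_phase(field)
    pmf <- phase_map(wf, "wrapped", f0 = 1, pitch = 1)
    uf <- unwrap_phase(pmf)
    expect_true(all(uf$mask))
    expect_lt(max(abs(wrap_phase(uf$values) - wf)), 1e-12)
    # smooth in-band fields unwrap to the original up to one global 2 pi k
    resid <- uf$values - field
    expect_lt(diff(range(resid)), 1e-9)
    frac <- (resid[1] / (2 * pi)) %% 1
    expect_lt(min(frac, 1 - frac), 1e-9)
  }

  # determinism: identical runs give identical output
  f <- smooth_field(64, amplitude = 12, sigma_px = 6, seed = 999)
  p1 <- unwrap_phase(phase_map(wrap_phase(f), "wrapped", 1, 1))
  p2 <- unwrap_phase(phase_map(wrap_phase(f), "wrapped", 1, 1))
  expect_identical(p1$values, p2$values)

  # the Itoh fallback agrees on a clean smooth field
  p3 <- unwrap_phase(phase_map(wrap_phase(f), "wrapped", 1, 1),
                     method = "itoh")
  expect_lt(diff(range(p3$values - p1$values)), 1e-9)
})

test_that("low-quality pixels are masked during unwrapping", {
  f <- smooth_field(64, amplitude = 10, sigma_px = 8, seed = 5)
  q <- matrix(1, 64, 64)
  q[1:8, 1:8] <- 1e-4   # a dead corner
  un <- unwrap_phase(phase_map(wrap_phase(f), "wrapped", 1, 1), quality = q)
  expect_true(all(!un$mask[1:8, 1:8]))
  expect_true(all(is.na(un$values[1:8, 1:8])))
  expect_true(all(un$mask[20:60, 20:60]))
})

test_that("phase-to-height inverts the worked triangulation example", {
  geom <- projection_geometry(L = 1000, D = 300, f0 = 1.0)
  ph <- phase_map(matrix(-19.0399, 4, 4), "unwrapped", 1.0, 1,
                  mask = matrix(TRUE, 4, 4))
  h <- phase_to_height(ph, geom)
  expect_equal(h$heights[1, 1], 10, tolerance = 1e-4)
  # reference plane maps to zero height
  ph0 <- phase_map(matrix(0, 4, 4), "unwrapped", 1.0, 1,
                   mask = matrix(TRUE, 4, 4))
  expect_true(all(phase_to_height(ph0, geom)$heights == 0))
  # small-phase linear limit h ~ -L dphi / (2 pi f0 D)
  eps <- 1e-4
  phs <- phase_map(matrix(-eps, 2, 2), "unwrapped", 1.0, 1,
                   mask = matrix(TRUE, 2, 2))
  expect_equal(phase_to_height(phs, geom)$heights[1, 1],
               1000 * eps / (2 * pi * 1.0 * 300), tolerance = 1e-4)
  # wrapped input is rejected
  wr <- phase_map(matrix(0.5, 2, 2), "wrapped", 1.0, 1)
  expect_error(phase_to_height(wr, geom), "unwrapped")
})

test_that("full round trip h -> phase -> h is exact to 1e-10 relative", {
  geom <- projection_geometry(L = 1000, D = 300, f0 = 1.0)
  cap <- make_spherical_cap(40, 10, pitch = 0.5)
  ph <- phase_modulation(cap, geom)
  ph$mask <- matrix(TRUE, cap$nrow, cap$ncol)
  h2 <- phase_to_height(ph, geom)
  expect_lt(max(abs(h2$heights - cap$heights)) / max(cap$heights), 1e-10)
})

test_that("end-to-end reconstruction recovers the cap in the clean limit", {
  geom <- projection_geometry(f0 = 1.0)
  cap <- make_spherical_cap(40, 10, pitch = 0.25)
  fr <- render_frame(cap, geom, clean_scene(), clean_camera())
  ref <- render_frame(flat_like(cap), geom, clean_scene(), clean_camera())
  rec <- reconstruct(fr, geom, reference = ref)
  err <- surface_rmse(rec$surface, cap)
  expect_lt(err$rmse_pct, 2)
  # deterministic pipeline
  rec2 <- reconstruct(fr, geom, reference = ref)
  expect_identical(rec$surface$heights, rec2$surface$heights)
})

test_that("reconstruction works without a reference frame via the carrier ramp", {
  geom <- projection_geometry(f0 = 1.0)
  cap <- make_spherical_cap(40, 10, pitch = 0.25)
  fr <- render_frame(cap, geom, clean_scene(), clean_camera())
  rec <- reconstruct(fr, geom, carrier = "geometry")
  err <- surface_rmse(rec$surface, cap)
  expect_lt(err$rmse_pct, 5)
})

test_that("reconstruction degrades monotonically with background and is rescued", {
  geom <- projection_geometry(f0 = 1.0)
  face <- make_face_phantom(11, pitch = 0.3, extent = 120, amplitude = 25)
  flat <- flat_like(face)
  run <- function(lux, fp) {
    scene <- photometric_scene(background_lux = lux)
    cam <- camera_model(filter_on = fp, polarizer_on = fp)
    fr <- render_frame(face, geom, scene, cam, rng_seed = 21)
    ref <- render_frame(flat, geom, scene, cam, rng_seed = 22)
    rec <- tryCatch(reconstruct(fr, geom, reference = ref),
                    error = function(e) NULL)
    if (is.null(rec)) return(Inf)
    surface_rmse(rec$surface, face)$rmse_pct
  }
  rmse_off <- vapply(c(0, 50, 175, 200), run, numeric(1), fp = FALSE)
  rmse_on <- vapply(c(50, 175, 200), run, numeric(1), fp = TRUE)
  # failed reconstructions count as the worst outcome in the ordering
  expect_true(all(diff(pmin(rmse_off, 1e6)) >= -1e-6))
  # rescue: filter+polarizer beats no-filter at every nonzero background
  expect_true(all(rmse_on < rmse_off[-1]))
  expect_true(all(rmse_on < 5))       # graded High
  expect_true(is.infinite(rmse_off[4]) || rmse_off[4] > 50)
})

test_that("higher carrier frequency reconstructs at least as accurately", {
  face <- make_face_phantom(11, pitch = 0.3, extent = 120, amplitude = 25)
  flat <- flat_like(face)
  run_f0 <- function(f0) {
    geom <- projection_geometry(f0 = f0)
    scene <- photometric_scene(background_lux = 50)
    cam <- camera_model(filter_on = TRUE, polarizer_on = TRUE)
    fr <- render_frame(face, geom, scene, cam, rng_seed = 31)
    ref <- render_frame(flat, geom, scene, cam, rng_seed = 32)
    surface_rmse(reconstruct(fr, geom, reference = ref)$surface,
                 face)$rmse_pct
  }
  expect_lte(run_f0(1.0), run_f0(0.3))
})
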