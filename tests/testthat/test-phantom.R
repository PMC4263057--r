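test_that("half-sine waveform peaks at q_peak, rests in diastole and has the closed-form mean", {
  q <- make_flow_waveform(500, 0.33, 100, 880)
  times <- attr(q, "times")
  expect_equal(max(q), 500, tolerance = 1e-3)
  expect_true(all(q[times > 0.33 * 880] == 0))
  # closed form: time average of the half-sine lobe = (2/pi) * q_peak * s
  expect_equal(mean(q), 2 / pi * 500 * 0.33,
               tolerance = 500 * 0.33 / 100 / 100)  # one frame-width of error
  expect_error(make_flow_waveform(500, 0.33, 3), class = "pcmri_invalid_spec")
  expect_error(make_flow_waveform(-1, 0.33, 100), class = "pcmri_invalid_spec")
  expect_error(make_flow_waveform(500, 1.2, 100), class = "pcmri_invalid_spec")
})

test_that("velocity profiles have the prescribed shape inside the lumen and vanish outside", {
  # plug: q = 98 ml/s through a 1.96 cm^2 lumen is exactly 50 cm/s everywhere
  r_mm <- 10 * sqrt(1.96 / pi)
  spec <- phantom_spec(grid_shape = c(48L, 48L), lumen_radius_sys = r_mm,
                       lumen_radius_dia = r_mm, profile = "plug", noise_sd = 0)
  u <- synthesize_velocity_frame(spec, 1, 98)
  inside <- u != 0
  expect_equal(unique(u[inside]), 50)
  rr <- sqrt(outer(((1:48 - spec$lumen_center[1]) * 1.4)^2,
                   ((1:48 - spec$lumen_center[2]) * 1.4)^2, `+`))
  expect_true(all(u[rr > r_mm] == 0))

  # parabolic: center velocity is twice the mean (Poiseuille)
  spec2 <- phantom_spec(grid_shape = c(48L, 48L), lumen_radius_sys = 12,
                        lumen_radius_dia = 12, profile = "parabolic",
                        noise_sd = 0)
  a <- pi * 1.2^2
  u2 <- synthesize_velocity_frame(spec2, 1, 300)
  expect_equal(u2[spec2$lumen_center[1], spec2$lumen_center[2]], 2 * 300 / a)
})

test_that("Womersley profile converges to the parabolic profile as alpha -> 0", {
  # inflate viscosity so the fundamental alpha drops to ~0.1 without touching
  # the profile-evaluation cutoff
  base <- list(grid_shape = c(48L, 48L), lumen_radius_sys = 12,
               lumen_radius_dia = 12, n_frames = 40L, noise_sd = 0,
               dynamic_viscosity = 4e4)
  sw <- do.call(phantom_spec, c(base, profile = "womersley"))
  sp <- do.call(phantom_spec, c(base, profile = "parabolic"))
  q <- make_flow_waveform(sw$q_peak, sw$systole_fraction, 40L, sw$rr_interval)
  f <- which.max(q)
  uw <- synthesize_velocity_frame(sw, f, q[f])
  up <- synthesize_velocity_frame(sp, f, q[f])
  expect_lt(max(abs(uw - up)), 0.01 * max(up))
})

test_that("every profile conserves the prescribed flow to 2% per frame at >= 8 px radius", {
  for (prof in c("plug", "parabolic", "womersley")) {
    # plug carries full velocity at the wall, so its pixel-sum error is the
    # raw disc-area quantization: give it the finer grid it needs
    spec <- if (prof == "plug")
      noiseless_spec(profile = prof, pixel_spacing = c(0.7, 0.7),
                     grid_shape = c(96L, 96L))
    else noiseless_spec(profile = prof)
    q <- make_flow_waveform(spec$q_peak, spec$systole_fraction, spec$n_frames,
                            spec$rr_interval)
    pa <- spec$pixel_spacing[1] * spec$pixel_spacing[2] / 100
    for (f in c(5, 8, which.max(q), 30)) {
      u <- synthesize_velocity_frame(spec, f, q[f])
      expect_lt(abs(sum(u) * pa - q[f]), 0.02 * spec$q_peak,
                label = sprintf("%s frame %d pixel-sum error", prof, f))
    }
  }
})

test_that("phase encoding follows the VENC convention and wraps 2*VENC-periodically", {
  venc <- 200
  expect_identical(encode_phase(venc / 2, venc), 1024L)
  expect_identical(encode_phase(0, venc), 0L)
  expect_identical(encode_phase(-venc, venc), -2048L)
  # 10% above the VENC aliases to a sign flip at -0.9*pi
  expect_identical(encode_phase(1.1 * venc, venc),
                   as.integer(floor(-0.9 * 2048)))
  set.seed(42)
  v <- runif(500, -venc * 0.9999, venc * 0.9999)
  stored <- encode_phase(v, venc)
  expect_true(all(stored >= -2048L & stored <= 2047L))
  decoded <- phase_to_velocity(stored, venc, "raw_phase")
  expect_lt(max(abs(decoded - v)), venc / 2048 + 1e-12)
  # aliasing is exactly 2*VENC-periodic
  expect_identical(encode_phase(v + 2 * venc, venc), stored)
  expect_identical(encode_phase(v - 4 * venc, venc), stored)
})

test_that("generated phantoms are bit-reproducible given the seed", {
  spec <- noiseless_spec(noise_sd = 3, seed = 7L)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$series$encoded, b$series$encoded)
  expect_identical(a$series$magnitude, b$series$magnitude)
  expect_identical(a$truth, b$truth)
  c <- generate_phantom(noiseless_spec(noise_sd = 3, seed = 8L))
  expect_false(identical(a$series$encoded, c$series$encoded))
})

test_that("phantom truth carries the analytic orifice areas", {
  # plug jet of radius 1 cm inside an 18 mm lumen: EOA is the jet area
  jet <- phantom_spec(profile = "plug", jet_radius = 10,
                      lumen_radius_sys = 18, lumen_radius_dia = 18,
                      grid_shape = c(64L, 64L), n_frames = 20L, noise_sd = 0)
  expect_equal(generate_phantom(jet)$truth$eoa_true, pi * 1^2,
               tolerance = 1e-3)
  # full-lumen parabolic profile: u > mean exactly inside r < R/sqrt(2)
  par <- noiseless_spec(n_frames = 20L)
  tr <- generate_phantom(par)$truth
  expect_equal(tr$eoa_true, tr$a_sys / 2, tolerance = 1e-3)
  expect_equal(tr$qmax_true, max(tr$q_true))
  expect_gte(tr$a_sys, tr$a_dia)
})

test_that("invalid phantom specifications are rejected", {
  expect_error(phantom_spec(n_frames = 3), class = "pcmri_invalid_spec")
  expect_error(phantom_spec(systole_fraction = 1), class = "pcmri_invalid_spec")
  expect_error(phantom_spec(jet_radius = 20, lumen_radius_dia = 15),
               class = "pcmri_invalid_spec")
  expect_error(phantom_spec(lumen_radius_sys = 80),
               class = "pcmri_invalid_spec")
  expect_error(phantom_spec(lumen_radius_sys = 10, lumen_radius_dia = 12),
               class = "pcmri_invalid_spec")
  expect_error(phantom_spec(pressures = c(80, 120)),
               class = "pcmri_invalid_spec")
})
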