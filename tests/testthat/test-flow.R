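test_that("velocity decomposition projects onto the plane basis orthogonally", {
  # series with a rotated orthonormal basis and known plane components
  set.seed(11)
  d <- c(6L, 6L, 3L)
  b <- qr.Q(qr(matrix(rnorm(9), 3)))
  comp <- replicate(3, array(rnorm(prod(d), 0, 20), d), simplify = FALSE)
  patient <- lapply(1:3, function(k)
    comp[[1]] * b[k, 1] + comp[[2]] * b[k, 2] + comp[[3]] * b[k, 3])
  series <- velocity_encoded_series(
    magnitude = array(1, d), encoded = patient, venc = 200,
    pixel_spacing = c(1, 1), frame_times = c(10, 20, 30), rr_interval = 500,
    plane_basis = b, dialect = "velocity")
  dec <- decompose_velocity(series)
  expect_equal(dec$through, comp[[3]], tolerance = 1e-10)
  expect_equal(dec$inplane[[1]], comp[[1]], tolerance = 1e-10)
  # Pythagoras: |v|^2 = v_through^2 + |v_inplane|^2
  mag2 <- patient[[1]]^2 + patient[[2]]^2 + patient[[3]]^2
  dec2 <- dec$through^2 + dec$inplane[[1]]^2 + dec$inplane[[2]]^2
  expect_equal(dec2, mag2, tolerance = 1e-6)

  tampered <- series; tampered$plane_basis <- matrix(1, 3, 3)
  expect_error(decompose_velocity(tampered), class = "pcmri_metadata_error")
})

test_that("a tilted flow axis splits velocity as cos/sin between through- and in-plane maps", {
  spec <- noiseless_spec(n_frames = 12L, plane_tilt = 30)
  ph <- generate_phantom(spec)
  dec <- decompose_velocity(ph$series)
  f <- ph$truth$peak_frame
  thr <- dec$through[, , f]; inp <- dec$inplane[[1]][, , f]
  step <- max(ph$truth$venc) / 2048
  expect_lt(max(abs(inp - thr * tan(30 * pi / 180))), 3 * step)
  expect_equal(max(dec$inplane[[2]]), 0)
  # zero-flow diastolic frames decompose to zero everywhere
  expect_true(all(abs(dec$through[, , 12]) <= step))
})

test_that("volumetric flow integrates velocity over the mask with sign", {
  d <- c(20L, 20L, 2L)
  m <- array(FALSE, d); m[6:15, 6:15, ] <- TRUE   # 100 px = 1.96 cm^2
  lm <- lumen_mask_series(m, pixel_area = 0.0196)
  v <- array(0, d); v[, , 1][m[, , 1]] <- 50; v[, , 2][m[, , 2]] <- -10
  fw <- volumetric_flow(v, lm)
  expect_equal(fw$q, c(98, -19.6))
  expect_equal(fw$q_max, 98)
  expect_equal(fw$peak_frame, 1L)
  expect_equal(fw$q_mean, mean(c(98, -19.6)))
  expect_error(volumetric_flow(v[1:10, , , drop = FALSE], lm),
               class = "pcmri_invalid_spec")
})

test_that("the pipeline recovers the prescribed waveform from a noiseless phantom", {
  spec <- noiseless_spec()
  ph <- generate_phantom(spec)
  res <- analyze_series(ph$series)
  expect_lt(max(abs(res$flow$q - ph$truth$q_true)), 0.02 * spec$q_peak)
  expect_lt(abs(res$flow$q_max / ph$truth$qmax_true - 1), 0.02)
  # half-sine closed form: q_mean ~ (2/pi) * q_peak * s
  expect_equal(res$flow$q_mean, 2 / pi * spec$q_peak * spec$systole_fraction,
               tolerance = 0.02)
})

test_that("peak velocity matches the analytic profile peak and keeps its sign", {
  ph <- generate_phantom(noiseless_spec())          # parabolic: peak = 2*q/A
  res <- analyze_series(ph$series)
  step <- ph$truth$venc[3] / 2048
  expect_lt(abs(res$orifice$v_max - ph$truth$vmax_true), step)

  plug <- generate_phantom(noiseless_spec(profile = "plug"))
  rp <- analyze_series(plug$series)
  expect_lt(abs(rp$orifice$v_max - plug$truth$vmax_true),
            plug$truth$venc[3] / 2048)

  # all-retrograde frame: v_max is negative by convention
  d <- c(8L, 8L, 1L)
  m <- array(TRUE, d)
  lm <- lumen_mask_series(m, pixel_area = 0.0196)
  v <- array(-30, d)
  expect_equal(peak_velocity(v, lm, 1), -30)
})

test_that("effective orifice area follows the above-spatial-mean rule", {
  # full-lumen parabolic profile: the > mean region is r < R/sqrt(2), half the area
  ph <- generate_phantom(noiseless_spec())
  res <- analyze_series(ph$series)
  ring <- 2 * pi * (16 / sqrt(2) / 10) * 0.14       # one-pixel boundary ring, cm^2
  expect_lt(abs(res$orifice$a_orifice - res$orifice$a_sinus / 2), ring)
  expect_equal(res$orifice$orifice_ratio, 0.5, tolerance = 0.06)

  # plug jet: two-level field, mean strictly between levels -> EOA = jet area
  jet <- generate_phantom(phantom_spec(
    profile = "plug", jet_radius = 10, lumen_radius_sys = 18,
    lumen_radius_dia = 18, grid_shape = c(64L, 64L), n_frames = 12L,
    noise_sd = 0))
  rj <- analyze_series(jet$series)
  ring_j <- 2 * pi * 1.0 * 0.14
  expect_lt(abs(rj$orifice$a_orifice - pi * 1.0^2), ring_j)

  # exactly uniform full-lumen plug: strict inequality gives a zero EOA
  d <- c(10L, 10L, 1L)
  lm <- lumen_mask_series(array(TRUE, d), pixel_area = 0.0196)
  expect_equal(effective_orifice_area(array(55, d), lm, 1)$a_orifice, 0)
})

test_that("EOA equals exhaustive pixel enumeration and is scale-invariant", {
  set.seed(21)
  for (i in 1:5) {
    d <- c(16L, 16L, 1L)
    m <- array(FALSE, d)
    m[, , 1] <- matrix(runif(256) < 0.6, 16, 16)
    if (!any(m)) next
    v <- array(rnorm(prod(d), 10, 40), d)
    lm <- lumen_mask_series(m, pixel_area = 0.0196)
    om <- effective_orifice_area(v, lm, 1)
    expect_identical(om$a_orifice, oracle_eoa(v[, , 1], m[, , 1], 0.0196))
    expect_gte(om$a_orifice, 0)
    expect_lte(om$a_orifice, om$a_sinus)
    expect_true(om$orifice_ratio >= 0 && om$orifice_ratio <= 1)
    # invariance under positive rescaling of the whole field
    om2 <- effective_orifice_area(v * 3.7, lm, 1)
    expect_identical(om2$a_orifice, om$a_orifice)
  }
})
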