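#' Specification of a synthetic velocity-encoded phantom
#'
#' Describes a pulsatile circular lumen imaged by a 2D phase-contrast cine
#' sequence: grid geometry, flow waveform, velocity profile, wall pulsation,
#' velocity-encoding limits and noise. The defaults emulate a typical
#' aortic-root acquisition: 1.4 x 1.4 mm reconstructed pixels, 100 cardiac
#' phases per cycle, a half-sine systolic flow lobe peaking at 500 ml/s, a
#' lumen pulsating between 15 and 16 mm radius, and a central pressure pair
#' of 131/79 mmHg.
#'
#' @param grid_shape integer (ny, nx) image size in pixels.
#' @param pixel_spacing numeric (row, col) pixel size in mm.
#' @param n_frames number of cardiac phases reconstructed per cycle.
#' @param rr_interval R-R interval in ms.
#' @param lumen_center (row, col) of the lumen axis in 1-based pixel
#'   coordinates; defaults to a pixel center near the grid middle so that the
#'   analytic profile peak is sampled exactly.
#' @param lumen_radius_sys,lumen_radius_dia systolic / diastolic lumen radius
#'   in mm. The radius follows the normalized flow waveform, so the lumen is
#'   widest at peak flow.
#' @param profile velocity profile: "plug", "parabolic" or "womersley".
#' @param jet_radius optional radius (mm) of a concentric stenotic jet; when
#'   set, all flow passes through the jet sub-disc and the velocity is zero in
#'   the rest of the lumen.
#' @param q_peak peak volumetric flow in ml/s.
#' @param systole_fraction fraction of the cycle occupied by the systolic
#'   half-sine lobe, in (0, 1).
#' @param q_waveform optional explicit per-frame flow waveform (ml/s, length
#'   \code{n_frames}) overriding the half-sine construction.
#' @param venc velocity-encoding limit(s) in cm/s: scalar or length 3 (one per
#'   patient axis). \code{NULL} (default) selects 10\% above the true peak
#'   velocity on each axis, the usual prescription for avoiding aliasing.
#' @param noise_sd additive Gaussian velocity noise, cm/s (applied before
#'   phase encoding); 0 gives a noiseless phantom.
#' @param pressures numeric (Ps, Pd) central systolic/diastolic pressure in
#'   mmHg.
#' @param blood_density blood density in kg/m^3.
#' @param dynamic_viscosity blood dynamic viscosity in mPa.s.
#' @param plane_tilt angle in degrees between the flow axis and the imaging
#'   plane normal; a nonzero tilt moves a known fraction sin(tilt) of the
#'   velocity onto the first in-plane axis.
#' @param seed integer seed making the phantom reproducible.
#' @return An object of class \code{phantom_spec} (a validated list).
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L),
                         pixel_spacing = c(1.4, 1.4),
                         n_frames = 100L,
                         rr_interval = 880,
                         lumen_center = NULL,
                         lumen_radius_sys = 16,
                         lumen_radius_dia = 15,
                         profile = c("parabolic", "plug", "womersley"),
                         jet_radius = NULL,
                         q_peak = 500,
                         systole_fraction = 0.33,
                         q_waveform = NULL,
                         venc = NULL,
                         noise_sd = 5,
                         pressures = c(131, 79),
                         blood_density = 1060,
                         dynamic_viscosity = 4.0,
                         plane_tilt = 0,
                         seed = 1L) {
  profile <- match.arg(profile)
  grid_shape <- as.integer(grid_shape)
  n_frames <- as.integer(n_frames)
  if (length(grid_shape) != 2L || any(grid_shape < 8L))
    stop_invalid_spec("grid_shape must be two integers >= 8")
  if (n_frames < 4L)
    stop_invalid_spec("n_frames must be >= 4")
  if (!is_scalar_number(q_peak) || q_peak <= 0)
    stop_invalid_spec("q_peak must be a positive number")
  if (!is_scalar_number(systole_fraction) ||
      systole_fraction <= 0 || systole_fraction >= 1)
    stop_invalid_spec("systole_fraction must lie strictly in (0, 1)")
  if (lumen_radius_sys <= 0 || lumen_radius_dia <= 0)
    stop_invalid_spec("lumen radii must be positive")
  if (lumen_radius_sys < lumen_radius_dia)
    stop_invalid_spec("lumen_radius_sys must be >= lumen_radius_dia")
  if (is.null(lumen_center))
    lumen_center <- floor(grid_shape / 2) + 1
  half_extent <- (grid_shape - 1) / 2 * pixel_spacing
  if (lumen_radius_sys >= min(half_extent))
    stop_invalid_spec("systolic lumen radius does not fit inside the grid")
  if (!is.null(jet_radius)) {
    if (jet_radius <= 0 || jet_radius > lumen_radius_dia)
      stop_invalid_spec("jet_radius must be in (0, lumen_radius_dia]")
  }
  if (!is.null(venc) && any(venc <= 0))
    stop_invalid_spec("venc must be positive")
  if (!is.null(q_waveform)) {
    if (length(q_waveform) != n_frames || !all(is.finite(q_waveform)))
      stop_invalid_spec("q_waveform must be a finite vector of length n_frames")
  }
  if (length(pressures) != 2L || pressures[1] <= pressures[2] ||
      pressures[2] <= 0)
    stop_invalid_spec("pressures must be (Ps, Pd) with Ps > Pd > 0")
  if (noise_sd < 0) stop_invalid_spec("noise_sd must be >= 0")

  spec <- list(
    grid_shape = grid_shape, pixel_spacing = as.numeric(pixel_spacing),
    n_frames = n_frames, rr_interval = as.numeric(rr_interval),
    lumen_center = as.numeric(lumen_center),
    lumen_radius_sys = lumen_radius_sys,
    lumen_radius_dia = lumen_radius_dia,
    profile = profile, jet_radius = jet_radius,
    q_peak = q_peak, systole_fraction = systole_fraction,
    q_waveform = q_waveform, venc = venc, noise_sd = noise_sd,
    pressures = as.numeric(pressures), blood_density = blood_density,
    dynamic_viscosity = dynamic_viscosity, plane_tilt = plane_tilt,
    seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  spec
}

#' Half-sine systolic flow waveform
#'
#' Builds the prescribed volumetric flow waveform Q(t): a half-sine lobe
#' \eqn{Q(t) = Q_{peak} \sin(\pi t / T_s)} during systole
#' (\eqn{T_s = s \cdot RR}) and zero flow in diastole, sampled at the
#' midpoints of \code{n_frames} uniform frames across one R-R interval.
#'
#' @param q_peak peak flow in ml/s.
#' @param systole_fraction systolic fraction s of the cycle, in (0, 1).
#' @param n_frames number of frames (>= 4).
#' @param rr_interval cycle length in ms.
#' @return Numeric vector of per-frame flow values (ml/s) with the frame
#'   midpoint times (ms) attached as attribute \code{"times"}.
#' @examples
#' q <- make_flow_waveform(500, 0.33, 100, 880)
#' max(q)                      # ~ 500 ml/s
#' mean(q)                     # ~ (2/pi) * 500 * 0.33
#' @export
make_flow_waveform <- function(q_peak, systole_fraction, n_frames,
                               rr_interval = 1000) {
  if (!is_scalar_number(q_peak) || q_peak <= 0)
    stop_invalid_spec("q_peak must be a positive number")
  if (n_frames < 4L)
    stop_invalid_spec("n_frames must be >= 4")
  if (systole_fraction <= 0 || systole_fraction >= 1)
    stop_invalid_spec("systole_fraction must lie strictly in (0, 1)")
  times <- frame_midpoints(n_frames, rr_interval)
  ts <- systole_fraction * rr_interval
  q <- ifelse(times <= ts, q_peak * sin(pi * times / ts), 0)
  attr(q, "times") <- times
  q
}

frame_midpoints <- function(n_frames, rr_interval) {
  (seq_len(n_frames) - 0.5) / n_frames * rr_interval
}

# Per-frame waveform for a spec (explicit array wins over half-sine).
phantom_waveform <- function(spec) {
  if (!is.null(spec$q_waveform)) {
    q <- as.numeric(spec$q_waveform)
    attr(q, "times") <- frame_midpoints(spec$n_frames, spec$rr_interval)
    q
  } else {
    make_flow_waveform(spec$q_peak, spec$systole_fraction, spec$n_frames,
                       spec$rr_interval)
  }
}

# Lumen radius at one frame: diastolic radius plus the systolic excursion
# scaled by the normalized flow, so the wall distends in phase with flow.
lumen_radius_at <- function(spec, q_frame) {
  qn <- q_frame / max(phantom_waveform(spec))
  qn <- min(max(qn, 0), 1)
  spec$lumen_radius_dia + (spec$lumen_radius_sys - spec$lumen_radius_dia) * qn
}

# Radial distance (mm) of every pixel center from the lumen axis.
pixel_radii <- function(spec) {
  ny <- spec$grid_shape[1]; nx <- spec$grid_shape[2]
  dy <- (seq_len(ny) - spec$lumen_center[1]) * spec$pixel_spacing[1]
  dx <- (seq_len(nx) - spec$lumen_center[2]) * spec$pixel_spacing[2]
  sqrt(outer(dy^2, dx^2, `+`))
}

# Womersley number for harmonic k at radius R (mm).
womersley_alpha <- function(spec, k, radius_mm) {
  omega0 <- 2 * pi / (spec$rr_interval / 1000)           # rad/s
  nu <- (spec$dynamic_viscosity / 1000) / spec$blood_density  # m^2/s
  (radius_mm / 1000) * sqrt(k * omega0 / nu)
}

# Normalized oscillatory pipe-flow profile for one harmonic: integrates to 1
# over the unit disc ((1/pi) * int phi(rho) 2*pi*rho drho = 1), so each
# harmonic of Q is conserved exactly in the continuum.
womersley_profile <- function(rho, alpha) {
  if (alpha < 1e-3) return(2 * (1 - rho^2))   # Poiseuille limit
  lam <- alpha * complex(modulus = 1, argument = 3 * pi / 4)  # i^(3/2) alpha
  j0l <- besselJ0_complex(lam)
  denom <- j0l - 2 * besselJ1_complex(lam) / lam
  (j0l - besselJ0_complex(lam * rho)) / denom
}

# Fourier coefficients of the sampled waveform, for harmonic reconstruction:
# q[j] = Re( sum_k coef[k] * exp(i * w_k * t_j) ) exactly at the frame times.
waveform_harmonics <- function(q) {
  n <- length(q)
  ft <- stats::fft(q) / n
  kmax <- floor(n / 2)
  k <- seq_len(kmax)
  # samples live at frame midpoints t_j = (j - 1/2) T / n, not frame starts:
  # shift each coefficient by half a sample so the series interpolates q
  coef <- ft[k + 1L] * exp(-1i * pi * k / n)
  weight <- rep(2, kmax)
  if (n %% 2 == 0) weight[kmax] <- 1  # Nyquist term appears once
  list(dc = Re(ft[1]), k = k, coef = coef * weight)
}

#' Synthesize one through-plane velocity frame
#'
#' Evaluates the noiseless through-plane velocity map (cm/s) of the phantom at
#' one frame: zero outside the flow region, and inside it a plug, parabolic
#' (Poiseuille) or Womersley profile normalized so the continuum integral of
#' velocity over the flow cross-section equals the frame flow \code{q_frame}.
#' When \code{jet_radius} is set the flow region is the concentric jet
#' sub-disc rather than the whole lumen.
#'
#' @param spec a [phantom_spec()].
#' @param frame_index 1-based frame number (needed by the time-dependent
#'   Womersley profile).
#' @param q_frame flow at this frame in ml/s.
#' @return ny x nx matrix of velocities in cm/s.
#' @export
synthesize_velocity_frame <- function(spec, frame_index, q_frame) {
  if (!is_scalar_number(q_frame))
    stop_invalid_spec("q_frame must be a finite number")
  lumen_r <- lumen_radius_at(spec, q_frame)
  flow_r <- spec$jet_radius %||% lumen_r
  if (flow_r > lumen_r)
    stop_invalid_spec(sprintf(
      "jet_radius (%.2f mm) exceeds the lumen radius at frame %d (%.2f mm)",
      flow_r, frame_index, lumen_r))
  rr <- pixel_radii(spec)
  inside <- rr <= flow_r
  area_cm2 <- pi * (flow_r / 10)^2                 # flow cross-section, cm^2
  u <- matrix(0, nrow(rr), ncol(rr))

  if (spec$profile == "plug") {
    u[inside] <- q_frame / area_cm2
  } else if (spec$profile == "parabolic") {
    ubar <- q_frame / area_cm2
    u[inside] <- 2 * ubar * (1 - (rr[inside] / flow_r)^2)
  } else {  # womersley
    qv <- phantom_waveform(spec)
    h <- waveform_harmonics(qv)
    t_s <- attr(qv, "times")[frame_index] / 1000
    omega0 <- 2 * pi / (spec$rr_interval / 1000)
    rho <- rr[inside] / flow_r
    prof <- h$dc / area_cm2 * 2 * (1 - rho^2)
    for (i in seq_along(h$k)) {
      k <- h$k[i]
      alpha <- womersley_alpha(spec, k, flow_r)
      prof <- prof + Re(h$coef[i] / area_cm2 * womersley_profile(rho, alpha) *
                          exp(1i * k * omega0 * t_s))
    }
    u[inside] <- prof
  }
  u
}

# Continuum radial profile at one frame on a fine grid; used for analytic
# ground truth (peak velocity, effective orifice area) of any profile shape.
continuum_profile <- function(spec, frame_index, q_frame, n_points = 4096L) {
  lumen_r <- lumen_radius_at(spec, q_frame)
  flow_r <- spec$jet_radius %||% lumen_r
  area_cm2 <- pi * (flow_r / 10)^2
  rho <- (seq_len(n_points) - 0.5) / n_points
  u <- switch(spec$profile,
    plug = rep(q_frame / area_cm2, n_points),
    parabolic = 2 * (q_frame / area_cm2) * (1 - rho^2),
    womersley = {
      qv <- phantom_waveform(spec)
      h <- waveform_harmonics(qv)
      t_s <- attr(qv, "times")[frame_index] / 1000
      omega0 <- 2 * pi / (spec$rr_interval / 1000)
      prof <- h$dc / area_cm2 * 2 * (1 - rho^2)
      for (i in seq_along(h$k)) {
        alpha <- womersley_alpha(spec, h$k[i], flow_r)
        prof <- prof + Re(h$coef[i] / area_cm2 *
                            womersley_profile(rho, alpha) *
                            exp(1i * h$k[i] * omega0 * t_s))
      }
      prof
    })
  list(rho = rho, u = u, flow_radius = flow_r, lumen_radius = lumen_r,
       area_cm2 = area_cm2)
}

# Analytic effective orifice area of the noiseless profile at the peak-flow
# frame, under the "velocity above the lumen spatial mean" rule.
truth_eoa <- function(spec, peak_frame, q_peak_frame) {
  cp <- continuum_profile(spec, peak_frame, q_peak_frame)
  lumen_area <- pi * (cp$lumen_radius / 10)^2
  vbar <- q_peak_frame / lumen_area            # spatial mean over whole lumen
  # area fraction of the *flow* disc where u > vbar, plus zero-flow annulus
  frac <- sum((cp$u > vbar) * 2 * cp$rho) / length(cp$rho)
  frac * cp$area_cm2
}

#' Generate a synthetic velocity-encoded series with ground truth
#'
#' Renders the phantom described by \code{spec} into a complete
#' [velocity_encoded_series()]: a magnitude stack (bright lumen on a dark
#' background), three patient-axis velocity stacks phase-encoded at the VENC
#' of each axis, and all acquisition metadata; alongside a
#' \code{phantom_truth} list holding every analytically known quantity that
#' the analysis pipeline is expected to recover.
#'
#' Velocity noise (\code{noise_sd}, cm/s) is added to each axis before phase
#' encoding; magnitude noise uses the same standard deviation in intensity
#' units (lumen 100, background 10). With \code{plane_tilt} nonzero, the flow
#' vector is tilted by that angle towards the first in-plane axis, so the
#' through-plane map carries cos(tilt) of the velocity and the first in-plane
#' map sin(tilt).
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements \code{series} (class
#'   \code{velocity_encoded_series}) and \code{truth} (class
#'   \code{phantom_truth}: \code{q_true}, \code{qmax_true}, \code{qmean_true},
#'   \code{vmax_true}, \code{eoa_true}, \code{a_sys}, \code{a_dia},
#'   \code{d_sys}, \code{d_dia}, pressures and the elasticity indices implied
#'   by them).
#' @examples
#' ph <- generate_phantom(phantom_spec(noise_sd = 0))
#' ph$truth$qmax_true
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  q <- phantom_waveform(spec)
  times <- attr(q, "times")
  n <- spec$n_frames
  ny <- spec$grid_shape[1]; nx <- spec$grid_shape[2]

  u_thr <- array(0, c(ny, nx, n))
  mag <- array(0, c(ny, nx, n))
  for (f in seq_len(n)) {
    u_thr[, , f] <- synthesize_velocity_frame(spec, f, q[f])
    lum <- pixel_radii(spec) <= lumen_radius_at(spec, q[f])
    mag[, , f] <- ifelse(lum, 100, 10)
  }

  tilt <- spec$plane_tilt * pi / 180
  v_through <- u_thr * cos(tilt)
  v_in1 <- u_thr * sin(tilt)
  v_in2 <- array(0, c(ny, nx, n))

  # identity plane basis: in-plane axes = patient x, y; normal = patient z
  basis <- diag(3)
  vx <- v_in1; vy <- v_in2; vz <- v_through

  if (spec$noise_sd > 0) {
    vx <- vx + array(stats::rnorm(length(vx), 0, spec$noise_sd), dim(vx))
    vy <- vy + array(stats::rnorm(length(vy), 0, spec$noise_sd), dim(vy))
    vz <- vz + array(stats::rnorm(length(vz), 0, spec$noise_sd), dim(vz))
    mag <- mag + array(stats::rnorm(length(mag), 0, spec$noise_sd), dim(mag))
  }

  venc <- spec$venc
  if (is.null(venc)) {
    venc <- 1.1 * c(max(abs(vx)), max(abs(vy)), max(abs(vz)))
    venc <- pmax(venc, 1)   # a zero-signal axis still needs a positive VENC
  } else if (length(venc) == 1L) {
    venc <- rep(venc, 3)
  }

  encoded <- list(encode_phase(vx, venc[1]),
                  encode_phase(vy, venc[2]),
                  encode_phase(vz, venc[3]))

  series <- velocity_encoded_series(
    magnitude = mag, encoded = encoded, venc = venc,
    pixel_spacing = spec$pixel_spacing, frame_times = times,
    rr_interval = spec$rr_interval, plane_basis = basis,
    dialect = "raw_phase")

  peak_frame <- which.max(q)[1]
  cp <- continuum_profile(spec, peak_frame, q[peak_frame])
  a_sys <- pi * (spec$lumen_radius_sys / 10)^2   # cm^2
  a_dia <- pi * (spec$lumen_radius_dia / 10)^2
  d_sys <- diameter_from_area(a_sys)
  d_dia <- diameter_from_area(a_dia)
  p <- pressure_pair(spec$pressures[1], spec$pressures[2])

  truth <- list(
    q_true = as.numeric(q), times = times,
    qmax_true = max(q), qmean_true = mean(q),
    vmax_true = max(cp$u) * cos(tilt),
    eoa_true = truth_eoa(spec, peak_frame, q[peak_frame]),
    peak_frame = peak_frame,
    a_sys = a_sys, a_dia = a_dia, d_sys = d_sys, d_dia = d_dia,
    pressures = spec$pressures,
    compliance_true = compliance(a_sys, a_dia, p),
    distensibility_true = distensibility(a_sys, a_dia, p),
    beta_true = if (d_sys > d_dia) stiffness_beta(d_sys, d_dia, p)
                else NA_real_,  # non-pulsating lumen: beta undefined
    venc = venc
  )
  class(truth) <- "phantom_truth"
  list(series = series, truth = truth)
}

#' Phase-encode a velocity map
#'
#' Maps velocity to phase, \eqn{\phi = \pi v / VENC}, wraps it into
#' \eqn{[-\pi, \pi)} (velocities at or beyond the VENC alias), and quantizes
#' linearly to 12-bit signed integers in \eqn{[-2048, 2047]} with
#' \eqn{-2048 \mapsto -\pi}, emulating raw scanner phase storage.
#'
#' @param velocity_map velocities in cm/s (any shape).
#' @param venc velocity-encoding limit in cm/s (> 0).
#' @return Integer array of stored phase values, same shape as the input.
#' @seealso [phase_to_velocity()] for the inverse.
#' @export
encode_phase <- function(velocity_map, venc) {
  if (!is_scalar_number(venc) || venc <= 0)
    stop_invalid_spec("venc must be a positive number")
  phi <- pi * velocity_map / venc
  phi <- (phi + pi) %% (2 * pi) - pi           # wrap into [-pi, pi)
  # floor (not round) quantization: phi < pi strictly maps to <= 2047, so any
  # unaliased velocity survives the round trip within one step venc/2048
  stored <- floor(phi / pi * 2048)
  stored <- ((stored + 2048) %% 4096) - 2048   # float-boundary safety
  storage <- array(as.integer(stored), dim = dim(velocity_map) %||%
                     length(velocity_map))
  if (is.null(dim(velocity_map))) as.integer(stored) else storage
}
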