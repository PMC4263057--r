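#' Decompose encoded velocities into through-plane and in-plane components
#'
#' Decodes the three patient-axis stacks to cm/s ([phase_to_velocity()]) and
#' projects the velocity 3-vector of every pixel onto the imaging-plane
#' basis: the through-plane component along the plane normal, and the
#' residual 2-vector along the two in-plane axes. The decomposition is
#' orthogonal, so \eqn{|v|^2 = v_{through}^2 + |v_{inplane}|^2}.
#'
#' @param series a [velocity_encoded_series()].
#' @return List with \code{through} (ny x nx x n_frames, cm/s) and
#'   \code{inplane} (list of two stacks along the in-plane axes).
#' @export
decompose_velocity <- function(series) {
  stopifnot(inherits(series, "velocity_encoded_series"))
  b <- series$plane_basis
  if (max(abs(crossprod(b) - diag(3))) > 1e-6)
    stop_metadata("plane_basis is not orthonormal", fields = "plane_basis")
  v <- lapply(1:3, function(i)
    phase_to_velocity(series$encoded[[i]], series$venc[i], series$dialect))
  proj <- function(axis)  # axis: unit vector in patient coordinates
    v[[1]] * axis[1] + v[[2]] * axis[2] + v[[3]] * axis[3]
  list(through = proj(b[, 3]),
       inplane = list(proj(b[, 1]), proj(b[, 2])))
}

#' Volumetric flow waveform from a through-plane velocity stack
#'
#' Integrates the through-plane velocity over the segmented lumen at each
#' frame: \eqn{Q(t) = \sum_{mask} v \cdot a_{pixel}} (cm/s x cm^2 = ml/s).
#' Retrograde (negative) pixels enter with their sign. The temporal maximum
#' \eqn{Q_{max}}, the whole-cycle time average \eqn{Q_{mean}} (diastolic
#' zero/retrograde frames included) and the earliest peak frame are derived
#' from the waveform.
#'
#' @param through_stack ny x nx x n_frames velocities in cm/s (e.g. from
#'   [decompose_velocity()]).
#' @param masks a [lumen_mask_series()] congruent with the stack.
#' @param frame_times optional frame times in ms, stored alongside.
#' @return Object of class \code{flow_waveform}: \code{times}, \code{q}
#'   (ml/s), \code{q_max}, \code{q_mean}, \code{peak_frame}.
#' @export
volumetric_flow <- function(through_stack, masks, frame_times = NULL) {
  stopifnot(inherits(masks, "lumen_mask_series"))
  if (!identical(dim(through_stack), dim(masks$masks)))
    stop_invalid_spec("velocity stack and masks have different shapes")
  n <- dim(through_stack)[3]
  q <- vapply(seq_len(n), function(f) {
    m <- masks$masks[, , f]
    if (!any(m)) stop_segmentation(sprintf("empty mask at frame %d", f),
                                   frame = f)
    sum(through_stack[, , f][m]) * masks$pixel_area
  }, numeric(1))
  structure(list(
    times = frame_times %||% seq_len(n), q = q,
    q_max = max(q), q_mean = mean(q), peak_frame = which.max(q)[1]
  ), class = "flow_waveform")
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf(
    "flow_waveform: %d frames, Qmax %.1f ml/s (frame %d), Qmean %.1f ml/s\n",
    length(x$q), x$q_max, x$peak_frame, x$q_mean))
  invisible(x)
}

#' @export
plot.flow_waveform <- function(x, ...) {
  plot(x$times, x$q, type = "l", xlab = "time (ms)", ylab = "Q (ml/s)",
       main = "Volumetric flow waveform", ...)
  graphics::points(x$times[x$peak_frame], x$q_max, pch = 19)
  invisible(x)
}

#' Peak spatial velocity at the peak-flow frame
#'
#' Maximum signed through-plane velocity over the lumen mask at the frame of
#' peak volumetric flow. The sign convention is kept: a frame dominated by
#' retrograde flow yields a negative value.
#'
#' @inheritParams volumetric_flow
#' @param peak_frame frame index of peak flow (e.g.
#'   \code{flow_waveform$peak_frame}).
#' @return Peak velocity in cm/s.
#' @export
peak_velocity <- function(through_stack, masks, peak_frame) {
  stopifnot(inherits(masks, "lumen_mask_series"))
  n <- dim(through_stack)[3]
  if (peak_frame < 1 || peak_frame > n)
    stop_invalid_spec("peak_frame out of range")
  m <- masks$masks[, , peak_frame]
  max(through_stack[, , peak_frame][m])
}

#' Effective orifice area at peak flow
#'
#' The effective orifice area (EOA) is the lumen area where the
#' through-plane velocity strictly exceeds the spatial mean velocity over the
#' lumen at the peak-flow frame. The spatial mean is taken over the full
#' lumen mask with signs retained (\code{averaging = "signed"}); a
#' sensitivity variant averages antegrade pixels only
#' (\code{averaging = "positive"}). For an exactly uniform velocity field the
#' strict inequality yields a zero EOA (degenerate by construction).
#'
#' Also reported: \code{a_sinus}, the segmented lumen area at the peak frame,
#' and \code{orifice_ratio = a_orifice / a_sinus}. Note the lumen area from
#' this PC-MRI segmentation need not match a sinus area measured on separate
#' anatomic 3D imaging; \code{a_sinus_source} records the provenance.
#'
#' @inheritParams peak_velocity
#' @param averaging velocity-averaging rule for the threshold.
#' @return Object of class \code{orifice_metrics}: \code{v_max} (cm/s),
#'   \code{v_threshold} (cm/s), \code{a_orifice}, \code{a_sinus} (cm^2),
#'   \code{orifice_ratio}, \code{averaging}, \code{a_sinus_source}.
#' @export
effective_orifice_area <- function(through_stack, masks, peak_frame,
                                   averaging = c("signed", "positive")) {
  averaging <- match.arg(averaging)
  stopifnot(inherits(masks, "lumen_mask_series"))
  n <- dim(through_stack)[3]
  if (peak_frame < 1 || peak_frame > n)
    stop_invalid_spec("peak_frame out of range")
  m <- masks$masks[, , peak_frame]
  v <- through_stack[, , peak_frame][m]
  vbar <- if (averaging == "signed") mean(v) else mean(v[v > 0])
  a_orifice <- sum(v > vbar) * masks$pixel_area
  a_sinus <- sum(m) * masks$pixel_area
  structure(list(
    v_max = max(v), v_threshold = vbar,
    a_orifice = a_orifice, a_sinus = a_sinus,
    orifice_ratio = a_orifice / a_sinus,
    averaging = averaging, a_sinus_source = "pcmri_segmentation"
  ), class = "orifice_metrics")
}

#' @export
print.orifice_metrics <- function(x, ...) {
  cat(sprintf(
    "orifice_metrics: EOA %.2f cm^2 of %.2f cm^2 lumen (ratio %.2f), Vmax %.1f cm/s\n",
    x$a_orifice, x$a_sinus, x$orifice_ratio, x$v_max))
  invisible(x)
}

#' Full hemodynamic analysis of one series
#'
#' One-call pipeline for a single subject: segment (or accept) lumen masks,
#' decompose velocities, reconstruct the flow waveform, and compute the peak
#' velocity, effective orifice area and wall-elasticity indices.
#'
#' @param series a [velocity_encoded_series()].
#' @param pressures a [pressure_pair()] (mmHg) for the elasticity indices,
#'   or \code{NULL} to skip them.
#' @param masks optional [lumen_mask_series()]; segmented from the magnitude
#'   stack when absent.
#' @param roi_box,seed_point forwarded to [segment_lumen()].
#' @param eoa_averaging forwarded to [effective_orifice_area()].
#' @param smooth_area forwarded to [area_waveform()].
#' @return List with \code{flow} (\code{flow_waveform}), \code{orifice}
#'   (\code{orifice_metrics}), \code{elasticity}
#'   (\code{elasticity_indices} or NULL), \code{area} (cm^2 per frame) and
#'   \code{masks}.
#' @export
analyze_series <- function(series, pressures = NULL, masks = NULL,
                           roi_box = NULL, seed_point = NULL,
                           eoa_averaging = "signed", smooth_area = FALSE) {
  if (is.null(masks))
    masks <- segment_lumen(series, roi_box = roi_box, seed_point = seed_point)
  dec <- decompose_velocity(series)
  fw <- volumetric_flow(dec$through, masks, frame_times = series$frame_times)
  om <- effective_orifice_area(dec$through, masks, fw$peak_frame,
                               averaging = eoa_averaging)
  aw <- area_waveform(masks, smooth = smooth_area)
  el <- if (!is.null(pressures)) elasticity_indices(aw, pressures) else NULL
  list(flow = fw, orifice = om, elasticity = el, area = aw, masks = masks)
}
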