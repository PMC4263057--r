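#' Lumen diameter from cross-sectional area
#'
#' Effective circular diameter of a cross-section,
#' \eqn{D = 2\sqrt{A/\pi}}, the convention used to turn aortic-root areas
#' into sinus diameters. Exact inverse of \eqn{A = \pi (D/2)^2}.
#'
#' @param area cross-sectional area (> 0), any length unit squared.
#' @return Diameter in the corresponding length unit.
#' @examples
#' diameter_from_area(7.8)  # 3.15 cm for a 7.8 cm^2 sinus
#' @export
diameter_from_area <- function(area) {
  if (any(!is.finite(area)) || any(area <= 0))
    stop_pcmri("area must be positive", "pcmri_domain_error")
  2 * sqrt(area / pi)
}

#' Systolic and diastolic extrema of an area waveform
#'
#' @param area_waveform per-frame lumen area over one cardiac cycle (>= 4
#'   frames), any unit.
#' @return List with \code{a_s} (maximum), \code{a_d} (minimum) and the
#'   earliest frames attaining them (\code{frame_s}, \code{frame_d}).
#' @export
area_extrema <- function(area_waveform) {
  if (length(area_waveform) < 4L)
    stop_invalid_spec("area waveform needs at least 4 frames")
  list(a_s = max(area_waveform), a_d = min(area_waveform),
       frame_s = which.max(area_waveform)[1],
       frame_d = which.min(area_waveform)[1])
}

area_cm2_to_mm2 <- function(a) a * 100

#' Aortic wall compliance
#'
#' Absolute lumen-area change per unit pulse pressure,
#' \eqn{(A_s - A_d) / (P_s - P_d)}, with areas in mm^2 and pressures in mmHg.
#' The \code{"table"} unit scales the raw mm^2/mmHg value by 10^3, matching
#' the \eqn{mm^2 \cdot mmHg^{-1} \cdot 10^{-3}} column convention of clinical
#' summary tables.
#'
#' @param a_s,a_d systolic / diastolic lumen area in cm^2.
#' @param p a [pressure_pair()].
#' @param units \code{"table"} (raw x 1000) or \code{"raw"} (mm^2/mmHg).
#' @return Compliance in the requested unit.
#' @export
compliance <- function(a_s, a_d, p, units = c("table", "raw")) {
  units <- match.arg(units)
  stopifnot(inherits(p, "pressure_pair"))
  if (a_s < a_d)
    stop_pcmri("a_s must be >= a_d", "pcmri_domain_error")
  raw <- (area_cm2_to_mm2(a_s) - area_cm2_to_mm2(a_d)) / (p$ps - p$pd)
  if (units == "raw") raw else raw * 1e3
}

#' Aortic wall distensibility
#'
#' Fractional lumen-area change per unit pulse pressure,
#' \eqn{((A_s - A_d)/A_d) / (P_s - P_d)} in mmHg^-1 (dimensionless numerator,
#' so the area unit cancels). The \code{"table"} unit scales by 10^3
#' (\eqn{mmHg^{-1} \cdot 10^{-3}} column convention).
#'
#' @inheritParams compliance
#' @return Distensibility in the requested unit.
#' @export
distensibility <- function(a_s, a_d, p, units = c("table", "raw")) {
  units <- match.arg(units)
  stopifnot(inherits(p, "pressure_pair"))
  if (a_d <= 0 || a_s < a_d)
    stop_pcmri("need a_s >= a_d > 0", "pcmri_domain_error")
  raw <- ((a_s - a_d) / a_d) / (p$ps - p$pd)
  if (units == "raw") raw else raw * 1e3
}

#' Stiffness index beta
#'
#' \eqn{\beta = \ln(P_s/P_d) / (D_s - D_d)} with diameters in cm (per-cm
#' units). This is the unnormalized form; the conventional dimensionless
#' stiffness index divides the diameter excursion by the diastolic diameter,
#' \eqn{\beta = \ln(P_s/P_d) / ((D_s - D_d)/D_d)}, and is returned when
#' \code{normalized = TRUE}. Both are reported by [elasticity_indices()];
#' neither is silently substituted for the other.
#'
#' @param d_s,d_d systolic / diastolic effective diameter in cm
#'   (\code{d_s > d_d}).
#' @param p a [pressure_pair()].
#' @param normalized use the conventional diastolic-diameter normalization.
#' @return Stiffness index (cm^-1 unnormalized, dimensionless normalized).
#' @export
stiffness_beta <- function(d_s, d_d, p, normalized = FALSE) {
  stopifnot(inherits(p, "pressure_pair"))
  if (!(d_s > d_d))
    stop_pcmri("stiffness index requires d_s > d_d", "pcmri_domain_error")
  delta <- if (normalized) (d_s - d_d) / d_d else d_s - d_d
  log(p$ps / p$pd) / delta
}

#' All wall-elasticity indices from an area waveform
#'
#' Convenience wrapper: extracts systolic/diastolic area extrema, converts
#' them to effective diameters, and computes compliance, distensibility and
#' both stiffness-index conventions against a central pressure pair.
#'
#' @param area_waveform per-frame lumen area in cm^2 (e.g. from
#'   [area_waveform()]).
#' @param p a [pressure_pair()] in mmHg.
#' @return Object of class \code{elasticity_indices}: a list with
#'   \code{a_s}, \code{a_d} (cm^2), \code{d_s}, \code{d_d} (cm), \code{p_s},
#'   \code{p_d} (mmHg), \code{compliance}, \code{distensibility} (table
#'   units, with \code{*_raw} companions), \code{beta} (cm^-1, as-printed
#'   convention) and \code{beta_normalized} (dimensionless).
#' @export
elasticity_indices <- function(area_waveform, p) {
  ext <- area_extrema(area_waveform)
  d_s <- diameter_from_area(ext$a_s)
  d_d <- diameter_from_area(ext$a_d)
  structure(list(
    a_s = ext$a_s, a_d = ext$a_d, d_s = d_s, d_d = d_d,
    p_s = p$ps, p_d = p$pd,
    compliance = compliance(ext$a_s, ext$a_d, p),
    compliance_raw = compliance(ext$a_s, ext$a_d, p, units = "raw"),
    distensibility = distensibility(ext$a_s, ext$a_d, p),
    distensibility_raw = distensibility(ext$a_s, ext$a_d, p, units = "raw"),
    beta = if (d_s > d_d) stiffness_beta(d_s, d_d, p) else NA_real_,
    beta_normalized = if (d_s > d_d)
      stiffness_beta(d_s, d_d, p, normalized = TRUE) else NA_real_
  ), class = "elasticity_indices")
}

#' @export
print.elasticity_indices <- function(x, ...) {
  cat(sprintf("elasticity_indices: As %.2f / Ad %.2f cm^2, Ds %.2f / Dd %.2f cm\n",
              x$a_s, x$a_d, x$d_s, x$d_d))
  cat(sprintf("  compliance %.1f (mm^2 mmHg^-1 1e-3), distensibility %.2f (mmHg^-1 1e-3)\n",
              x$compliance, x$distensibility))
  cat(sprintf("  beta %.3f cm^-1 (as-printed), %.3f (Dd-normalized)\n",
              x$beta, x$beta_normalized))
  invisible(x)
}
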