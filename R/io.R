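#' A velocity-encoded (phase-contrast) image series at one plane
#'
#' The in-memory container for one 2D cine phase-contrast acquisition:
#' a magnitude stack plus three direction-encoded stacks (one per patient
#' axis), with the metadata needed to decode and orient them.
#'
#' @param magnitude ny x nx x n_frames array, arbitrary intensity units.
#' @param encoded list of three stacks of the same shape, one per patient
#'   axis (x, y, z): raw 12-bit stored phase integers when
#'   \code{dialect = "raw_phase"}, or already-decoded velocities in cm/s when
#'   \code{dialect = "velocity"}.
#' @param venc velocity-encoding limit per axis, cm/s (length 3, or scalar
#'   recycled).
#' @param pixel_spacing (row, col) pixel size in mm.
#' @param frame_times frame midpoint times in ms, strictly increasing, within
#'   \code{[0, rr_interval)}.
#' @param rr_interval R-R interval in ms.
#' @param plane_basis 3 x 3 orthonormal matrix whose columns are the two
#'   in-plane axes and the plane normal, expressed in patient axes
#'   (x = left-right, y = anterior-posterior, z = feet-head).
#' @param dialect phase-storage dialect, \code{"raw_phase"} or
#'   \code{"velocity"}.
#' @return An object of class \code{velocity_encoded_series}.
#' @export
velocity_encoded_series <- function(magnitude, encoded, venc, pixel_spacing,
                                    frame_times, rr_interval,
                                    plane_basis = diag(3),
                                    dialect = c("raw_phase", "velocity")) {
  dialect <- match.arg(dialect)
  bad <- character()
  if (length(dim(magnitude)) != 3L) bad <- c(bad, "magnitude")
  if (!is.list(encoded) || length(encoded) != 3L ||
      !all(vapply(encoded, function(e)
        identical(dim(e), dim(magnitude)), logical(1))))
    bad <- c(bad, "encoded")
  if (length(venc) == 1L) venc <- rep(venc, 3)
  if (length(venc) != 3L || any(!is.finite(venc)) || any(venc <= 0))
    bad <- c(bad, "venc")
  if (length(pixel_spacing) != 2L || any(pixel_spacing <= 0))
    bad <- c(bad, "pixel_spacing")
  n <- dim(magnitude)[3]
  if (length(frame_times) != n || any(diff(frame_times) <= 0) ||
      frame_times[1] < 0 || frame_times[length(frame_times)] >= rr_interval)
    bad <- c(bad, "frame_times")
  if (!is_scalar_number(rr_interval) || rr_interval <= 0)
    bad <- c(bad, "rr_interval")
  if (!is.matrix(plane_basis) || any(dim(plane_basis) != 3L) ||
      max(abs(crossprod(plane_basis) - diag(3))) > 1e-6)
    bad <- c(bad, "plane_basis")
  if (length(bad))
    stop_metadata(paste0("invalid series metadata: ",
                         paste(bad, collapse = ", ")), fields = bad)
  structure(list(
    magnitude = magnitude, encoded = encoded, venc = as.numeric(venc),
    pixel_spacing = as.numeric(pixel_spacing),
    frame_times = as.numeric(frame_times),
    rr_interval = as.numeric(rr_interval),
    plane_basis = plane_basis, dialect = dialect
  ), class = "velocity_encoded_series")
}

#' @export
print.velocity_encoded_series <- function(x, ...) {
  d <- dim(x$magnitude)
  cat(sprintf(
    "velocity_encoded_series: %d x %d pixels, %d frames (%s dialect)\n",
    d[1], d[2], d[3], x$dialect))
  cat(sprintf("  pixel spacing %.2f x %.2f mm; RR %.0f ms; VENC %s cm/s\n",
              x$pixel_spacing[1], x$pixel_spacing[2], x$rr_interval,
              paste(signif(x$venc, 4), collapse = "/")))
  invisible(x)
}

#' A systolic/diastolic central pressure pair
#'
#' @param ps systolic pressure, mmHg.
#' @param pd diastolic pressure, mmHg.
#' @return Object of class \code{pressure_pair}.
#' @export
pressure_pair <- function(ps, pd) {
  if (!is_scalar_number(ps) || !is_scalar_number(pd) || !(ps > pd) || pd <= 0)
    stop_invalid_spec("pressures must satisfy ps > pd > 0")
  structure(list(ps = ps, pd = pd), class = "pressure_pair")
}

series_stack_names <- c("mag", "vx", "vy", "vz")

#' Write / read a velocity-encoded series on disk
#'
#' The on-disk layout is four NIfTI-1 volumes (\code{mag.nii.gz},
#' \code{vx.nii.gz}, \code{vy.nii.gz}, \code{vz.nii.gz}) plus a
#' \code{series.json} sidecar carrying \code{venc} (cm/s per axis),
#' \code{pixel_spacing} (mm), \code{frame_times} (ms), \code{rr_interval}
#' (ms), \code{plane_basis} (column-wise, patient axes) and \code{dialect}.
#' \code{write_series} followed by \code{read_series} is an identity on all
#' arrays and metadata.
#'
#' @param series a [velocity_encoded_series()].
#' @param path directory to write into (created if absent) / to read from.
#' @return \code{write_series} returns \code{path} invisibly;
#'   \code{read_series} returns the reconstructed series.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "velocity_encoded_series"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  stacks <- c(list(series$magnitude), series$encoded)
  for (i in seq_along(stacks)) {
    RNifti::writeNifti(RNifti::asNifti(stacks[[i]],
                                       pixdim = c(series$pixel_spacing, 1)),
                       file.path(path, paste0(series_stack_names[i], ".nii.gz")))
  }
  sidecar <- list(
    venc = series$venc, pixel_spacing = series$pixel_spacing,
    frame_times = series$frame_times, rr_interval = series$rr_interval,
    plane_basis = series$plane_basis, dialect = series$dialect,
    units = list(venc = "cm/s", pixel_spacing = "mm", frame_times = "ms",
                 rr_interval = "ms")
  )
  jsonlite::write_json(sidecar, file.path(path, "series.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "columnmajor")
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  sc_path <- file.path(path, "series.json")
  if (!file.exists(sc_path))
    stop_metadata(sprintf("sidecar not found: %s", sc_path),
                  fields = "series.json")
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  required <- c("venc", "pixel_spacing", "frame_times", "rr_interval",
                "plane_basis", "dialect")
  missing <- setdiff(required, names(sc))
  if (length(missing))
    stop_metadata(paste0("sidecar missing required fields: ",
                         paste(missing, collapse = ", ")), fields = missing)
  stacks <- lapply(series_stack_names, function(nm) {
    f <- file.path(path, paste0(nm, ".nii.gz"))
    if (!file.exists(f))
      stop_metadata(sprintf("missing volume: %s", f), fields = nm)
    arr <- as.array(RNifti::readNifti(f))
    arr <- array(as.vector(arr),
                 utils::head(c(dim(arr), 1, 1), 3))  # plain array, 3D
    arr
  })
  enc <- stacks[2:4]
  if (identical(sc$dialect, "raw_phase"))
    enc <- lapply(enc, function(e) array(as.integer(round(e)), dim(e)))
  velocity_encoded_series(
    magnitude = stacks[[1]], encoded = enc, venc = sc$venc,
    pixel_spacing = sc$pixel_spacing, frame_times = sc$frame_times,
    rr_interval = sc$rr_interval,
    plane_basis = matrix(unlist(sc$plane_basis), 3, 3),
    dialect = sc$dialect)
}

#' Convert stored phase to velocity under the VENC convention
#'
#' For the \code{"raw_phase"} dialect, stored 12-bit integers in
#' \eqn{[-2048, 2047]} map linearly to velocity as
#' \eqn{v = VENC \cdot stored / 2048} (so \eqn{-2048 \mapsto -VENC}); for the
#' \code{"velocity"} dialect values are already cm/s and pass through.
#' Decoded magnitudes never exceed the VENC.
#'
#' @param encoded_stack stored values (any shape).
#' @param venc velocity-encoding limit, cm/s.
#' @param dialect \code{"raw_phase"} or \code{"velocity"}.
#' @return Velocities in cm/s, same shape.
#' @export
phase_to_velocity <- function(encoded_stack, venc,
                              dialect = c("raw_phase", "velocity")) {
  dialect <- match.arg(dialect)
  if (!is_scalar_number(venc) || venc <= 0)
    stop_invalid_spec("venc must be a positive number")
  if (dialect == "velocity") {
    if (any(abs(encoded_stack) > venc + 1e-9, na.rm = TRUE))
      stop_corrupt_data("velocity-dialect values exceed the stated VENC")
    return(encoded_stack)
  }
  if (any(encoded_stack < -2048 | encoded_stack > 2047, na.rm = TRUE))
    stop_corrupt_data("stored phase values outside the 12-bit range [-2048, 2047]")
  venc * encoded_stack / 2048
}
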