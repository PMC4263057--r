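#' Per-frame lumen mask series
#'
#' @param masks logical ny x nx x n_frames stack, one lumen mask per frame.
#' @param pixel_area pixel area in cm^2.
#' @param source \code{"auto"} (from [segment_lumen()]) or \code{"provided"}
#'   (externally drawn masks).
#' @return Object of class \code{lumen_mask_series}.
#' @export
lumen_mask_series <- function(masks, pixel_area,
                              source = c("auto", "provided")) {
  source <- match.arg(source)
  if (!is.logical(masks) || length(dim(masks)) != 3L)
    stop_invalid_spec("masks must be a logical ny x nx x n_frames array")
  if (!is_scalar_number(pixel_area) || pixel_area <= 0)
    stop_invalid_spec("pixel_area must be positive (cm^2)")
  counts <- apply(masks, 3, sum)
  if (any(counts == 0L))
    stop_segmentation(sprintf("empty lumen mask at frame %d",
                              which(counts == 0L)[1]),
                      frame = which(counts == 0L)[1])
  structure(list(masks = masks, pixel_area = pixel_area, source = source),
            class = "lumen_mask_series")
}

pixel_area_cm2 <- function(pixel_spacing_mm) {
  pixel_spacing_mm[1] * pixel_spacing_mm[2] / 100
}

# Otsu + largest (or seeded) connected component + hole fill, on one frame.
segment_frame <- function(frame, roi_box, seed_point, frame_index) {
  r0 <- roi_box[1]; c0 <- roi_box[2]; r1 <- roi_box[3]; c1 <- roi_box[4]
  sub <- frame[r0:r1, c0:c1]
  rng <- range(sub)
  if (diff(rng) <= 0)
    stop_segmentation(
      sprintf("cannot segment frame %d: constant magnitude in ROI",
              frame_index), frame = frame_index)
  x01 <- (sub - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(x01))
  fg <- x01 > th
  if (!any(fg))
    stop_segmentation(sprintf("empty foreground at frame %d", frame_index),
                      frame = frame_index)
  lab <- EBImage::bwlabel(fg)
  pick <- NA_integer_
  if (!is.null(seed_point)) {
    sr <- seed_point[1] - r0 + 1L; sc <- seed_point[2] - c0 + 1L
    if (sr >= 1 && sr <= nrow(lab) && sc >= 1 && sc <= ncol(lab))
      pick <- lab[sr, sc]
  }
  if (is.na(pick) || pick == 0) {
    tab <- tabulate(lab[lab > 0])
    pick <- which.max(tab)
  }
  comp <- lab == pick
  comp <- EBImage::fillHull(comp) > 0
  mask <- matrix(FALSE, nrow(frame), ncol(frame))
  mask[r0:r1, c0:c1] <- comp
  mask
}

#' Segment the lumen on every frame of a magnitude series
#'
#' Bright-blood lumen segmentation of the magnitude stack, frame by frame:
#' Otsu threshold inside the region of interest, keep the connected component
#' containing the seed point (largest component if no seed is given), fill
#' interior holes. Re-segmenting each frame independently is what yields the
#' cross-sectional area waveform A(t) over the cycle.
#'
#' @param series a [velocity_encoded_series()].
#' @param roi_box pixel rectangle \code{c(r0, c0, r1, c1)} (1-based,
#'   inclusive) restricting the search; defaults to the full grid.
#' @param seed_point optional \code{c(row, col)} pixel known to lie inside
#'   the lumen.
#' @param masks optional externally drawn logical mask stack; when supplied
#'   the segmentation is bypassed and the masks are returned with
#'   \code{source = "provided"}.
#' @return A [lumen_mask_series()].
#' @export
segment_lumen <- function(series, roi_box = NULL, seed_point = NULL,
                          masks = NULL) {
  stopifnot(inherits(series, "velocity_encoded_series"))
  pa <- pixel_area_cm2(series$pixel_spacing)
  if (!is.null(masks))
    return(lumen_mask_series(masks, pa, source = "provided"))
  d <- dim(series$magnitude)
  if (is.null(roi_box)) roi_box <- c(1L, 1L, d[1], d[2])
  roi_box <- as.integer(roi_box)
  if (roi_box[1] < 1 || roi_box[2] < 1 || roi_box[3] > d[1] ||
      roi_box[4] > d[2] || roi_box[1] > roi_box[3] || roi_box[2] > roi_box[4])
    stop_invalid_spec("roi_box must be c(r0, c0, r1, c1) inside the grid")
  out <- array(FALSE, d)
  for (f in seq_len(d[3]))
    out[, , f] <- segment_frame(series$magnitude[, , f], roi_box, seed_point, f)
  lumen_mask_series(out, pa, source = "auto")
}

#' Cross-sectional area waveform from lumen masks
#'
#' \eqn{A(t) =} pixel count \eqn{\times} pixel area per frame. An optional
#' circular 3-frame moving average can suppress single-frame segmentation
#' jitter; it slightly damps the systolic/diastolic extrema, so it is off by
#' default.
#'
#' @param masks a [lumen_mask_series()].
#' @param smooth apply the 3-frame circular moving average.
#' @return Numeric vector of per-frame areas in cm^2.
#' @export
area_waveform <- function(masks, smooth = FALSE) {
  stopifnot(inherits(masks, "lumen_mask_series"))
  a <- apply(masks$masks, 3, sum) * masks$pixel_area
  if (smooth && length(a) >= 3) {
    n <- length(a)
    a <- (a[c(n, 1:(n - 1))] + a + a[c(2:n, 1)]) / 3
  }
  a
}
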