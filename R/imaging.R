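# Calcium-image quantification: delta-F/F activity maps and best-fit-ellipse
# shape descriptors.
#
# Recordings hold 5 s of pre-stimulus and 5 s of during-stimulus frames at
# 10 frames/s. The baseline image is the mean of frames 2-3 s after
# recording onset and the stimulation image the mean of frames 2-3 s after
# stimulus onset; delta-F/F = (stim - baseline) / baseline, thresholded at
# 0.15 to reject fluorescence noise.

#' Compute a delta-F/F activity map from a recording
#'
#' Baseline and stimulation images are means over the 2-3 s windows after
#' recording and stimulus onset respectively (frame indices `[20, 30)` of
#' each epoch at 10 frames/s). Pixels whose baseline is not strictly
#' positive are masked out; their count is reported via a warning.
#'
#' @param rec A `fluorescence_recording` (see [render_recording()] /
#'   [read_recording()]), or a list with `baseline_img` and `stim_img`
#'   matrices (the pre-averaged fast path).
#' @param threshold Activity threshold on delta-F/F (default 0.15).
#' @return An `activity_map`: list with `dff`, `active_mask`, `threshold`,
#'   `pixel_size_um`, `n_bad_baseline`.
#' @export
compute_activity_map <- function(rec, threshold = 0.15) {
  if (!is.null(rec$frames)) {
    fr <- rec$frame_rate_hz
    pre <- rec$pre_stim_duration_s * fr
    win <- function(start_frame) (start_frame + 2 * fr + 1):(start_frame + 3 * fr)
    stopifnot(dim(rec$frames)[3] >= pre + 3 * fr)
    baseline <- apply(rec$frames[, , win(0), drop = FALSE], c(1, 2), mean)
    stim_img <- apply(rec$frames[, , win(pre), drop = FALSE], c(1, 2), mean)
  } else {
    baseline <- rec$baseline_img
    stim_img <- rec$stim_img
  }
  bad <- !(baseline > 0)
  n_bad <- sum(bad)
  if (n_bad > 0) {
    warning(sprintf("%d pixels with non-positive baseline masked out", n_bad))
    baseline[bad] <- NA_real_
  }
  dff <- (stim_img - baseline) / baseline
  mask <- !is.na(dff) & dff > threshold
  structure(list(dff = dff, active_mask = mask, threshold = threshold,
                 pixel_size_um = rec$pixel_size_um,
                 n_bad_baseline = n_bad),
            class = "activity_map")
}

#' Fit the equivalent ellipse to the active pixel set
#'
#' Second-central-moment (equivalent-ellipse) fit over all active pixels,
#' treated as one point set. Semi-axes are `2 * sqrt(eigenvalue)` of the
#' pixel covariance (with the 1/12 single-pixel spread added so degenerate
#' masks stay finite); activation area is `pi * semi_major * semi_minor *
#' pixel_size^2` and eccentricity `sqrt(1 - (minor/major)^2)`, i.e. the
#' focal distance over the major-axis length (0 = circle, 1 = line
#' segment). An empty mask yields area 0 and eccentricity 0 as sentinels;
#' class assignment keys off `n_active_pixels`, not these values.
#'
#' @param map An `activity_map` (or a logical matrix used as the mask).
#' @param pixel_size_um Pixel size in um/pixel; defaults to the map's.
#' @return A `response_shape`: list with `area_um2`, `eccentricity`,
#'   `ellipse` (center, semi-axes in px, orientation in degrees),
#'   `n_active_pixels`, `pixel_size_um`, and `area_normalized` (NA until a
#'   region maximum is known).
#' @export
fit_response_shape <- function(map, pixel_size_um = NULL) {
  if (is.matrix(map) && is.logical(map)) {
    mask <- map
    if (is.null(pixel_size_um)) pixel_size_um <- 1
  } else {
    mask <- map$active_mask
    if (is.null(pixel_size_um)) pixel_size_um <- map$pixel_size_um
  }
  pts <- which(mask, arr.ind = TRUE)
  n <- nrow(pts)
  if (n == 0) {
    return(structure(list(
      area_um2 = 0, area_normalized = NA_real_, eccentricity = 0,
      ellipse = list(center_px = c(NA_real_, NA_real_),
                     semi_major_px = 0, semi_minor_px = 0,
                     orientation_deg = 0),
      n_active_pixels = 0L, pixel_size_um = pixel_size_um),
      class = "response_shape"))
  }
  ctr <- colMeans(pts)
  d <- sweep(pts, 2, ctr)
  # population covariance + 1/12 pixel spread (a pixel is a unit square)
  cxx <- sum(d[, 1]^2) / n + 1 / 12
  cyy <- sum(d[, 2]^2) / n + 1 / 12
  cxy <- sum(d[, 1] * d[, 2]) / n
  tr <- cxx + cyy
  det_ <- cxx * cyy - cxy^2
  disc <- sqrt(max(0, (tr / 2)^2 - det_))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, 0)
  semi_major <- 2 * sqrt(l1)
  semi_minor <- 2 * sqrt(l2)
  ecc <- if (semi_major <= 0) 0 else
    sqrt(max(0, 1 - (semi_minor / semi_major)^2))
  # principal-axis angle; pts columns are (row, col) = (y, x)
  ang <- 0.5 * atan2(2 * cxy, cxx - cyy) * 180 / pi
  structure(list(
    area_um2 = pi * semi_major * semi_minor * pixel_size_um^2,
    area_normalized = NA_real_,
    eccentricity = ecc,
    ellipse = list(center_px = unname(ctr), semi_major_px = semi_major,
                   semi_minor_px = semi_minor, orientation_deg = ang),
    n_active_pixels = as.integer(n), pixel_size_um = pixel_size_um),
    class = "response_shape")
}

#' @export
print.response_shape <- function(x, ...) {
  cat(sprintf("<response_shape> area %.0f um^2, eccentricity %.3f, %d active px\n",
              x$area_um2, x$eccentricity, x$n_active_pixels))
  invisible(x)
}

#' Write / read a delta-F/F map as TIFF plus JSON sidecar
#'
#' Values are affinely mapped to 16-bit; the offset/scale, threshold and
#' pixel size go to a `.json` sidecar so the map round-trips.
#'
#' @param map An `activity_map`.
#' @param path Path to the `.tif` file (sidecar at `<path>.json`).
#' @export
write_activity_map <- function(map, path) {
  dff <- map$dff
  dff[is.na(dff)] <- 0
  lo <- min(dff); hi <- max(dff)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((dff - lo) / scale, path, bits.per.sample = 16)
  jsonlite::write_json(list(offset = lo, scale = scale,
                            threshold = map$threshold,
                            pixel_size_um = map$pixel_size_um,
                            n_bad_baseline = map$n_bad_baseline),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_activity_map
#' @export
read_activity_map <- function(path) {
  img <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dff <- img * meta$scale + meta$offset
  structure(list(dff = dff, active_mask = dff > meta$threshold,
                 threshold = meta$threshold,
                 pixel_size_um = meta$pixel_size_um,
                 n_bad_baseline = meta$n_bad_baseline),
            class = "activity_map")
}

#' Draw a solid ellipse mask (test/oracle helper)
#'
#' @param side Image side in pixels.
#' @param center Ellipse center `(row, col)` in pixels.
#' @param semi_axes `(semi_major, semi_minor)` in pixels.
#' @param orientation_deg Major-axis angle in degrees.
#' @return Logical matrix.
#' @export
draw_ellipse_mask <- function(side, center = c(side, side) / 2,
                              semi_axes = c(side / 4, side / 8),
                              orientation_deg = 0) {
  yy <- matrix(seq_len(side), side, side)
  xx <- t(yy)
  th <- orientation_deg * pi / 180
  u <- (yy - center[1]) * cos(th) + (xx - center[2]) * sin(th)
  v <- -(yy - center[1]) * sin(th) + (xx - center[2]) * cos(th)
  (u / semi_axes[1])^2 + (v / semi_axes[2])^2 <= 1
}
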