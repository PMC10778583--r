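#' Select the frame used for morphometry
#'
#' Morphology is measured on a single frame — by default the first frame
#' of the sequence, before photobleaching has degraded the signal.
#'
#' @param movie A [calibrated_movie()].
#' @param config A [pipeline_config()] (`morphology_frame_index`).
#' @return The selected frame (numeric matrix).
#' @export
select_morphology_frame <- function(movie, config) {
  idx <- config$morphology_frame_index
  if (idx < 1 || idx > n_frames(movie))
    stop(sprintf("morphology frame index %d out of range (movie has %d frame(s))",
                 idx, n_frames(movie)))
  movie$frames[[idx]]
}

#' Segment a frame into foreground mask
#'
#' Foreground is every pixel with intensity greater than or equal to the
#' threshold.  The threshold is computed by Otsu's method (default) or
#' supplied as a fixed value; a constant frame has no Otsu threshold and
#' asks for a fixed one instead.
#'
#' @param frame Numeric matrix.
#' @param threshold_method `"otsu"` or a single numeric threshold.
#' @return Logical matrix of the same shape.
#' @export
segment <- function(frame, threshold_method = "otsu") {
  if (is.numeric(threshold_method)) {
    thr <- threshold_method
  } else {
    rng <- range(frame)
    if (diff(rng) == 0)
      stop("frame is constant; Otsu's method is undefined - supply a fixed threshold")
    thr <- EBImage::otsu(frame, range = rng, levels = 256L)
  }
  frame >= thr
}

#' Extract gated particles from a binary mask
#'
#' Connected components are found with 8-connectivity (diagonally
#' touching pixels belong to one particle).  Component area is
#' `pixel count x pixel_size^2`; components strictly below
#' `min_particle_area` or strictly above `max_particle_area` are excluded
#' (the gate endpoints themselves are kept).  Survivors get a Feret
#' diameter, an aspect ratio and a centroid, and are ordered by
#' (centroid y, centroid x).
#'
#' @param mask Logical matrix from [segment()].
#' @param calibration A [calibration()].
#' @param config A [pipeline_config()] (area gate).
#' @return Data frame with columns `particle_id`, `area_um2`, `feret_um`,
#'   `aspect_ratio`, `centroid_x_um`, `centroid_y_um`; attributes
#'   `n_total_components` and `n_excluded` record the gate bookkeeping.
#' @export
extract_particles <- function(mask, calibration, config) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  lab <- label_components_cpp(mask != 0)
  ncomp <- max(lab)
  if (ncomp == 0) {
    out <- empty_particles_table()
    attr(out, "n_total_components") <- 0L
    attr(out, "n_excluded") <- 0L
    return(out)
  }
  px2 <- calibration$pixel_size^2
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  comps <- split.data.frame(idx, labs)
  areas <- vapply(comps, nrow, integer(1)) * px2
  keep <- areas >= config$min_particle_area & areas <= config$max_particle_area
  kept <- comps[keep]
  if (length(kept) == 0) {
    out <- empty_particles_table()
  } else {
    rows <- lapply(kept, function(co) {
      xs <- co[, 2] - 1   # 0-based pixel centre coordinates
      ys <- co[, 1] - 1
      data.frame(area_um2 = nrow(co) * px2,
                 feret_um = feret_diameter(cbind(xs, ys), calibration),
                 aspect_ratio = aspect_ratio(cbind(xs, ys)),
                 centroid_x_um = mean(xs) * calibration$pixel_size,
                 centroid_y_um = mean(ys) * calibration$pixel_size)
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$centroid_y_um, out$centroid_x_um), , drop = FALSE]
    out <- cbind(particle_id = seq_len(nrow(out)), out)
    rownames(out) <- NULL
  }
  attr(out, "n_total_components") <- ncomp
  attr(out, "n_excluded") <- ncomp - sum(keep)
  out
}

#' Feret (maximum caliper) diameter of a pixel component
#'
#' The maximum pairwise Euclidean distance over the component's pixel
#' *corner* points (each pixel contributes its four corners at
#' `centre +/- 0.5`), computed on the convex hull.  Using corners rather
#' than centres matches the caliper definition and gives a single pixel a
#' Feret diameter of one pixel diagonal rather than zero.
#'
#' @param pixels Two-column matrix of 0-based pixel centre coordinates
#'   (x, y) in pixel units.
#' @param calibration A [calibration()].
#' @return Feret diameter in um.
#' @export
feret_diameter <- function(pixels, calibration) {
  stopifnot(nrow(pixels) >= 1)
  corners <- rbind(cbind(pixels[, 1] - 0.5, pixels[, 2] - 0.5),
                   cbind(pixels[, 1] + 0.5, pixels[, 2] - 0.5),
                   cbind(pixels[, 1] - 0.5, pixels[, 2] + 0.5),
                   cbind(pixels[, 1] + 0.5, pixels[, 2] + 0.5))
  corners <- unique(corners)
  hull <- corners[grDevices::chull(corners[, 1], corners[, 2]), , drop = FALSE]
  d2 <- outer(hull[, 1], hull[, 1], "-")^2 + outer(hull[, 2], hull[, 2], "-")^2
  sqrt(max(d2)) * calibration$pixel_size
}

#' Aspect ratio of a pixel component
#'
#' Ratio of major to minor axis of the best-fit ellipse from the
#' second-order central moments of the (unweighted) pixel centres.  Each
#' pixel contributes the variance of a unit square (1/12 per axis), which
#' regularizes degenerate components: a one-pixel-wide line gets a large
#' but finite ratio, a single pixel gets exactly 1.
#'
#' @param pixels Two-column matrix of pixel centre coordinates (x, y).
#' @return Aspect ratio (dimensionless, >= 1).
#' @export
aspect_ratio <- function(pixels) {
  stopifnot(nrow(pixels) >= 1)
  x <- pixels[, 1]; y <- pixels[, 2]
  n <- length(x)
  vxx <- sum((x - mean(x))^2) / n + 1 / 12
  vyy <- sum((y - mean(y))^2) / n + 1 / 12
  vxy <- sum((x - mean(x)) * (y - mean(y))) / n
  tr <- vxx + vyy
  det <- vxx * vyy - vxy^2
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  sqrt(l1 / l2)
}

#' First-frame morphometry of a movie
#'
#' Convenience wrapper: selects the morphology frame, segments it and
#' extracts gated particles.
#'
#' @param movie A [calibrated_movie()].
#' @param config A [pipeline_config()].
#' @return Particle table as from [extract_particles()].
#' @export
measure_morphology <- function(movie, config) {
  frame <- select_morphology_frame(movie, config)
  mask <- segment(frame, config$threshold_method)
  extract_particles(mask, movie$calibration, config)
}
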