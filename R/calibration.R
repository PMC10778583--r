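#' Spatial and temporal calibration of a movie
#'
#' A calibration couples the pixel raster to physical units: `pixel_size`
#' converts pixels to micrometres and `frame_interval` converts frame steps
#' to seconds.  All conversions in the package are exact multiplications by
#' these two factors; nothing is ever guessed from image content.
#'
#' @param pixel_size Pixel edge length in micrometres per pixel (> 0).
#' @param frame_interval Time between consecutive frames in seconds (> 0).
#'
#' @return An object of class `"calibration"` with elements `pixel_size`
#'   and `frame_interval`.
#' @examples
#' cal <- calibration(pixel_size = 0.2, frame_interval = 4)
#' px_to_um(10, cal)   # 2 micrometres
#' @export
calibration <- function(pixel_size, frame_interval) {
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1L,
            is.finite(pixel_size), pixel_size > 0,
            is.numeric(frame_interval), length(frame_interval) == 1L,
            is.finite(frame_interval), frame_interval > 0)
  structure(list(pixel_size = as.numeric(pixel_size),
                 frame_interval = as.numeric(frame_interval)),
            class = "calibration")
}

#' @rdname calibration
#' @param px,um,frames Quantities to convert.
#' @param cal A `calibration` object.
#' @export
px_to_um <- function(px, cal) px * cal$pixel_size

#' @rdname calibration
#' @export
um_to_px <- function(um, cal) um / cal$pixel_size

#' @rdname calibration
#' @export
frames_to_s <- function(frames, cal) frames * cal$frame_interval

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("calibration: %g um/px, %g s/frame\n",
              x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Calibrated time-lapse movie
#'
#' Container for an ordered sequence of single-channel 2-D frames plus
#' their calibration.  Frames are numeric matrices indexed `[row, column]`;
#' the pixel at matrix position `[i, j]` has its centre at physical
#' coordinates `x = (j - 1) * pixel_size`, `y = (i - 1) * pixel_size`
#' micrometres, i.e. the origin is the centre of the top-left pixel of the
#' field and `x` runs along columns, `y` along rows.
#'
#' A single-frame movie is valid: morphology can be measured on it, but
#' motility analysis needs at least two frames.
#'
#' @param frames A list of numeric matrices, all of identical dimensions.
#' @param calibration A [calibration()] object.
#' @param name Identifier used in logs and output tables.
#'
#' @return An object of class `"calibrated_movie"`.
#' @export
calibrated_movie <- function(frames, calibration, name = "movie") {
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(is.list(frames), length(frames) >= 1L,
            inherits(calibration, "calibration"))
  dims <- vapply(frames, dim, integer(2))
  if (!all(dims[1, ] == dims[1, 1]) || !all(dims[2, ] == dims[2, 1]))
    stop("all frames must share identical width and height")
  frames <- lapply(frames, function(f) {
    storage.mode(f) <- "double"
    f
  })
  structure(list(frames = frames, calibration = calibration,
                 name = as.character(name)),
            class = "calibrated_movie")
}

#' @export
print.calibrated_movie <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("calibrated_movie '%s': %d frame(s) of %d x %d px (%g um/px, %g s/frame)\n",
              x$name, length(x$frames), d[2], d[1],
              x$calibration$pixel_size, x$calibration$frame_interval))
  invisible(x)
}

#' @export
length.calibrated_movie <- function(x) length(x$frames)

n_frames <- function(movie) length(movie$frames)

frame_dim <- function(movie) dim(movie$frames[[1]])
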