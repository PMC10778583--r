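#' Scale-normalized Laplacian-of-Gaussian blob response
#'
#' Computes the negated, scale-normalized LoG response of one frame at the
#' Gaussian scale matched to the nominal blob diameter,
#' `sigma = (blob_diameter / 2) / sqrt(2)` (converted to pixels), so that
#' bright, roughly round blobs of the nominal size produce positive local
#' maxima.  The response is multiplied by `sigma^2` (scale normalization)
#' and the discrete kernel has zero mean, so a constant image yields an
#' identically zero response.  Filtering uses reflective boundary padding.
#'
#' @param frame Numeric matrix of pixel intensities.
#' @param blob_diameter Nominal blob diameter in um.
#' @param calibration A [calibration()]; the diameter must map to at least
#'   2 pixels.
#' @return Numeric matrix of the same size as `frame`.
#' @export
log_response <- function(frame, blob_diameter, calibration) {
  stopifnot(is.matrix(frame), blob_diameter > 0)
  diameter_px <- blob_diameter / calibration$pixel_size
  if (diameter_px < 2)
    stop(sprintf("blob diameter of %.3g um is only %.2f px at %g um/px; at least 2 px needed",
                 blob_diameter, diameter_px, calibration$pixel_size))
  sigma <- (diameter_px / 2) / sqrt(2)
  k <- log_kernel(sigma)
  conv2_reflect(frame, k)
}

# Negated scale-normalized LoG kernel with zero mean; half-width 4*sigma.
log_kernel <- function(sigma) {
  h <- max(2L, as.integer(ceiling(4 * sigma)))
  g <- seq(-h, h)
  xx <- matrix(g, 2 * h + 1, 2 * h + 1, byrow = TRUE)
  yy <- t(xx)
  r2 <- xx^2 + yy^2
  gauss <- exp(-r2 / (2 * sigma^2)) / (2 * pi * sigma^2)
  k <- -sigma^2 * ((r2 - 2 * sigma^2) / sigma^4) * gauss
  k - mean(k)
}

# 2-D convolution with reflective (symmetric) boundary padding, via FFT.
conv2_reflect <- function(img, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  p <- pad_reflect(img, kr, kc)
  pr <- nrow(p); pc <- ncol(p)
  kp <- matrix(0, pr, pc)
  kp[seq_len(nrow(kernel)), seq_len(ncol(kernel))] <- kernel
  # center the kernel at (1,1) with circular wrap so no phase shift remains
  kp <- kp[wrap_index(seq_len(pr) - 1 + kr, pr) + 1,
           wrap_index(seq_len(pc) - 1 + kc, pc) + 1]
  res <- Re(stats::fft(stats::fft(p) * stats::fft(kp), inverse = TRUE)) / (pr * pc)
  res[(kr + 1):(kr + nrow(img)), (kc + 1):(kc + ncol(img)), drop = FALSE]
}

pad_reflect <- function(img, kr, kc) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- c(rev(seq_len(min(kr, nr))), seq_len(nr),
          nr + 1 - seq_len(min(kr, nr)))
  ci <- c(rev(seq_len(min(kc, nc))), seq_len(nc),
          nc + 1 - seq_len(min(kc, nc)))
  img[ri, ci, drop = FALSE]
}

#' Detect spots in one frame
#'
#' Spots are strict local maxima (8-neighborhood) of the LoG response of
#' [log_response()] whose response value (the spot *quality*) reaches
#' `config$quality_threshold`.  Maxima closer to a stronger maximum than
#' one blob radius are suppressed; ties are broken deterministically in
#' favor of the smaller (y, x) pixel position.  The retained maxima are
#' refined to sub-pixel precision by a separable quadratic fit of the 3x3
#' response neighborhood, and exported in micrometres.  Maxima whose 3x3
#' neighborhood leaves the image are discarded.
#'
#' @param frame Numeric matrix of pixel intensities.
#' @param config A [pipeline_config()] (uses `blob_diameter` and
#'   `quality_threshold`).
#' @param calibration A [calibration()].
#' @param frame_index 1-based frame ordinal recorded in the output.
#' @return Data frame with columns `frame`, `x_um`, `y_um`, `quality`,
#'   ordered by descending quality.
#' @export
detect_spots <- function(frame, config, calibration, frame_index = 1L) {
  resp <- log_response(frame, config$blob_diameter, calibration)
  nr <- nrow(resp); nc <- ncol(resp)
  if (nr < 3 || nc < 3) return(empty_spots_table())
  ci <- 2:(nr - 1); cj <- 2:(nc - 1)
  center <- resp[ci, cj, drop = FALSE]
  ismax <- center > resp[ci - 1, cj - 1] & center > resp[ci - 1, cj] &
           center > resp[ci - 1, cj + 1] & center > resp[ci, cj - 1] &
           center > resp[ci, cj + 1] & center > resp[ci + 1, cj - 1] &
           center > resp[ci + 1, cj] & center > resp[ci + 1, cj + 1] &
           center >= config$quality_threshold
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty_spots_table())
  py <- idx[, 1] + 1L   # 1-based row in resp
  px <- idx[, 2] + 1L
  q <- resp[cbind(py, px)]

  # radius suppression, strongest first; (y, x) lexicographic tie-break
  ord <- order(-q, py, px)
  py <- py[ord]; px <- px[ord]; q <- q[ord]
  radius_px <- (config$blob_diameter / 2) / calibration$pixel_size
  keep <- logical(length(q))
  for (s in seq_along(q)) {
    if (s == 1) { keep[1] <- TRUE; next }
    kept <- which(keep[seq_len(s - 1)])
    d2 <- (py[kept] - py[s])^2 + (px[kept] - px[s])^2
    keep[s] <- all(d2 > radius_px^2)
  }
  py <- py[keep]; px <- px[keep]; q <- q[keep]

  # sub-pixel refinement, separable parabola on the 3x3 neighborhood
  off_x <- off_y <- numeric(length(q))
  for (s in seq_along(q)) {
    off_x[s] <- parabolic_offset(resp[py[s], px[s] - 1], resp[py[s], px[s]],
                                 resp[py[s], px[s] + 1])
    off_y[s] <- parabolic_offset(resp[py[s] - 1, px[s]], resp[py[s], px[s]],
                                 resp[py[s] + 1, px[s]])
  }
  out <- data.frame(frame = as.integer(frame_index),
                    x_um = ((px - 1) + off_x) * calibration$pixel_size,
                    y_um = ((py - 1) + off_y) * calibration$pixel_size,
                    quality = q)
  rownames(out) <- NULL
  out
}

#' Detect spots in every frame of a movie
#'
#' @param movie A [calibrated_movie()].
#' @param config A [pipeline_config()].
#' @return List with one spot data frame per frame (see [detect_spots()]).
#' @export
detect_movie <- function(movie, config) {
  lapply(seq_len(n_frames(movie)), function(t) {
    detect_spots(movie$frames[[t]], config, movie$calibration, t)
  })
}
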