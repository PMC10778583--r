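#' Pipeline configuration
#'
#' Bundles every tunable threshold of the motility/morphology pipeline.
#' The defaults are the settings used for 40x spinning-disk imaging of
#' neuronal mitochondria: spots are detected as bright blobs of nominal
#' diameter 1.5 um, linked frame-to-frame within 2 um with gap closing
#' disabled, a track counts as motile when its start-to-end displacement
#' exceeds 1.5 um, and first-frame morphometry keeps particles between
#' 0.2 and 5 um^2 (bounds inclusive; strictly smaller or larger particles
#' are excluded).
#'
#' @param blob_diameter Nominal blob diameter in um (> 0). Default 1.5.
#' @param quality_threshold Minimum detector response (quality) a spot must
#'   reach to be retained.  Quality is the scale-normalized
#'   Laplacian-of-Gaussian response at the maximum, so its absolute scale
#'   depends on image bit depth and illumination; default 1.0.
#' @param max_link_distance Maximum frame-to-frame linking distance in um.
#'   Default 2.0.
#' @param gap_closing Logical; re-linking across missed frames.  Fixed
#'   `FALSE` in this release: a detection gap always terminates a track.
#' @param min_track_displacement Displacement (um) a track must strictly
#'   exceed to count as motile.  Default 1.5.
#' @param min_particle_area,max_particle_area Area gate in um^2 applied to
#'   first-frame particles, endpoints inclusive.  Defaults 0.2 and 5.
#' @param morphology_frame_index 1-based index of the frame used for
#'   morphometry.  Default 1 (the first frame).
#' @param threshold_method Either `"otsu"` (default) or a single numeric
#'   fixed threshold for segmentation.
#' @param speed_on_motile_only Logical; if `TRUE`, per-ROI speed and
#'   displacement summaries are computed over motile tracks only (default),
#'   if `FALSE` over all tracks.
#' @param motile_denominator `"particles"` (default) or `"tracks"`:
#'   denominator of the motile fraction.
#'
#' @return An object of class `"pipeline_config"` (a named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$max_link_distance
#' @export
pipeline_config <- function(blob_diameter = 1.5,
                            quality_threshold = 1.0,
                            max_link_distance = 2.0,
                            gap_closing = FALSE,
                            min_track_displacement = 1.5,
                            min_particle_area = 0.2,
                            max_particle_area = 5.0,
                            morphology_frame_index = 1L,
                            threshold_method = "otsu",
                            speed_on_motile_only = TRUE,
                            motile_denominator = c("particles", "tracks")) {
  stopifnot(blob_diameter > 0, max_link_distance > 0,
            min_track_displacement > 0,
            min_particle_area > 0, max_particle_area > 0,
            min_particle_area < max_particle_area,
            morphology_frame_index >= 1)
  if (isTRUE(gap_closing))
    stop("gap closing is not supported: a missed detection always ends a track")
  if (is.character(threshold_method)) {
    threshold_method <- match.arg(threshold_method, "otsu")
  } else {
    stopifnot(is.numeric(threshold_method), length(threshold_method) == 1L,
              is.finite(threshold_method))
  }
  motile_denominator <- match.arg(motile_denominator)
  structure(list(blob_diameter = blob_diameter,
                 quality_threshold = quality_threshold,
                 max_link_distance = max_link_distance,
                 gap_closing = FALSE,
                 min_track_displacement = min_track_displacement,
                 min_particle_area = min_particle_area,
                 max_particle_area = max_particle_area,
                 morphology_frame_index = as.integer(morphology_frame_index),
                 threshold_method = threshold_method,
                 speed_on_motile_only = isTRUE(speed_on_motile_only),
                 motile_denominator = motile_denominator),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
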