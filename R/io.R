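#' Read a calibrated movie from a multi-page TIFF
#'
#' Reads a single-channel grayscale TIFF stack in acquisition order.
#' Calibration is resolved with the precedence: explicit arguments >
#' TIFF resolution tags > a JSON calibration sidecar written by
#' [write_movie()].  If a required calibration value is available from
#' none of these sources, reading fails; calibration is never guessed.
#'
#' Integer TIFF data are returned as raw integer counts (no rescaling to
#' `[0, 1]`); intensities are only ever used comparatively downstream.
#'
#' @param path Path to a multi-page grayscale TIFF.
#' @param pixel_size Optional pixel size in um/px; overrides file metadata.
#' @param frame_interval Optional frame interval in seconds; overrides file
#'   metadata.
#' @param name Movie identifier; defaults to the file name without extension.
#'
#' @return A [calibrated_movie()].
#' @seealso [write_movie()]
#' @export
read_movie <- function(path, pixel_size = NULL, frame_interval = NULL,
                       name = NULL) {
  if (!file.exists(path)) stop("movie file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop("multi-channel or RGB TIFF not supported; expected single-channel grayscale frames")

  side <- read_calibration_sidecar(path)
  if (is.null(pixel_size)) {
    xres <- attr(pages[[1]], "x.resolution")
    if (!is.null(xres) && is.finite(xres) && xres > 0) {
      # resolution tags are stored as pixels per micrometre
      pixel_size <- 1 / xres
    } else if (!is.null(side$pixel_size_um)) {
      pixel_size <- side$pixel_size_um
    }
  }
  if (is.null(frame_interval)) {
    if (!is.null(side$frame_interval_s)) frame_interval <- side$frame_interval_s
  }
  if (is.null(pixel_size))
    stop("no pixel size: not in TIFF metadata or sidecar and not supplied as an argument")
  if (is.null(frame_interval))
    stop("no frame interval: not in sidecar and not supplied as an argument")

  frames <- lapply(pages, function(p) {
    attributes(p) <- list(dim = dim(p))
    p
  })
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  calibrated_movie(frames, calibration(pixel_size, frame_interval), name = name)
}

#' Write a calibrated movie as a multi-page TIFF
#'
#' Frames are stored as 16-bit grayscale (values are rounded and clipped to
#' `[0, 65535]`).  Calibration travels in a JSON sidecar
#' (`<path>.calibration.json`) because baseline TIFF has no frame-interval
#' tag; [read_movie()] picks the sidecar up automatically.
#'
#' @param movie A [calibrated_movie()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "calibrated_movie"))
  pages <- lapply(movie$frames, function(f) {
    pmin(pmax(round(f), 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(pixel_size_um = movie$calibration$pixel_size,
         frame_interval_s = movie$calibration$frame_interval,
         name = movie$name),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".calibration.json")

read_calibration_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(list())
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write the tabular outputs of a pipeline run
#'
#' Writes four CSV files into `out_dir`: `spots.csv` (frame, x_um, y_um,
#' quality), `tracks.csv` (track_id, n_spots, first_frame, last_frame,
#' displacement_um, mean_speed_um_per_s, motile), `morphology.csv`
#' (particle_id, area_um2, feret_um, aspect_ratio, centroid_x_um,
#' centroid_y_um) and `roi_summary.csv`.  Lengths are micrometres, areas
#' um^2, speeds um/s.  Spots are sorted by (frame, y, x); rows of the
#' other tables keep their deterministic upstream order.  Missing
#' aggregates are written as empty cells, never as 0.
#'
#' @param spots,tracks,particles,summaries Data frames as produced by the
#'   detection, tracking, morphology and metrics stages (possibly empty).
#' @param out_dir Output directory; created if needed.
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_tables <- function(spots, tracks, particles, summaries, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  spots <- as.data.frame(spots)
  if (nrow(spots) > 0)
    spots <- spots[order(spots$frame, spots$y_um, spots$x_um), , drop = FALSE]
  paths <- c(spots = file.path(out_dir, "spots.csv"),
             tracks = file.path(out_dir, "tracks.csv"),
             morphology = file.path(out_dir, "morphology.csv"),
             roi_summary = file.path(out_dir, "roi_summary.csv"))
  write_csv_plain(spots, paths[["spots"]])
  write_csv_plain(as.data.frame(tracks), paths[["tracks"]])
  write_csv_plain(as.data.frame(particles), paths[["morphology"]])
  write_csv_plain(as.data.frame(summaries), paths[["roi_summary"]])
  invisible(paths)
}

# RFC 4180, '.' decimal separator, NA -> empty cell, no row names;
# format numbers with full precision so reruns are byte-identical.
write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a reproducibility manifest for one pipeline run
#'
#' Captures the full configuration, package version, input file (with MD5
#' hash when it exists on disk) and calibration, so a run can be audited
#' and reproduced exactly.
#'
#' @param config A [pipeline_config()].
#' @param movie The analysed [calibrated_movie()].
#' @param path Output JSON path.
#' @param input_path Optional path of the source TIFF (hashed if readable).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(config, movie, path, input_path = NULL) {
  manifest <- list(
    package = "mitomotion",
    version = as.character(utils::packageVersion("mitomotion")),
    movie = list(name = movie$name,
                 n_frames = n_frames(movie),
                 height_px = frame_dim(movie)[1],
                 width_px = frame_dim(movie)[2],
                 pixel_size_um = movie$calibration$pixel_size,
                 frame_interval_s = movie$calibration$frame_interval),
    config = unclass(config))
  if (!is.null(input_path) && file.exists(input_path)) {
    manifest$input <- list(path = input_path,
                           md5 = unname(tools::md5sum(input_path)))
  }
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

empty_spots_table <- function() {
  data.frame(frame = integer(), x_um = numeric(), y_um = numeric(),
             quality = numeric())
}

empty_tracks_table <- function() {
  data.frame(track_id = integer(), n_spots = integer(),
             first_frame = integer(), last_frame = integer(),
             displacement_um = numeric(), mean_speed_um_per_s = numeric(),
             motile = integer())
}

empty_particles_table <- function() {
  data.frame(particle_id = integer(), area_um2 = numeric(),
             feret_um = numeric(), aspect_ratio = numeric(),
             centroid_x_um = numeric(), centroid_y_um = numeric())
}
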