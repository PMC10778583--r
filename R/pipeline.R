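#' Run the full pipeline on one ROI
#'
#' Executes drift correction, per-frame spot detection, frame-to-frame
#' linking, the motility filter, first-frame morphometry and the ROI
#' summary on a single movie.  A single-frame movie yields morphology
#' only; drift correction and tracking are skipped with a logged notice.
#'
#' @param movie A [calibrated_movie()], or a path to a TIFF readable by
#'   [read_movie()].
#' @param config A [pipeline_config()].
#' @param roi_id ROI identifier.
#' @param condition Treatment-group label.
#' @param out_dir Optional output directory: writes `spots.csv`,
#'   `tracks.csv`, `morphology.csv`, `roi_summary.csv`, `drift.csv` and a
#'   JSON run manifest.
#' @param register Logical; estimate and correct drift first (default).
#' @param pixel_size,frame_interval Calibration overrides forwarded to
#'   [read_movie()] when `movie` is a path.
#' @param verbose Log stage counts via `message()`.
#' @return List with elements `movie` (corrected), `drift`,
#'   `spots_by_frame`, `spots` (pooled table), `tracks`, `tracks_df`,
#'   `particles`, `summary`.
#' @export
run_roi <- function(movie, config = pipeline_config(), roi_id = "roi",
                    condition = "none", out_dir = NULL, register = TRUE,
                    pixel_size = NULL, frame_interval = NULL,
                    verbose = FALSE) {
  input_path <- NULL
  if (is.character(movie)) {
    input_path <- movie
    movie <- tryCatch(
      read_movie(movie, pixel_size = pixel_size, frame_interval = frame_interval),
      error = function(e) stop("ROI '", roi_id, "': ", conditionMessage(e),
                               call. = FALSE))
  }
  stopifnot(inherits(movie, "calibrated_movie"),
            inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf("[%s] ", roi_id), sprintf(...))

  nf <- n_frames(movie)
  if (register && nf >= 2) {
    drift <- estimate_drift(movie)
    movie <- apply_correction(movie, drift)
    say("drift corrected: max |offset| %.2f px",
        max(abs(c(drift$dx_px, drift$dy_px))))
  } else {
    drift <- structure(data.frame(frame = seq_len(nf), dx_px = 0, dy_px = 0),
                       class = c("drift_trace", "data.frame"))
    if (register && nf < 2) say("single frame: drift correction skipped")
  }

  spots_by_frame <- detect_movie(movie, config)
  spots <- do.call(rbind, spots_by_frame)
  if (is.null(spots) || nrow(spots) == 0) spots <- empty_spots_table()
  say("detected %d spots over %d frame(s) (%.1f/frame)",
      nrow(spots), nf, nrow(spots) / nf)

  if (nf >= 2) {
    tracks <- build_tracks(spots_by_frame, config)
  } else {
    say("single frame: tracking skipped, morphology only")
    tracks <- list()
  }
  tracks_df <- tracks_table(tracks, config, movie$calibration)
  say("%d tracks, %d motile (displacement > %g um)",
      nrow(tracks_df), sum(tracks_df$motile), config$min_track_displacement)

  particles <- measure_morphology(movie, config)
  say("%d particles gated in, %d components excluded by the %g-%g um^2 gate",
      nrow(particles), attr(particles, "n_excluded"),
      config$min_particle_area, config$max_particle_area)

  summary <- summarize_roi(tracks_df, particles, config, roi_id, condition)

  if (!is.null(out_dir)) {
    write_tables(spots, tracks_df, particles, summary, out_dir)
    write_drift(drift, file.path(out_dir, "drift.csv"))
    write_run_manifest(config, movie, file.path(out_dir, "run_manifest.json"),
                       input_path = input_path)
  }
  list(movie = movie, drift = drift, spots_by_frame = spots_by_frame,
       spots = spots, tracks = tracks, tracks_df = tracks_df,
       particles = particles, summary = summary)
}

#' Run a batch of ROIs and compare conditions
#'
#' Runs [run_roi()] for every row of a batch manifest, pools the
#' per-track and per-particle tables, and compares the conditions on each
#' metric with the tie-corrected Kruskal-Wallis test followed by Dunn's
#' post hoc test on the preselected pairs.  Displacement and speed enter
#' per track, morphology descriptors per particle (large n), while the
#' motile fraction enters per ROI.
#'
#' @param manifest Data frame with columns `path` (TIFF path), `roi_id`
#'   (unique) and `condition` (non-empty label).
#' @param config A [pipeline_config()].
#' @param pairs List of length-2 character vectors of condition labels for
#'   the preselected comparisons; defaults to every condition against the
#'   first one in the manifest.
#' @param out_dir Optional output directory; per-ROI subdirectories plus
#'   combined `roi_summary.csv` and `stats.csv`.
#' @param skip_failures If `TRUE`, a failing ROI is skipped with a
#'   warning instead of aborting the batch.
#' @param verbose Forwarded to [run_roi()].
#' @return List with `rois` (named list of per-ROI results), `summaries`
#'   (combined ROI table), `comparisons` (list of
#'   [compare_conditions()] results) and `stats` (flat table), the last
#'   two `NULL` when fewer than two conditions are present.
#' @export
run_batch <- function(manifest, config = pipeline_config(), pairs = NULL,
                      out_dir = NULL, skip_failures = FALSE, verbose = FALSE) {
  stopifnot(is.data.frame(manifest),
            all(c("path", "roi_id", "condition") %in% names(manifest)))
  if (anyDuplicated(manifest$roi_id))
    stop("roi_ids must be unique")
  if (any(!nzchar(manifest$condition)) || any(is.na(manifest$condition)))
    stop("conditions must be non-empty strings")
  missing <- !file.exists(manifest$path)
  if (any(missing))
    stop("manifest row(s) reference missing file(s): ",
         paste(sprintf("%s (roi %s)", manifest$path[missing],
                       manifest$roi_id[missing]), collapse = "; "))

  rois <- list()
  for (r in seq_len(nrow(manifest))) {
    roi_id <- as.character(manifest$roi_id[r])
    roi_out <- if (is.null(out_dir)) NULL else file.path(out_dir, roi_id)
    res <- tryCatch(
      run_roi(manifest$path[r], config, roi_id = roi_id,
              condition = as.character(manifest$condition[r]),
              out_dir = roi_out, verbose = verbose),
      error = function(e) e)
    if (inherits(res, "error")) {
      if (skip_failures) {
        warning("ROI '", roi_id, "' skipped: ", conditionMessage(res))
        next
      }
      stop("ROI '", roi_id, "' failed: ", conditionMessage(res))
    }
    rois[[roi_id]] <- res
  }
  if (length(rois) == 0) stop("no ROI completed")

  summaries <- do.call(rbind, lapply(rois, `[[`, "summary"))
  rownames(summaries) <- NULL
  per_track <- do.call(rbind, lapply(rois, function(r) {
    df <- r$tracks_df
    if (nrow(df) == 0) return(NULL)
    cbind(roi_id = r$summary$roi_id, condition = r$summary$condition, df)
  }))
  per_particle <- do.call(rbind, lapply(rois, function(r) {
    df <- r$particles
    if (nrow(df) == 0) return(NULL)
    cbind(roi_id = r$summary$roi_id, condition = r$summary$condition,
          as.data.frame(df))
  }))
  if (!is.null(per_track)) rownames(per_track) <- NULL
  if (!is.null(per_particle)) rownames(per_particle) <- NULL

  conditions <- unique(summaries$condition)
  comparisons <- NULL
  stats <- NULL
  if (length(conditions) >= 2) {
    if (is.null(pairs))
      pairs <- lapply(conditions[-1], function(cc) c(conditions[1], cc))
    obs <- batch_observations(summaries, per_track, per_particle, config)
    comparisons <- lapply(names(obs), function(metric) {
      compare_conditions(obs[[metric]], metric, pairs)
    })
    names(comparisons) <- names(obs)
    stats <- stats_table(comparisons)
  } else {
    message("only one condition present: group statistics skipped")
  }

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_csv_plain(summaries, file.path(out_dir, "roi_summary.csv"))
    if (!is.null(stats))
      write_csv_plain(stats, file.path(out_dir, "stats.csv"))
  }
  list(rois = rois, summaries = summaries, per_track = per_track,
       per_particle = per_particle, comparisons = comparisons, stats = stats)
}

# Long observation tables per metric for group statistics.
batch_observations <- function(summaries, per_track, per_particle, config) {
  obs <- list()
  if (!is.null(per_track) && nrow(per_track) > 0) {
    sel <- if (config$speed_on_motile_only) per_track$motile == 1L
           else rep(TRUE, nrow(per_track))
    tr <- per_track[sel, , drop = FALSE]
    if (nrow(tr) > 0) {
      obs$track_displacement <- data.frame(condition = tr$condition,
                                           value = tr$displacement_um)
      obs$track_speed <- data.frame(condition = tr$condition,
                                    value = tr$mean_speed_um_per_s)
    }
  }
  if (!is.null(per_particle) && nrow(per_particle) > 0) {
    obs$area <- data.frame(condition = per_particle$condition,
                           value = per_particle$area_um2)
    obs$feret <- data.frame(condition = per_particle$condition,
                            value = per_particle$feret_um)
    obs$aspect_ratio <- data.frame(condition = per_particle$condition,
                                   value = per_particle$aspect_ratio)
  }
  obs$motile_fraction <- data.frame(condition = summaries$condition,
                                    value = summaries$motile_fraction)
  obs
}
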