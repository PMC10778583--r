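#' Fraction of motile mitochondria
#'
#' The motility and morphology layers are combined into one per-ROI
#' statistic: the number of motile tracks (displacement above the
#' configured threshold) divided by the number of gated particles
#' segmented in the morphology frame.  A ratio above 1 — possible when a
#' particle yields several track fragments — is clipped to 1 with a
#' warning.  With zero particles the fraction is undefined (`NA`) and the
#' ROI is flagged so it can be excluded from group statistics.
#'
#' @param n_motile_tracks Number of motile tracks (count).
#' @param n_particles Number of gated first-frame particles (count).
#' @return Fraction in `[0, 1]`, or `NA` when `n_particles` is 0.
#' @export
motile_fraction <- function(n_motile_tracks, n_particles) {
  stopifnot(n_motile_tracks >= 0, n_particles >= 0)
  if (n_particles == 0) {
    warning("motile fraction undefined: no particles in the morphology frame")
    return(NA_real_)
  }
  f <- n_motile_tracks / n_particles
  if (f > 1) {
    warning(sprintf("motile fraction %.3f > 1 clipped to 1 (more motile tracks than particles)", f))
    f <- 1
  }
  f
}

#' Summarize one ROI
#'
#' Bundles counts and mean/SD/median aggregates of the per-track and
#' per-particle measures into a single row.  Displacement and speed are
#' aggregated over motile tracks (default) or all tracks depending on
#' `config$speed_on_motile_only`; morphology aggregates run over the
#' gated particles.  Aggregates that are undefined (no observations, or
#' SD of a single observation) are `NA`, never 0.
#'
#' @param tracks_df Per-track table from [tracks_table()].
#' @param particles Particle table from [extract_particles()].
#' @param config A [pipeline_config()].
#' @param roi_id ROI identifier.
#' @param condition Treatment-group label.
#' @return One-row data frame (an ROI summary).
#' @export
summarize_roi <- function(tracks_df, particles, config,
                          roi_id = "roi", condition = "none") {
  n_tracks <- nrow(tracks_df)
  n_motile <- if (n_tracks > 0) sum(tracks_df$motile == 1L) else 0L
  n_particles <- nrow(particles)
  frac <- if (n_particles > 0) {
    if (config$motile_denominator == "particles")
      motile_fraction(n_motile, n_particles)
    else if (n_tracks > 0) n_motile / n_tracks else NA_real_
  } else NA_real_

  sel <- if (config$speed_on_motile_only && n_tracks > 0)
    tracks_df$motile == 1L else rep(TRUE, n_tracks)
  disp <- tracks_df$displacement_um[sel]
  speed <- tracks_df$mean_speed_um_per_s[sel]

  agg <- function(x, f) if (length(x) == 0) NA_real_ else f(x)
  agg_sd <- function(x) if (length(x) < 2) NA_real_ else sd(x)
  data.frame(
    roi_id = roi_id, condition = condition,
    n_particles = n_particles, n_tracks = n_tracks,
    n_motile_tracks = n_motile, motile_fraction = frac,
    mean_displacement_um = agg(disp, mean),
    sd_displacement_um = agg_sd(disp),
    median_displacement_um = agg(disp, median),
    mean_speed_um_per_s = agg(speed, mean),
    sd_speed_um_per_s = agg_sd(speed),
    median_speed_um_per_s = agg(speed, median),
    mean_area_um2 = agg(particles$area_um2, mean),
    sd_area_um2 = agg_sd(particles$area_um2),
    median_area_um2 = agg(particles$area_um2, median),
    mean_feret_um = agg(particles$feret_um, mean),
    sd_feret_um = agg_sd(particles$feret_um),
    median_feret_um = agg(particles$feret_um, median),
    mean_aspect_ratio = agg(particles$aspect_ratio, mean),
    sd_aspect_ratio = agg_sd(particles$aspect_ratio),
    median_aspect_ratio = agg(particles$aspect_ratio, median))
}
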