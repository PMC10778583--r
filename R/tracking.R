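#' Optimally link spots between two consecutive frames
#'
#' One-to-one matching between the spots of frame *t* and frame *t + 1*
#' using only pairs closer than `max_link_distance`.  Among all feasible
#' matchings the one with the largest number of links is chosen, and among
#' those the one minimizing the total squared Euclidean distance; this is
#' solved exactly as a linear assignment problem (no greedy heuristics).
#' Spots may remain unmatched, which starts or ends a track.
#'
#' @param spots_a,spots_b Data frames with columns `x_um`, `y_um`
#'   (all of frame *t* and frame *t + 1* respectively).
#' @param max_link_distance Hard distance cutoff in um.
#' @return Data frame with columns `a`, `b` (row indices into `spots_a`
#'   and `spots_b`) and `dist_um`; zero rows when nothing can be linked.
#' @export
link_frame_pair <- function(spots_a, spots_b, max_link_distance) {
  n <- nrow(spots_a); m <- nrow(spots_b)
  empty <- data.frame(a = integer(), b = integer(), dist_um = numeric())
  if (n == 0 || m == 0) return(empty)
  dx <- outer(spots_a$x_um, spots_b$x_um, "-")
  dy <- outer(spots_a$y_um, spots_b$y_um, "-")
  d2 <- dx^2 + dy^2
  feasible <- d2 <= max_link_distance^2
  if (!any(feasible)) return(empty)
  # square LAP with per-spot "stay unmatched" slots: the penalty P exceeds
  # any possible saving from dropping links, so cardinality dominates cost
  P <- max_link_distance^2 * (min(n, m) + 1)
  BIG <- (n + m) * P * 10 + 1
  N <- n + m
  cost <- matrix(BIG, N, N)
  sub <- matrix(BIG, n, m)
  sub[feasible] <- d2[feasible]
  cost[seq_len(n), seq_len(m)] <- sub
  for (i in seq_len(n)) cost[i, m + i] <- P
  for (j in seq_len(m)) cost[n + j, j] <- P
  cost[(n + 1):N, (m + 1):N] <- 0
  assign <- solve_lap_cpp(cost)
  a <- seq_len(n)
  b <- assign[seq_len(n)]
  keep <- b >= 1 & b <= m
  keep[keep] <- feasible[cbind(a[keep], b[keep])]
  data.frame(a = a[keep], b = b[keep],
             dist_um = sqrt(d2[cbind(a[keep], b[keep])]))
}

#' Build tracks by chaining frame-to-frame links
#'
#' Pairwise optimal matchings ([link_frame_pair()]) are chained over
#' consecutive frames.  A spot left unmatched in the next frame terminates
#' its chain — there is no gap closing, so a particle missed for one frame
#' yields two tracks, never one.  Chains of a single spot are dropped
#' (a lone detection carries no motion information).
#'
#' @param spots_by_frame List of per-frame spot data frames in frame
#'   order (as from [detect_movie()]).
#' @param config A [pipeline_config()] (uses `max_link_distance`).
#' @return List of tracks; each track is a data frame of its spots
#'   (columns `frame`, `x_um`, `y_um`, `quality`) on strictly consecutive
#'   frames.  Tracks are numbered in order of (first frame, y, x) of their
#'   first spot.
#' @export
build_tracks <- function(spots_by_frame, config) {
  nfr <- length(spots_by_frame)
  if (nfr < 2) return(list())
  chains <- list()                 # finished + active chains of (frame, row) pairs
  active <- list()                 # chain index by spot row in current frame
  s1 <- spots_by_frame[[1]]
  if (nrow(s1) > 0) {
    for (r in seq_len(nrow(s1))) {
      chains[[length(chains) + 1L]] <- cbind(1L, r)
      active[[r]] <- length(chains)
    }
  }
  for (t in seq_len(nfr - 1)) {
    sa <- spots_by_frame[[t]]; sb <- spots_by_frame[[t + 1]]
    links <- link_frame_pair(sa, sb, config$max_link_distance)
    nxt <- vector("list", max(1L, nrow(sb)))
    if (nrow(sb) > 0) {
      matched_b <- integer(0)
      if (nrow(links) > 0) {
        for (k in seq_len(nrow(links))) {
          ci <- active[[links$a[k]]]
          chains[[ci]] <- rbind(chains[[ci]], cbind(t + 1L, links$b[k]))
          nxt[[links$b[k]]] <- ci
        }
        matched_b <- links$b
      }
      for (r in setdiff(seq_len(nrow(sb)), matched_b)) {
        chains[[length(chains) + 1L]] <- cbind(t + 1L, r)
        nxt[[r]] <- length(chains)
      }
    }
    active <- nxt
  }
  tracks <- list()
  for (ch in chains) {
    if (nrow(ch) < 2) next
    sp <- do.call(rbind, lapply(seq_len(nrow(ch)), function(k) {
      spots_by_frame[[ch[k, 1]]][ch[k, 2], c("frame", "x_um", "y_um", "quality")]
    }))
    rownames(sp) <- NULL
    tracks[[length(tracks) + 1L]] <- sp
  }
  if (length(tracks) == 0) return(list())
  ord <- order(vapply(tracks, function(s) s$frame[1], numeric(1)),
               vapply(tracks, function(s) s$y_um[1], numeric(1)),
               vapply(tracks, function(s) s$x_um[1], numeric(1)))
  tracks[ord]
}

#' Track displacement
#'
#' Straight-line (Euclidean) distance in um between a track's first and
#' last spot; a looping track that returns to its start has displacement 0.
#'
#' @param track A track data frame (`x_um`, `y_um` in spot order).
#' @return Displacement in um.
#' @export
track_displacement <- function(track) {
  n <- nrow(track)
  sqrt((track$x_um[n] - track$x_um[1])^2 + (track$y_um[n] - track$y_um[1])^2)
}

#' Mean track speed
#'
#' Total traveled path length (sum of consecutive step lengths) divided by
#' the track duration (`number of steps x frame_interval`), in um/s.
#'
#' @param track A track data frame.
#' @param frame_interval Frame interval in seconds.
#' @return Mean speed in um/s.
#' @export
track_mean_speed <- function(track, frame_interval) {
  stopifnot(frame_interval > 0)
  n <- nrow(track)
  steps <- sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)
  sum(steps) / ((n - 1) * frame_interval)
}

#' Keep motile tracks only
#'
#' Retains tracks whose displacement is strictly greater than
#' `min_track_displacement` (a track exactly at the threshold is *not*
#' motile); input order is preserved.
#'
#' @param tracks List of tracks.
#' @param min_track_displacement Displacement threshold in um.
#' @return Filtered list of tracks.
#' @export
filter_motile <- function(tracks, min_track_displacement) {
  Filter(function(tr) track_displacement(tr) > min_track_displacement, tracks)
}

#' Per-track feature table
#'
#' @param tracks List of tracks from [build_tracks()].
#' @param config A [pipeline_config()] (motility threshold).
#' @param calibration A [calibration()] (frame interval).
#' @return Data frame with one row per track: `track_id`, `n_spots`,
#'   `first_frame`, `last_frame`, `displacement_um`,
#'   `mean_speed_um_per_s`, `motile` (0/1).
#' @export
tracks_table <- function(tracks, config, calibration) {
  if (length(tracks) == 0) return(empty_tracks_table())
  disp <- vapply(tracks, track_displacement, numeric(1))
  data.frame(
    track_id = seq_along(tracks),
    n_spots = vapply(tracks, nrow, integer(1)),
    first_frame = vapply(tracks, function(s) as.integer(s$frame[1]), integer(1)),
    last_frame = vapply(tracks, function(s) as.integer(s$frame[nrow(s)]), integer(1)),
    displacement_um = disp,
    mean_speed_um_per_s = vapply(tracks, track_mean_speed, numeric(1),
                                 frame_interval = calibration$frame_interval),
    motile = as.integer(disp > config$min_track_displacement))
}
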