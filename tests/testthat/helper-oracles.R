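# Shared fixtures and independent oracles used across the test files.

cal02 <- calibration(pixel_size = 0.2, frame_interval = 4)

# Brute-force oracle for frame-pair linking: enumerate every one-to-one
# matching that uses only pairs within the cutoff, prefer maximum
# cardinality, then minimum total squared distance.  Recursive over the
# spots of frame a; feasible only for small instances.
brute_link_cost <- function(spots_a, spots_b, cutoff) {
  n <- nrow(spots_a); m <- nrow(spots_b)
  d2 <- outer(spots_a$x_um, spots_b$x_um, "-")^2 +
        outer(spots_a$y_um, spots_b$y_um, "-")^2
  feasible <- d2 <= cutoff^2
  best <- list(card = -1L, cost = Inf)
  recurse <- function(i, used_b, card, cost) {
    if (i > n) {
      if (card > best$card || (card == best$card && cost < best$cost))
        best <<- list(card = card, cost = cost)
      return(invisible())
    }
    recurse(i + 1L, used_b, card, cost)           # leave spot i unmatched
    for (j in seq_len(m)) {
      if (!used_b[j] && feasible[i, j]) {
        used_b[j] <- TRUE
        recurse(i + 1L, used_b, card + 1L, cost + d2[i, j])
        used_b[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, m), 0L, 0)
  best
}

link_cost <- function(matches, spots_a, spots_b) {
  if (nrow(matches) == 0) return(list(card = 0L, cost = 0))
  d2 <- (spots_a$x_um[matches$a] - spots_b$x_um[matches$b])^2 +
        (spots_a$y_um[matches$a] - spots_b$y_um[matches$b])^2
  list(card = nrow(matches), cost = sum(d2))
}

random_spots <- function(n, extent = 5) {
  data.frame(x_um = runif(n, 0, extent), y_um = runif(n, 0, extent))
}

# Exhaustive Feret oracle: max pairwise distance over all 4 corner points
# of every pixel (no convex hull shortcut).
brute_feret <- function(pixels, pixel_size) {
  pts <- rbind(cbind(pixels[, 1] - 0.5, pixels[, 2] - 0.5),
               cbind(pixels[, 1] + 0.5, pixels[, 2] - 0.5),
               cbind(pixels[, 1] - 0.5, pixels[, 2] + 0.5),
               cbind(pixels[, 1] + 0.5, pixels[, 2] + 0.5))
  d2 <- outer(pts[, 1], pts[, 1], "-")^2 + outer(pts[, 2], pts[, 2], "-")^2
  sqrt(max(d2)) * pixel_size
}

# Random 8-connected pixel component grown from a seed pixel.
random_component <- function(n_px) {
  pts <- matrix(c(0, 0), ncol = 2)
  while (nrow(pts) < n_px) {
    base <- pts[sample.int(nrow(pts), 1), ]
    step <- c(sample(-1:1, 1), sample(-1:1, 1))
    cand <- base + step
    if (!any(pts[, 1] == cand[1] & pts[, 2] == cand[2]))
      pts <- rbind(pts, cand)
  }
  pts
}

# Rasterize an ellipse (semi-axes in um, rotation phi) into a logical mask.
raster_ellipse <- function(semi_a_um, semi_b_um, phi, pixel_size,
                           field_px = 64) {
  c0 <- (field_px - 1) / 2
  xs <- matrix((0:(field_px - 1)) - c0, field_px, field_px, byrow = TRUE)
  ys <- t(xs)
  u <- (xs * cos(phi) + ys * sin(phi)) * pixel_size
  v <- (-xs * sin(phi) + ys * cos(phi)) * pixel_size
  (u / semi_a_um)^2 + (v / semi_b_um)^2 <= 1
}

# Independent re-implementation of Dunn's z and p for one pair, written
# directly from the definition with its own rank/tie handling.
dunn_pair_oracle <- function(groups, a, b) {
  x <- unlist(groups, use.names = FALSE)
  lab <- rep(names(groups), vapply(groups, length, integer(1)))
  n <- length(x)
  # midranks computed by explicit counting rather than rank()
  r <- vapply(seq_len(n), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
  tie_sizes <- as.numeric(table(x))
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (n - 1))
  va <- n * (n + 1) / 12 - tie_term
  ra <- mean(r[lab == a]); rb <- mean(r[lab == b])
  na <- sum(lab == a); nb <- sum(lab == b)
  z <- (ra - rb) / sqrt(va * (1 / na + 1 / nb))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

# A small scene that keeps unit tests fast.
small_scene <- function(seed, ...) {
  scene_config(field_px = 128L, n_mitochondria = 12L, n_frames = 10L,
               seed = seed, ...)
}
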