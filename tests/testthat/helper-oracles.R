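# Independent brute-force oracles, deliberately implemented differently
# from the package's geometry code paths.

# Winding-number point-in-polygon, one point at a time (signed angle sum).
oracle_point_in_polygon <- function(px, py, rings) {
  if (is.matrix(rings)) rings <- list(rings)
  vapply(seq_along(px), function(k) {
    crossings <- 0L
    for (ring in rings) {
      ring <- as.matrix(ring)
      n <- nrow(ring)
      for (i in seq_len(n)) {
        j <- if (i == n) 1L else i + 1L
        y1 <- ring[i, 2]; y2 <- ring[j, 2]
        if ((y1 <= py[k]) != (y2 <= py[k])) {
          xint <- ring[i, 1] + (py[k] - y1) * (ring[j, 1] - ring[i, 1]) / (y2 - y1)
          if (px[k] < xint) crossings <- crossings + 1L
        }
      }
    }
    crossings %% 2L == 1L
  }, logical(1))
}

# Grid-integration oracle for the area of (polygon intersect disc).
oracle_circle_polygon_area <- function(rings, center, r, n_grid = 400) {
  if (is.matrix(rings)) rings <- list(rings)
  outer <- as.matrix(rings[[1]])
  x0 <- max(min(outer[, 1]), center[1] - r); x1 <- min(max(outer[, 1]), center[1] + r)
  y0 <- max(min(outer[, 2]), center[2] - r); y1 <- min(max(outer[, 2]), center[2] + r)
  if (x1 <= x0 || y1 <= y0) return(0)
  xs <- seq(x0, x1, length.out = n_grid)
  ys <- seq(y0, y1, length.out = n_grid)
  g <- expand.grid(x = xs, y = ys)
  in_disc <- (g$x - center[1])^2 + (g$y - center[2])^2 <= r^2
  in_poly <- stereotau::point_in_polygon(g$x, g$y, rings)
  mean(in_disc & in_poly) * (x1 - x0) * (y1 - y0)
}

# All-pairs nearest-distance vessel association oracle (plain loops).
oracle_vessel_association <- function(markers, vessels, threshold = 100,
                                      min_diameter = 30) {
  elig <- vessels[vessels$diameter > min_diameter, , drop = FALSE]
  n_assoc <- 0L
  dists <- numeric(0)
  for (i in seq_len(nrow(elig))) {
    best <- Inf
    for (j in seq_len(nrow(markers))) {
      if (markers$section_id[j] != elig$section_id[i]) next
      d <- sqrt((markers$x[j] - elig$x[i])^2 + (markers$y[j] - elig$y[i])^2)
      best <- min(best, max(0, d - elig$diameter[i] / 2))
    }
    if (is.finite(best) && best <= threshold) {
      n_assoc <- n_assoc + 1L
      dists <- c(dists, best)
    }
  }
  list(n_vessels = nrow(elig), n_associated = n_assoc,
       pct = if (nrow(elig) > 0) 100 * n_assoc / nrow(elig) else NA_real_,
       mean_distance = if (n_assoc > 0) mean(dists) else NA_real_)
}

# Random star-shaped simple polygon around a center.
random_simple_polygon <- function(n = 12, center = c(0, 0), rmin = 50, rmax = 200) {
  ang <- sort(stats::runif(n, 0, 2 * pi))
  rad <- stats::runif(n, rmin, rmax)
  cbind(center[1] + rad * cos(ang), center[2] + rad * sin(ang))
}
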