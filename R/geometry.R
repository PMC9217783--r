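# Small planar-geometry toolkit for annotation polygons.
#
# Polygons are lists of rings; each ring is an n x 2 numeric matrix of
# vertices in micrometres, stored *open* (last vertex not repeated).
# Ring 1 is the outer boundary, subsequent rings are holes. Winding is
# normalized on construction: outer counter-clockwise, holes clockwise.

#' Signed shoelace area of a single ring
#'
#' Positive for counter-clockwise vertex order.
#'
#' @param ring n x 2 numeric matrix, open ring.
#' @return Signed area in squared input units.
#' @keywords internal
ring_area_signed <- function(ring) {
  n <- nrow(ring)
  if (is.null(n) || n < 3) return(0)
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Normalize a polygon's ring windings
#'
#' Outer ring counter-clockwise, holes clockwise; drops a repeated closing
#' vertex if present.
#'
#' @param rings list of n x 2 matrices (ring 1 outer, rest holes).
#' @return list of matrices with normalized winding.
#' @keywords internal
normalize_polygon <- function(rings) {
  lapply(seq_along(rings), function(i) {
    ring <- as.matrix(rings[[i]])
    storage.mode(ring) <- "double"
    n <- nrow(ring)
    if (n > 1 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
    a <- ring_area_signed(ring)
    want_ccw <- (i == 1L)
    if ((a < 0 && want_ccw) || (a > 0 && !want_ccw)) {
      ring <- ring[rev(seq_len(nrow(ring))), , drop = FALSE]
    }
    unname(ring)
  })
}

#' Area of a polygon with holes
#'
#' @param rings list of open rings (ring 1 outer, rest holes).
#' @return Non-negative area: |outer| minus the summed hole areas.
#' @export
polygon_area <- function(rings) {
  if (is.matrix(rings)) rings <- list(rings)
  areas <- vapply(rings, function(r) abs(ring_area_signed(as.matrix(r))), numeric(1))
  if (length(areas) == 0) return(0)
  areas[1] - sum(areas[-1])
}

# Even-odd crossing test for a vector of points against one ring.
# Vectorized over points; loops over edges.
points_in_ring <- function(px, py, ring) {
  ring <- as.matrix(ring)
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  if (n < 3) return(inside)
  xs <- ring[, 1]; ys <- ring[, 2]
  j <- n
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    cr <- (yi > py) != (yj > py)
    if (any(cr)) {
      xint <- xi + (py[cr] - yi) * (xj - xi) / (yj - yi)
      inside[cr] <- xor(inside[cr], px[cr] < xint)
    }
    j <- i
  }
  inside
}

#' Point-in-polygon test (even-odd rule, holes respected)
#'
#' @param px,py coordinate vectors of equal length.
#' @param rings polygon as a list of open rings, or a single matrix.
#' @return Logical vector: TRUE where the point falls in the polygon's
#'   interior (inside the outer ring an odd number of ring crossings).
#' @export
point_in_polygon <- function(px, py, rings) {
  if (is.matrix(rings)) rings <- list(rings)
  inside <- rep(FALSE, length(px))
  for (ring in rings) inside <- xor(inside, points_in_ring(px, py, ring))
  inside
}

# Strict (proper) crossing of segment (ax,ay)-(bx,by) against segments
# (cx,cy)-(dx,dy); all of c/d may be vectors. Shared endpoints and
# collinear touching do not count.
segments_cross <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  o <- function(px, py, qx, qy, rx, ry) (qx - px) * (ry - py) - (qy - py) * (rx - px)
  o1 <- o(ax, ay, bx, by, cx, cy)
  o2 <- o(ax, ay, bx, by, dx, dy)
  o3 <- o(cx, cy, dx, dy, ax, ay)
  o4 <- o(cx, cy, dx, dy, bx, by)
  (o1 * o2 < 0) & (o3 * o4 < 0)
}

# TRUE when a ring is simple: no two non-adjacent edges properly cross.
ring_is_simple <- function(ring) {
  ring <- as.matrix(ring)
  n <- nrow(ring)
  if (n < 3) return(FALSE)
  xs <- ring[, 1]; ys <- ring[, 2]
  nx <- c(xs[-1], xs[1]); ny <- c(ys[-1], ys[1])
  for (i in seq_len(n - 2L)) {
    # skip adjacent edges (i-1, i, i+1) and the wrap pair (1, n)
    js <- seq.int(i + 2L, n)
    if (i == 1L) js <- js[js < n]
    if (length(js) == 0) next
    hit <- segments_cross(xs[i], ys[i], nx[i], ny[i],
                          xs[js], ys[js], nx[js], ny[js])
    if (any(hit)) return(FALSE)
  }
  TRUE
}

# Minimum distance from points to any edge of a ring (vectorized over points).
dist_to_ring <- function(px, py, ring) {
  ring <- as.matrix(ring)
  n <- nrow(ring)
  xs <- ring[, 1]; ys <- ring[, 2]
  nx <- c(xs[-1], xs[1]); ny <- c(ys[-1], ys[1])
  best <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    ex <- nx[i] - xs[i]; ey <- ny[i] - ys[i]
    len2 <- ex * ex + ey * ey
    if (len2 == 0) {
      d2 <- (px - xs[i])^2 + (py - ys[i])^2
    } else {
      t <- pmin(1, pmax(0, ((px - xs[i]) * ex + (py - ys[i]) * ey) / len2))
      d2 <- (px - xs[i] - t * ex)^2 + (py - ys[i] - t * ey)^2
    }
    best <- pmin(best, d2)
  }
  sqrt(best)
}

# Exact interior-overlap test for two simple polygons (outer rings only).
# Overlap <=> boundaries properly cross, or one polygon has a vertex
# strictly inside the other (farther than eps from its boundary). Shared
# boundary segments between adjacent regions do not trigger.
polygons_interiors_overlap <- function(rings_a, rings_b, eps = NULL) {
  a <- as.matrix(if (is.matrix(rings_a)) rings_a else rings_a[[1]])
  b <- as.matrix(if (is.matrix(rings_b)) rings_b else rings_b[[1]])
  if (max(a[, 1]) < min(b[, 1]) || max(b[, 1]) < min(a[, 1]) ||
      max(a[, 2]) < min(b[, 2]) || max(b[, 2]) < min(a[, 2])) {
    return(FALSE)
  }
  if (is.null(eps)) {
    scale <- sqrt(max(abs(ring_area_signed(a)), abs(ring_area_signed(b)), 1))
    eps <- 1e-6 * scale
  }
  na <- nrow(a)
  ax <- a[, 1]; ay <- a[, 2]
  anx <- c(ax[-1], ax[1]); any_ <- c(ay[-1], ay[1])
  bx <- b[, 1]; by <- b[, 2]
  bnx <- c(bx[-1], bx[1]); bny <- c(by[-1], by[1])
  for (i in seq_len(na)) {
    hit <- segments_cross(ax[i], ay[i], anx[i], any_[i], bx, by, bnx, bny)
    if (any(hit, na.rm = TRUE)) return(TRUE)
  }
  # vertices or edge midpoints of one ring strictly interior to the other
  # (catches overlaps whose boundaries touch only at shared vertices/edges)
  strictly_inside <- function(px, py, ring) {
    ins <- points_in_ring(px, py, ring)
    any(ins) && any(dist_to_ring(px[ins], py[ins], ring) > eps)
  }
  if (strictly_inside(c(ax, (ax + anx) / 2), c(ay, (ay + any_) / 2), b)) return(TRUE)
  if (strictly_inside(c(bx, (bx + bnx) / 2), c(by, (by + bny) / 2), a)) return(TRUE)
  FALSE
}

# Per-edge contribution to the disc-polygon intersection area
# (coordinates already relative to the circle center).
edge_disc_contrib <- function(ax, ay, bx, by, r) {
  dx <- bx - ax; dy <- by - ay
  A <- dx * dx + dy * dy
  if (A == 0) return(0)
  B <- 2 * (ax * dx + ay * dy)
  C <- ax * ax + ay * ay - r * r
  disc <- B * B - 4 * A * C
  ts <- c(0, 1)
  if (disc > 0) {
    sq <- sqrt(disc)
    cand <- c((-B - sq) / (2 * A), (-B + sq) / (2 * A))
    cand <- cand[cand > 0 & cand < 1]
    ts <- sort(unique(c(0, cand, 1)))
  }
  total <- 0
  r2 <- r * r
  for (k in seq_len(length(ts) - 1L)) {
    t0 <- ts[k]; t1 <- ts[k + 1L]
    tm <- (t0 + t1) / 2
    mx <- ax + tm * dx; my <- ay + tm * dy
    p0x <- ax + t0 * dx; p0y <- ay + t0 * dy
    p1x <- ax + t1 * dx; p1y <- ay + t1 * dy
    if (mx * mx + my * my <= r2) {
      total <- total + 0.5 * (p0x * p1y - p0y * p1x)
    } else {
      dth <- atan2(p1y, p1x) - atan2(p0y, p0x)
      dth <- dth - 2 * pi * round(dth / (2 * pi))
      total <- total + 0.5 * r2 * dth
    }
  }
  total
}

#' Exact area of intersection between a disc and a polygon
#'
#' Decomposes each polygon edge into sub-segments inside and outside the
#' disc; inside parts contribute signed triangle areas, outside parts the
#' circular sector they subtend (Green's theorem along the clipped
#' boundary). Holes subtract through their winding.
#'
#' @param rings polygon (list of open rings, or single matrix).
#' @param center numeric length-2, disc center.
#' @param r disc radius (same units as the vertices).
#' @return Intersection area, in squared input units.
#' @export
circle_polygon_area <- function(rings, center, r) {
  if (is.matrix(rings)) rings <- list(rings)
  total <- 0
  for (ring in rings) {
    ring <- as.matrix(ring)
    n <- nrow(ring)
    if (n < 3) next
    px <- ring[, 1] - center[1]
    py <- ring[, 2] - center[2]
    nx <- c(px[-1], px[1]); ny <- c(py[-1], py[1])
    for (i in seq_len(n)) {
      total <- total + edge_disc_contrib(px[i], py[i], nx[i], ny[i], r)
    }
  }
  abs(total)
}

# Apply a 2x2 linear + translation affine to an n x 2 coordinate matrix.
# coef: named numeric (a, b, c, d, tx, ty); x' = a x + b y + tx, y' = c x + d y + ty.
apply_affine <- function(xy, coef) {
  xy <- as.matrix(xy)
  cbind(coef[["a"]] * xy[, 1] + coef[["b"]] * xy[, 2] + coef[["tx"]],
        coef[["c"]] * xy[, 1] + coef[["d"]] * xy[, 2] + coef[["ty"]])
}
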