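# Spatial analyses on aligned annotations: cortical-layer assignment,
# sulcal/gyral partition, perivascular association and density heatmaps.

#' Assign markers to cortical layer polygons
#'
#' Each marker receives the label of the layer polygon containing it in
#' its own section; candidate layers are tried in the canonical order I,
#' II, III, IV-VI, WM so that a marker on a shared band boundary resolves
#' deterministically to the more superficial layer. Markers outside every
#' polygon are labelled `"unassigned"`; their number is attached as the
#' `n_unassigned` attribute.
#'
#' @param markers tibble with `section_id`, `x`, `y` (and optionally
#'   `structure`, carried through).
#' @param layers tibble with `section_id`, `layer`, `polygon` (as in an
#'   [annotation_set()]).
#' @return The `markers` tibble with an added `layer` column and a
#'   `marker` row-index column; attribute `n_unassigned`.
#' @export
assign_markers_to_layers <- function(markers, layers) {
  markers <- tibble::as_tibble(markers)
  out <- markers
  out$marker <- seq_len(nrow(markers))
  out$layer <- rep("unassigned", nrow(markers))
  if (nrow(markers) > 0 && nrow(layers) > 0) {
    order_key <- match(layers$layer, LAYER_LABELS)
    for (sec in unique(markers$section_id)) {
      mi <- which(markers$section_id == sec)
      li <- which(layers$section_id == sec)
      li <- li[order(order_key[li])]
      unass <- mi
      for (j in li) {
        if (length(unass) == 0) break
        hit <- point_in_polygon(markers$x[unass], markers$y[unass],
                                layers$polygon[[j]])
        out$layer[unass[hit]] <- layers$layer[j]
        unass <- unass[!hit]
      }
    }
  }
  attr(out, "n_unassigned") <- sum(out$layer == "unassigned")
  out
}

#' Partition in-cortex markers into sulcal and gyral compartments
#'
#' The sulcal depth is the mean Euclidean distance from the annotated
#' fundus to the two sulcus mouth points; a marker is *sulcal* when it
#' lies in the grey-matter ribbon and within `depth_fraction` (default
#' one third, taken from the sulcus annotation) of the depth from the
#' fundus, measured as straight-line distance. All other in-ribbon
#' markers are *gyral*; markers outside the ribbon are `"unassigned"`.
#' Sections without a sulcus annotation are entirely gyral.
#'
#' Compartment areas (needed for densities) are computed per section:
#' the sulcal area is the exact intersection of the fundus-centred disc
#' with each grey-layer polygon, the gyral area is the remaining grey
#' ribbon area.
#'
#' @param markers tibble with `section_id`, `x`, `y` (and optionally
#'   `structure`).
#' @param layers layer polygons as in an [annotation_set()].
#' @param sulci sulcus annotations as in an [annotation_set()].
#' @param grey_layers layer labels forming the cortical ribbon.
#' @return List with `labels` (markers plus `label` and
#'   `distance_to_fundus`) and `areas` (per-section tibble with
#'   `sulcal_area` and `gyral_area`, µm²).
#' @export
partition_sulcal_gyral <- function(markers, layers, sulci,
                                   grey_layers = GREY_LAYERS) {
  assigned <- assign_markers_to_layers(markers, layers)
  in_ribbon <- assigned$layer %in% grey_layers

  labels <- assigned
  labels$label <- ifelse(in_ribbon, "gyral", "unassigned")
  labels$distance_to_fundus <- NA_real_

  grey <- layers[layers$layer %in% grey_layers, , drop = FALSE]
  secs <- unique(grey$section_id)
  areas <- tibble::tibble(section_id = secs, sulcal_area = 0,
                          gyral_area = NA_real_)
  for (k in seq_along(secs)) {
    sec <- secs[k]
    gi <- which(grey$section_id == sec)
    grey_area <- sum(vapply(grey$polygon[gi], polygon_area, numeric(1)))
    s <- sulci[sulci$section_id == sec, , drop = FALSE]
    sulcal_area <- 0
    if (nrow(s) >= 1) {
      s <- s[1, ]
      da <- sqrt((s$fundus_x - s$mouth_ax)^2 + (s$fundus_y - s$mouth_ay)^2)
      db <- sqrt((s$fundus_x - s$mouth_bx)^2 + (s$fundus_y - s$mouth_by)^2)
      depth <- mean(c(da, db))
      if (depth <= 0) stop("degenerate sulcus (zero depth) in section ", sec)
      radius <- s$depth_fraction * depth
      for (j in gi) {
        sulcal_area <- sulcal_area +
          circle_polygon_area(grey$polygon[[j]], c(s$fundus_x, s$fundus_y), radius)
      }
      mi <- which(labels$section_id == sec)
      if (length(mi) > 0) {
        d <- sqrt((labels$x[mi] - s$fundus_x)^2 + (labels$y[mi] - s$fundus_y)^2)
        labels$distance_to_fundus[mi] <- d
        sulcal <- d <= radius & labels$label[mi] == "gyral"
        labels$label[mi][sulcal] <- "sulcal"
      }
    }
    areas$sulcal_area[k] <- sulcal_area
    areas$gyral_area[k] <- grey_area - sulcal_area
  }
  list(labels = labels, areas = areas)
}

#' Volume-adjusted densities for the sulcal and gyral compartments
#'
#' Counts partitioned markers (optionally one structure type), scales the
#' counts by the design's inverse sampling fractions, and divides by the
#' compartment volume (summed compartment area across sections times the
#' section period).
#'
#' @param partition result of [partition_sulcal_gyral()].
#' @param design a [sampling_design()].
#' @param structure restrict to one marker structure (default: all).
#' @param unit_scale `"per_mm3"` (default, matching how sulcal/gyral
#'   densities are conventionally tabulated) or `"per_cm3"`.
#' @param subject_id,region carried into the output rows.
#' @return Two-row density tibble (sulcal, gyral) as from
#'   [layer_density()].
#' @export
regional_density <- function(partition, design, structure = NULL,
                             unit_scale = "per_mm3",
                             subject_id = NA_character_, region = NA_character_) {
  labels <- partition$labels
  if (!is.null(structure)) labels <- labels[labels$structure %in% structure, ]
  rows <- lapply(c("sulcal", "gyral"), function(lab) {
    area <- sum(partition$areas[[paste0(lab, "_area")]])
    if (!(area > 0)) stop("zero ", lab, " area; cannot form a density")
    cnt <- sum(labels$label == lab)
    fr <- sampling_fractions(design)
    pop <- cnt / (fr[["ssf"]] * fr[["asf"]] * fr[["tsf"]])
    layer_density(pop, area * design$section_period, unit_scale = unit_scale,
                  subject_id = subject_id, region = region,
                  partition_label = lab,
                  structure = if (is.null(structure)) "all" else structure)
  })
  dplyr::bind_rows(rows)
}

#' Perivascular association of tau markers with blood vessels
#'
#' For every vessel larger than `min_diameter` (strictly), the distance
#' from the vessel *edge* to its nearest marker on the same section is
#' `max(0, ||marker - center|| - diameter/2)`; the vessel is associated
#' when that distance is at most `threshold` (inclusive). The summary
#' reports the eligible-vessel count, the associated count and
#' percentage, and the mean nearest-marker edge distance over associated
#' vessels only.
#'
#' @param markers tibble with `section_id`, `x`, `y`, and optionally
#'   `structure`.
#' @param vessels tibble with `section_id`, `x`, `y`, `diameter` (µm).
#' @param threshold association distance from the vessel edge, µm.
#' @param min_diameter eligibility cut-off (exclusive), µm.
#' @param structures optionally restrict the marker types considered
#'   (default: all pooled).
#' @return Object of class `vessel_association`: list with `n_vessels`,
#'   `n_associated`, `pct_associated` (`NA` when no vessel is eligible),
#'   `mean_distance` (`NA` when none associated), `threshold`,
#'   `min_diameter`, and a per-vessel `detail` tibble.
#' @export
vessel_association <- function(markers, vessels, threshold = 100,
                               min_diameter = 30, structures = NULL) {
  if (!(threshold > 0)) stop("threshold must be positive")
  markers <- tibble::as_tibble(markers)
  vessels <- tibble::as_tibble(vessels)
  if (nrow(vessels) > 0 && any(!(vessels$diameter > 0))) {
    stop("vessel diameters must be positive")
  }
  if (!is.null(structures) && "structure" %in% names(markers)) {
    markers <- markers[markers$structure %in% structures, , drop = FALSE]
  }
  elig <- vessels[vessels$diameter > min_diameter, , drop = FALSE]
  n_elig <- nrow(elig)
  detail <- tibble::tibble(section_id = elig$section_id, x = elig$x, y = elig$y,
                           diameter = elig$diameter,
                           edge_distance = rep(NA_real_, n_elig),
                           associated = rep(FALSE, n_elig))
  if (n_elig > 0 && nrow(markers) > 0) {
    for (sec in unique(elig$section_id)) {
      vi <- which(elig$section_id == sec)
      mi <- which(markers$section_id == sec)
      if (length(mi) == 0) next
      mx <- markers$x[mi]; my <- markers$y[mi]
      for (j in vi) {
        d2 <- (mx - elig$x[j])^2 + (my - elig$y[j])^2
        detail$edge_distance[j] <- max(0, sqrt(min(d2)) - elig$diameter[j] / 2)
      }
    }
    detail$associated <- !is.na(detail$edge_distance) &
      detail$edge_distance <= threshold
  }
  n_assoc <- sum(detail$associated)
  structure(
    list(n_vessels = n_elig,
         n_associated = n_assoc,
         pct_associated = if (n_elig > 0) 100 * n_assoc / n_elig else NA_real_,
         mean_distance = if (n_assoc > 0) {
           mean(detail$edge_distance[detail$associated])
         } else NA_real_,
         threshold = threshold, min_diameter = min_diameter,
         detail = detail),
    class = "vessel_association")
}

#' @export
print.vessel_association <- function(x, ...) {
  cat(sprintf("<vessel_association> %d/%d vessels (> %g µm) within %g µm: %s%%, mean edge distance %s µm\n",
              x$n_associated, x$n_vessels, x$min_diameter, x$threshold,
              if (is.na(x$pct_associated)) "NA" else sprintf("%.1f", x$pct_associated),
              if (is.na(x$mean_distance)) "NA" else sprintf("%.1f", x$mean_distance)))
  invisible(x)
}

#' Binned density heatmap of pooled marker coordinates
#'
#' Bins raw marker coordinates (pooled across the aligned serial
#' sections, no fractionator correction) onto a square grid, optionally
#' followed by Gaussian smoothing. The raw `counts` matrix always sums to
#' the number of binned markers.
#'
#' @param markers tibble with `x`, `y` and optionally `structure`.
#' @param cell bin side length, µm (default 250).
#' @param bandwidth Gaussian smoothing bandwidth in µm (default one
#'   cell), or `NULL` to skip smoothing.
#' @param structure restrict to one structure type (default: all).
#' @param origin grid origin; defaults to the lower-left corner of the
#'   marker bounding box.
#' @return Object of class `heatmap_grid`: list with `origin`, `cell`,
#'   `counts` (rows indexing x bins, columns y bins), `smoothed` (or
#'   `NULL`), `structure`.
#' @export
density_heatmap <- function(markers, cell = 250, bandwidth = cell,
                            structure = NULL, origin = NULL) {
  if (!(cell > 0)) stop("cell size must be positive")
  markers <- tibble::as_tibble(markers)
  if (!is.null(structure) && "structure" %in% names(markers)) {
    markers <- markers[markers$structure %in% structure, , drop = FALSE]
  }
  if (nrow(markers) == 0) {
    counts <- matrix(0, 1, 1)
    if (is.null(origin)) origin <- c(0, 0)
  } else {
    if (is.null(origin)) origin <- c(min(markers$x), min(markers$y))
    ix <- floor((markers$x - origin[1]) / cell) + 1L
    iy <- floor((markers$y - origin[2]) / cell) + 1L
    keep <- ix >= 1L & iy >= 1L
    ix <- ix[keep]; iy <- iy[keep]
    counts <- matrix(0, max(ix), max(iy))
    for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1
  }
  smoothed <- NULL
  if (!is.null(bandwidth)) {
    if (!(bandwidth > 0)) stop("bandwidth must be positive")
    smoothed <- gaussian_smooth_matrix(counts, sigma = bandwidth / cell)
  }
  structure(list(origin = origin, cell = cell, counts = counts,
                 smoothed = smoothed, structure = structure),
            class = "heatmap_grid")
}

# Separable Gaussian blur; sigma in cell units. Each source cell spreads
# its mass with a kernel renormalized over the in-grid support, so the
# total is conserved exactly.
gaussian_smooth_matrix <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq.int(-r, r), sd = sigma)
  blur1 <- function(mat) {
    n <- nrow(mat)
    # normalization: kernel mass that stays in-grid for each source row
    w <- vapply(seq_len(n), function(i) {
      o <- seq.int(max(1L, i - r), min(n, i + r)) - i
      sum(k[o + r + 1L])
    }, numeric(1))
    src <- mat / w
    out <- matrix(0, n, ncol(mat))
    for (o in seq.int(-r, r)) {
      dst <- seq_len(n) + o
      ok <- dst >= 1L & dst <= n
      out[dst[ok], ] <- out[dst[ok], , drop = FALSE] +
        k[o + r + 1L] * src[ok, , drop = FALSE]
    }
    out
  }
  t(blur1(t(blur1(m))))
}

#' Long-format data frame view of a heatmap grid
#'
#' @param x a `heatmap_grid`.
#' @param which `"counts"` or `"smoothed"`.
#' @param ... unused.
#' @return Tibble with bin-centre coordinates `x`, `y` (µm) and `value`.
#' @export
as.data.frame.heatmap_grid <- function(x, which = c("counts", "smoothed"), ...) {
  which <- match.arg(which)
  m <- x[[which]]
  if (is.null(m)) stop("heatmap has no ", which, " layer")
  ij <- expand.grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  xc <- x$origin[1] + (ij$i - 0.5) * x$cell
  yc <- x$origin[2] + (ij$j - 0.5) * x$cell
  tibble::tibble(x = xc, y = yc, value = m[cbind(ij$i, ij$j)])
}
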