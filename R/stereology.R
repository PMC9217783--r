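# Design-based stereology: optical-fractionator population estimates,
# Gundersen-Jensen coefficient of error, Cavalieri volumes and
# volume-adjusted densities.

#' Sampling design for the optical fractionator
#'
#' Holds the counting-frame dimensions, the area sampling fraction of the
#' SRS grid, the optical dissector height with its guard zones, the knife
#' cut thickness, the serial section period, and the mounted (post-
#' processing) section thickness. Defaults correspond to exhaustive
#' counting with a 700 x 700 µm frame at 100% grid coverage, an 11 µm
#' dissector with 2 µm guard zones top and bottom, 50 µm cut sections
#' every 500 µm, and a 15 µm mounted thickness.
#'
#' The mounted thickness is the denominator of the thickness sampling
#' fraction and therefore rescales every population estimate by a
#' constant; its default (dissector height plus both guards, the minimum
#' admissible value) should be replaced by a measured value whenever one
#' is available.
#'
#' @param frame_w,frame_h counting-frame width and height, µm.
#' @param grid_fraction fraction of the region of interest covered by
#'   counting frames, in (0, 1]; 1 means exhaustive counting.
#' @param dissector_height optical dissector height, µm.
#' @param guard_top,guard_bottom guard-zone thicknesses, µm.
#' @param cut_thickness knife setting at sectioning, µm.
#' @param section_period distance between consecutive sampled sections, µm.
#' @param mounted_thickness measured section thickness after mounting, µm.
#' @return An object of class `sampling_design`.
#' @export
sampling_design <- function(frame_w = 700, frame_h = 700, grid_fraction = 1,
                            dissector_height = 11, guard_top = 2, guard_bottom = 2,
                            cut_thickness = 50, section_period = 500,
                            mounted_thickness = 15) {
  d <- list(frame_w = frame_w, frame_h = frame_h, grid_fraction = grid_fraction,
            dissector_height = dissector_height, guard_top = guard_top,
            guard_bottom = guard_bottom, cut_thickness = cut_thickness,
            section_period = section_period, mounted_thickness = mounted_thickness)
  num <- vapply(d, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), logical(1))
  if (!all(num)) stop("all design fields must be finite numeric scalars")
  if (frame_w <= 0 || frame_h <= 0) stop("counting frame dimensions must be positive")
  if (!(grid_fraction > 0 && grid_fraction <= 1)) {
    stop("grid_fraction must lie in (0, 1]")
  }
  if (dissector_height <= 0) stop("dissector_height must be positive")
  if (guard_top < 0 || guard_bottom < 0) stop("guard zones cannot be negative")
  if (dissector_height + guard_top + guard_bottom > mounted_thickness) {
    stop("dissector plus guard zones exceed the mounted thickness")
  }
  if (mounted_thickness > cut_thickness) {
    stop("mounted thickness cannot exceed the cut thickness")
  }
  if (section_period < cut_thickness) {
    stop("section period cannot be smaller than the cut thickness")
  }
  structure(d, class = "sampling_design")
}

#' Sampling fractions implied by a design
#'
#' @param design a [sampling_design()].
#' @return Named numeric vector with `ssf` (section sampling fraction,
#'   cut thickness / section period), `asf` (area sampling fraction, the
#'   grid fraction) and `tsf` (thickness sampling fraction, dissector
#'   height / mounted thickness). All lie in (0, 1].
#' @export
sampling_fractions <- function(design) {
  stopifnot(inherits(design, "sampling_design"))
  c(ssf = design$cut_thickness / design$section_period,
    asf = design$grid_fraction,
    tsf = design$dissector_height / design$mounted_thickness)
}

#' Gundersen-Jensen coefficient of error for a systematic section series
#'
#' For per-section counts \eqn{Q_i}, with \eqn{A = \sum Q_i^2},
#' \eqn{B = \sum Q_i Q_{i+1}}, \eqn{C = \sum Q_i Q_{i+2}} and total
#' \eqn{n = \sum Q_i}, the systematic-sampling variance contribution is
#' \eqn{(3(A - n) - 4B + C)/240} for smoothness class `m = 1` (the
#' conventional choice for smooth biological series) or denominator 12
#' for `m = 0`, clamped at zero when negative. The CE is
#' \eqn{\sqrt{n + Var_{SRS}} / n}: Poisson counting noise plus the
#' systematic component, relative to the total count.
#'
#' @param section_counts non-negative integer counts, in serial order.
#' @param m smoothness class, 0 or 1 (default 1).
#' @return The CE as a proportion, or `NA_real_` when undefined (fewer
#'   than 3 sections, or an all-zero series).
#' @export
gundersen_ce <- function(section_counts, m = 1) {
  q <- as.numeric(section_counts)
  if (any(q < 0)) stop("section counts must be non-negative")
  if (!m %in% c(0, 1)) stop("smoothness class m must be 0 or 1")
  n <- sum(q)
  if (length(q) < 3 || n == 0) return(NA_real_)
  A <- sum(q^2)
  B <- sum(q[-length(q)] * q[-1])
  C <- sum(q[seq_len(length(q) - 2)] * q[-(1:2)])
  denom <- if (m == 1) 240 else 12
  var_srs <- (3 * (A - n) - 4 * B + C) / denom
  var_srs <- max(0, var_srs)
  sqrt(n + var_srs) / n
}

#' Optical-fractionator population estimate
#'
#' Scales the raw dissector count by the inverse sampling fractions:
#' \eqn{\hat N = \sum Q^- \cdot \frac{1}{ssf}\cdot\frac{1}{asf}\cdot\frac{1}{tsf}}.
#'
#' @param section_counts non-negative per-section counts in serial order.
#' @param design a [sampling_design()].
#' @param m smoothness class passed to [gundersen_ce()].
#' @return An object of class `population_estimate`: list with
#'   `raw_count`, `ssf`, `asf`, `tsf`, `estimate` and `ce` (`NA` when the
#'   series has fewer than 3 sections or no counts).
#' @export
fractionator_estimate <- function(section_counts, design, m = 1) {
  q <- as.numeric(section_counts)
  if (length(q) < 1) stop("at least one section count is required")
  if (any(q < 0)) stop("section counts must be non-negative")
  fr <- sampling_fractions(design)
  raw <- sum(q)
  structure(
    list(raw_count = raw,
         ssf = unname(fr["ssf"]), asf = unname(fr["asf"]), tsf = unname(fr["tsf"]),
         estimate = raw / (fr[["ssf"]] * fr[["asf"]] * fr[["tsf"]]),
         ce = gundersen_ce(q, m = m),
         n_sections = length(q)),
    class = "population_estimate")
}

#' @export
print.population_estimate <- function(x, ...) {
  cat(sprintf("<population_estimate> raw %d -> N-hat %.2f (ssf %.3g, asf %.3g, tsf %.3g), CE %s\n",
              x$raw_count, x$estimate, x$ssf, x$asf, x$tsf,
              if (is.na(x$ce)) "undefined" else sprintf("%.3f", x$ce)))
  invisible(x)
}

#' Cavalieri volume from serial profile areas
#'
#' @param areas numeric vector of per-section profile areas, µm²
#'   (optionally named by section id).
#' @param spacing distance between consecutive sections, µm.
#' @return Object of class `volume_estimate`: list with
#'   `per_section_areas`, `spacing` and `volume` (µm³, the summed areas
#'   times the spacing).
#' @export
cavalieri_volume <- function(areas, spacing) {
  areas <- as.numeric(areas)
  if (length(areas) == 0) stop("at least one section area is required")
  if (any(areas < 0)) stop("section areas must be non-negative")
  if (!(spacing > 0)) stop("section spacing must be positive")
  structure(list(per_section_areas = areas, spacing = spacing,
                 volume = sum(areas) * spacing),
            class = "volume_estimate")
}

UNIT_SCALE_UM3 <- c(per_mm3 = 1e9, per_cm3 = 1e12)

#' Volume-adjusted density record
#'
#' @param estimate a `population_estimate` or a plain numeric population.
#' @param volume a `volume_estimate` or a plain numeric volume in µm³.
#' @param unit_scale `"per_mm3"` or `"per_cm3"`.
#' @param subject_id,region,partition_label,structure identifying fields
#'   carried into the output row.
#' @return One-row tibble with `subject_id`, `region`, `partition_label`,
#'   `structure`, `density`, `unit_scale`, `population`, `volume_um3`.
#' @export
layer_density <- function(estimate, volume, unit_scale = c("per_cm3", "per_mm3"),
                          subject_id = NA_character_, region = NA_character_,
                          partition_label = NA_character_,
                          structure = NA_character_) {
  unit_scale <- match.arg(unit_scale)
  pop <- if (inherits(estimate, "population_estimate")) estimate$estimate else as.numeric(estimate)
  vol <- if (inherits(volume, "volume_estimate")) volume$volume else as.numeric(volume)
  if (!(vol > 0)) stop("volume must be positive")
  tibble::tibble(subject_id = subject_id, region = region,
                 partition_label = partition_label, structure = structure,
                 density = pop / vol * UNIT_SCALE_UM3[[unit_scale]],
                 unit_scale = unit_scale,
                 population = pop, volume_um3 = vol)
}

# ---------------------------------------------------------------------------
# Sampling simulators (used for design calibration and unbiasedness checks)

#' Per-section dissector counts for a slab of 1-D particle depths
#'
#' Simulates how a fractionator design samples particles along the
#' sectioning axis: a particle at depth `z` falls in a sampled section
#' when `z` lies within the first `cut_thickness` of a period starting at
#' `phase`, and is counted when its relative depth within the mounted
#' section falls inside the dissector window (between the top guard and
#' the guard plus dissector height), modelling uniform compression from
#' cut to mounted thickness.
#'
#' @param z numeric vector of particle depths, µm.
#' @param design a [sampling_design()].
#' @param phase sectioning phase offset in `[0, section_period)`, µm.
#' @return Integer vector of per-section dissector counts covering the
#'   sampled range (sections with no particles included as zeros).
#' @export
section_dissector_counts <- function(z, design, phase = 0) {
  stopifnot(inherits(design, "sampling_design"))
  p <- design$section_period
  rel <- (z - phase) %% p
  sec <- floor((z - phase) / p)
  in_section <- rel < design$cut_thickness
  # uniform compression of the cut section onto the mounted thickness
  mounted_depth <- rel / design$cut_thickness * design$mounted_thickness
  counted <- in_section &
    mounted_depth >= design$guard_top &
    mounted_depth < design$guard_top + design$dissector_height
  if (!any(in_section)) return(integer(0))
  rng <- range(sec)
  idx <- factor(sec[counted], levels = seq.int(rng[1], rng[2]))
  as.integer(table(idx))
}

#' Counting-frame subsampling with the forbidden-line rule
#'
#' Places a counting frame of `frame_w` x `frame_h` at the origin corner
#' of every grid tile and keeps the points falling inside it, counting
#' points on the inclusion (left/bottom) edges and excluding the
#' forbidden (right/top) edges. With tile dimensions equal to the frame
#' this reduces to exhaustive counting.
#'
#' @param xy n x 2 matrix of point coordinates, µm.
#' @param design a [sampling_design()]; the grid tile area is
#'   `frame_w * frame_h / grid_fraction`, split isotropically.
#' @param origin grid origin (length 2), µm.
#' @return Logical vector: TRUE for counted points.
#' @export
frame_counted <- function(xy, design, origin = c(0, 0)) {
  stopifnot(inherits(design, "sampling_design"))
  xy <- as.matrix(xy)
  s <- 1 / sqrt(design$grid_fraction)
  tw <- design$frame_w * s
  th <- design$frame_h * s
  rx <- (xy[, 1] - origin[1]) %% tw
  ry <- (xy[, 2] - origin[2]) %% th
  rx >= 0 & rx < design$frame_w & ry >= 0 & ry < design$frame_h
}
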