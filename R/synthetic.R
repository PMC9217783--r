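# Synthetic annotation-set generator with known ground truth.
#
# Emulates the statistical structure the analyses assume: a layered
# gyrus-sulcus cortical ribbon, marker intensity decaying geometrically
# with laminar depth, enrichment in the bottom third of the sulcus
# (exactly (1+beta)-fold in expectation, by Poisson thinning), sparse
# white matter, and a share of markers drawn as Gaussian clusters around
# blood vessels.

#' Parameters of the synthetic annotation generator
#'
#' @param lambda0 layer-I background marker intensity, markers/mm².
#' @param depth_decay multiplicative intensity decay per layer (layer
#'   \eqn{l} gets `lambda0 * depth_decay^(l-1)`), in (0, 1].
#' @param wm_factor white-matter intensity as a fraction of `lambda0`;
#'   should not exceed the grey-profile minimum.
#' @param sulcal_enrichment beta >= 0: the sulcal compartment's intensity
#'   is `(1 + beta)`-fold the local layer intensity.
#' @param vessel_density vessels/mm² of ribbon (grey plus white matter).
#' @param vessel_diameter_meanlog,vessel_diameter_sdlog log-normal
#'   diameter parameters, µm scale; the default mean 40 µm with sd-log
#'   0.4 leaves roughly a quarter of vessels below the 30 µm eligibility
#'   cut so the filter is exercised.
#' @param perivascular_fraction share of markers drawn as Gaussian
#'   clusters around randomly chosen vessels, in \[0, 1\].
#' @param cluster_sd Gaussian cluster spread around the vessel centre, µm.
#' @param n_sections number of serial sections.
#' @param seed master seed; geometry, vessel and marker streams derive
#'   fixed substreams from it.
#' @param width mediolateral extent of the modelled ribbon, µm.
#' @param sulcus_depth amplitude of the sulcal infolding, µm (0 for a
#'   flat ribbon without a sulcus annotation).
#' @param sulcus_width Gaussian half-width of the infolding, µm.
#' @param layer_thickness named vector of grey band thicknesses, µm, for
#'   layers I, II, III, IV-VI.
#' @param wm_thickness white-matter band thickness, µm.
#' @param sulcus_depth_fraction fraction of the sulcal depth defining the
#'   sulcal compartment (default 1/3, the bottom-third rule).
#' @param structure_mix marker-type proportions (neuropil threads
#'   dominate, neurons rare, as in tau-immunostained cortex).
#' @param section_wobble relative smooth variation of the sulcus
#'   amplitude across the serial series.
#' @param subject_id,region identifiers stamped on the generated set.
#' @return List of class `synthetic_params`.
#' @export
synthetic_params <- function(lambda0 = 200, depth_decay = 0.6, wm_factor = 0.02,
                             sulcal_enrichment = 2, vessel_density = 5,
                             vessel_diameter_meanlog = log(40),
                             vessel_diameter_sdlog = 0.4,
                             perivascular_fraction = 0.2, cluster_sd = 50,
                             n_sections = 10, seed = 1,
                             width = 8000, sulcus_depth = 3000,
                             sulcus_width = 500,
                             layer_thickness = c("I" = 200, "II" = 300,
                                                 "III" = 500, "IV-VI" = 800),
                             wm_thickness = 700,
                             sulcus_depth_fraction = 1 / 3,
                             structure_mix = c(neuropil_thread = 0.88,
                                               neuritic_thread_cluster = 0.10,
                                               neuron = 0.02),
                             section_wobble = 0.05,
                             subject_id = "synthetic", region = "prefrontal") {
  stopifnot(lambda0 >= 0, depth_decay > 0, depth_decay <= 1, wm_factor >= 0,
            sulcal_enrichment >= 0, vessel_density >= 0,
            perivascular_fraction >= 0, perivascular_fraction <= 1,
            cluster_sd > 0, n_sections >= 1, width > 0,
            sulcus_depth >= 0, sulcus_width > 0,
            all(layer_thickness > 0), wm_thickness > 0,
            sulcus_depth_fraction > 0, sulcus_depth_fraction <= 1)
  if (wm_factor > depth_decay^(length(layer_thickness) - 1)) {
    stop("wm_factor must not exceed the grey-matter intensity profile minimum")
  }
  structure(as.list(environment()), class = "synthetic_params")
}

# Deterministic substream seeds below 2^31, derived from the master seed.
substream_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483647
}

# Per-section sulcus amplitude (smooth variation across the series).
section_amplitude <- function(params, s) {
  params$sulcus_depth *
    (1 + params$section_wobble * sin(2 * pi * s / max(1, params$n_sections)))
}

# Pial surface height at x for one section (y = 0 baseline, dips downward).
pial_y <- function(params, amplitude, x) {
  -amplitude * exp(-(x - params$width / 2)^2 / (2 * params$sulcus_width^2))
}

#' Build the layered gyrus-sulcus geometry for every section
#'
#' The pial surface is a Gaussian infolding of amplitude `sulcus_depth`;
#' grey bands (layers I, II, III, IV-VI) and the white-matter core are
#' vertical offsets of the pial curve, so each band's area is exactly
#' `width * thickness` up to polygonization. Fundus and mouth landmarks
#' sit on the pial curve (mouths where the infolding has decayed to 5% of
#' its amplitude). A flat ribbon (`sulcus_depth = 0`) carries no sulcus
#' annotation.
#'
#' @param params a [synthetic_params()].
#' @return List with `layers` (tibble as in [annotation_set()]), `sulci`,
#'   `sections`, `amplitudes` and `params`.
#' @export
make_cortex_geometry <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  set.seed(substream_seed(params$seed, 1))
  nx <- 101L
  xs <- seq(0, params$width, length.out = nx)
  cum <- cumsum(c(0, params$layer_thickness))
  depths_top <- cum[-length(cum)]
  depths_bot <- cum[-1]
  bands <- c(names(params$layer_thickness), "WM")
  depths_top <- c(depths_top, cum[length(cum)])
  depths_bot <- c(depths_bot, cum[length(cum)] + params$wm_thickness)

  sections <- sprintf("s%02d", seq_len(params$n_sections))
  amplitudes <- vapply(seq_len(params$n_sections), function(s) {
    section_amplitude(params, s)
  }, numeric(1))

  layer_rows <- list()
  sulci_rows <- list()
  for (s in seq_len(params$n_sections)) {
    yp <- pial_y(params, amplitudes[s], xs)
    for (b in seq_along(bands)) {
      top <- cbind(xs, yp - depths_top[b])
      bot <- cbind(rev(xs), rev(yp) - depths_bot[b])
      layer_rows[[length(layer_rows) + 1L]] <- tibble::tibble(
        section_id = sections[s], layer = bands[b],
        polygon = list(list(rbind(top, bot))))
    }
    if (params$sulcus_depth > 0) {
      xm <- params$sulcus_width * sqrt(2 * log(20))  # 5% decay point
      xa <- params$width / 2 - xm
      xb <- params$width / 2 + xm
      sulci_rows[[length(sulci_rows) + 1L]] <- tibble::tibble(
        section_id = sections[s],
        fundus_x = params$width / 2, fundus_y = -amplitudes[s],
        mouth_ax = xa, mouth_ay = pial_y(params, amplitudes[s], xa),
        mouth_bx = xb, mouth_by = pial_y(params, amplitudes[s], xb),
        depth_fraction = params$sulcus_depth_fraction)
    }
  }
  list(layers = dplyr::bind_rows(layer_rows),
       sulci = if (length(sulci_rows) > 0) dplyr::bind_rows(sulci_rows) else
         tibble::tibble(section_id = character(), fundus_x = numeric(),
                        fundus_y = numeric(), mouth_ax = numeric(),
                        mouth_ay = numeric(), mouth_bx = numeric(),
                        mouth_by = numeric(), depth_fraction = numeric()),
       sections = sections, amplitudes = amplitudes, params = params)
}

#' Sample blood vessels as a homogeneous Poisson process in the ribbon
#'
#' Vessel centres are uniform over the full ribbon (grey plus white
#' matter) of each section; diameters are log-normal, deliberately
#' spanning the 30 µm eligibility cut.
#'
#' @param geometry result of [make_cortex_geometry()].
#' @param params a [synthetic_params()] (defaults to the geometry's).
#' @return Vessel tibble (`section_id`, `x`, `y`, `diameter`).
#' @export
sample_vessels <- function(geometry, params = geometry$params) {
  set.seed(substream_seed(params$seed, 2))
  thickness <- sum(params$layer_thickness) + params$wm_thickness
  area_mm2 <- params$width * thickness / 1e6
  rows <- list()
  for (s in seq_along(geometry$sections)) {
    n <- stats::rpois(1, params$vessel_density * area_mm2)
    if (n == 0) next
    x <- stats::runif(n, 0, params$width)
    depth <- stats::runif(n, 0, thickness)
    y <- pial_y(params, geometry$amplitudes[s], x) - depth
    rows[[length(rows) + 1L]] <- tibble::tibble(
      section_id = geometry$sections[s], x = x, y = y,
      diameter = stats::rlnorm(n, params$vessel_diameter_meanlog,
                               params$vessel_diameter_sdlog))
  }
  if (length(rows) == 0) {
    return(tibble::tibble(section_id = character(), x = numeric(),
                          y = numeric(), diameter = numeric()))
  }
  dplyr::bind_rows(rows)
}

# Straight-line sulcal radius (depth_fraction x mean fundus-mouth distance)
# for one section, or NA when that section has no sulcus.
sulcal_radius <- function(geometry, section_id) {
  s <- geometry$sulci[geometry$sulci$section_id == section_id, , drop = FALSE]
  if (nrow(s) == 0) return(NA_real_)
  da <- sqrt((s$fundus_x - s$mouth_ax)^2 + (s$fundus_y - s$mouth_ay)^2)
  db <- sqrt((s$fundus_x - s$mouth_bx)^2 + (s$fundus_y - s$mouth_by)^2)
  s$depth_fraction[1] * mean(c(da, db))
}

#' Sample markers with layered, sulcus-enriched, perivascular structure
#'
#' Background markers follow an inhomogeneous Poisson process with
#' intensity `lambda0 * depth_decay^(l-1)` in grey layer \eqn{l} and
#' `wm_factor * lambda0` in white matter; candidates are generated at the
#' `(1 + beta)`-inflated rate and thinned outside the sulcal compartment,
#' so the sulcal intensity is exactly `(1 + beta)`-fold in expectation.
#' A `perivascular_fraction` share of markers is then drawn as Gaussian
#' clusters (sd `cluster_sd`) around uniformly chosen vessels of the same
#' section. Marker types follow `structure_mix`.
#'
#' @param geometry result of [make_cortex_geometry()].
#' @param vessels vessel tibble (required when
#'   `perivascular_fraction > 0`).
#' @param params a [synthetic_params()] (defaults to the geometry's).
#' @return List with `markers` (tibble) and `truth`, the generation-time
#'   ground truth: per-stratum background counts, perivascular counts,
#'   intended intensities and the realized vessel-association truth.
#' @export
sample_markers <- function(geometry, vessels, params = geometry$params) {
  set.seed(substream_seed(params$seed, 3))
  pf <- params$perivascular_fraction
  if (pf > 0 && (is.null(vessels) || nrow(vessels) == 0)) {
    stop("perivascular_fraction > 0 requires vessels in the geometry")
  }
  beta <- params$sulcal_enrichment
  bands <- c(names(params$layer_thickness), "WM")
  mult <- c(params$depth_decay^(seq_along(params$layer_thickness) - 1),
            params$wm_factor)
  cum <- cumsum(c(0, params$layer_thickness, params$wm_thickness))
  rows <- list()
  truth_counts <- list()
  peri_vessels <- character(0)
  n_peri_total <- 0
  for (s in seq_along(geometry$sections)) {
    sec <- geometry$sections[s]
    amp <- geometry$amplitudes[s]
    radius <- sulcal_radius(geometry, sec)
    sul <- geometry$sulci[geometry$sulci$section_id == sec, , drop = FALSE]
    sec_bg <- 0
    for (b in seq_along(bands)) {
      lam_mm2 <- params$lambda0 * mult[b]
      area_mm2 <- params$width * (cum[b + 1] - cum[b]) / 1e6
      n_cand <- stats::rpois(1, lam_mm2 * (1 + beta) * (1 - pf) * area_mm2)
      n_kept_sulcal <- 0L; n_kept_gyral <- 0L
      if (n_cand > 0) {
        x <- stats::runif(n_cand, 0, params$width)
        depth <- stats::runif(n_cand, cum[b], cum[b + 1])
        y <- pial_y(params, amp, x) - depth
        if (nrow(sul) > 0 && is.finite(radius)) {
          d <- sqrt((x - sul$fundus_x[1])^2 + (y - sul$fundus_y[1])^2)
          sulcal <- d <= radius
        } else {
          sulcal <- rep(FALSE, n_cand)
        }
        keep <- sulcal | (stats::runif(n_cand) < 1 / (1 + beta))
        x <- x[keep]; y <- y[keep]; sulcal <- sulcal[keep]
        n_kept_sulcal <- sum(sulcal); n_kept_gyral <- sum(!sulcal)
        if (length(x) > 0) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            section_id = sec, x = x, y = y,
            structure = sample(names(params$structure_mix), length(x),
                               replace = TRUE, prob = params$structure_mix))
          sec_bg <- sec_bg + length(x)
        }
      }
      truth_counts[[length(truth_counts) + 1L]] <- tibble::tibble(
        section_id = sec, layer = bands[b],
        intensity_mm2 = lam_mm2,
        n_background = n_kept_sulcal + n_kept_gyral,
        n_sulcal = n_kept_sulcal, n_gyral = n_kept_gyral)
    }
    if (pf > 0) {
      vi <- which(vessels$section_id == sec)
      if (length(vi) > 0 && sec_bg > 0) {
        n_peri <- stats::rpois(1, pf / (1 - pf) * sec_bg)
        if (n_peri > 0) {
          pick <- vi[sample.int(length(vi), n_peri, replace = TRUE)]
          rows[[length(rows) + 1L]] <- tibble::tibble(
            section_id = sec,
            x = vessels$x[pick] + stats::rnorm(n_peri, 0, params$cluster_sd),
            y = vessels$y[pick] + stats::rnorm(n_peri, 0, params$cluster_sd),
            structure = sample(names(params$structure_mix), n_peri,
                               replace = TRUE, prob = params$structure_mix))
          peri_vessels <- c(peri_vessels, paste0(sec, ":", pick))
          n_peri_total <- n_peri_total + n_peri
        }
      }
    }
  }
  markers <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    tibble::tibble(section_id = character(), x = numeric(), y = numeric(),
                   structure = character())
  truth <- list(
    per_stratum = dplyr::bind_rows(truth_counts),
    n_background = sum(vapply(truth_counts, function(t) sum(t$n_background),
                              numeric(1))),
    n_perivascular = n_peri_total,
    clustered_vessels = unique(peri_vessels),
    vessel_truth_association_rate =
      if (is.null(vessels) || nrow(vessels) == 0) NA_real_ else
        length(unique(peri_vessels)) / nrow(vessels),
    lambda0 = params$lambda0, depth_decay = params$depth_decay,
    sulcal_enrichment = beta, wm_factor = params$wm_factor,
    perivascular_fraction = pf)
  list(markers = markers, truth = truth)
}

#' Generate a complete synthetic annotation set with ground truth
#'
#' Runs geometry, vessel and marker generation under the master seed,
#' assembles an [annotation_set()] with identity transforms and the
#' default sampling design, and optionally writes the plain-text bundle
#' plus a `ground_truth.json`.
#'
#' @param params a [synthetic_params()].
#' @param dir optional output directory for
#'   [write_annotation_set()] plus the ground-truth JSON.
#' @param design a [sampling_design()] stamped on the set.
#' @return List with `set` (the `annotation_set`) and `truth`.
#' @export
generate_annotation_bundle <- function(params = synthetic_params(), dir = NULL,
                                       design = sampling_design()) {
  geometry <- make_cortex_geometry(params)
  vessels <- sample_vessels(geometry, params)
  mk <- sample_markers(geometry, vessels, params)
  set <- annotation_set(subject_id = params$subject_id, region = params$region,
                        sections = geometry$sections,
                        layers = geometry$layers, markers = mk$markers,
                        vessels = vessels, sulci = geometry$sulci,
                        design = design)
  if (!is.null(dir)) {
    write_annotation_set(set, dir)
    truth_json <- mk$truth
    truth_json$clustered_vessels <- NULL  # internal ids, not part of the contract
    jsonlite::write_json(truth_json, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  list(set = set, truth = mk$truth)
}
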