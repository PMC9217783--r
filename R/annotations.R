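# Annotation-set data model and plain-text bundle I/O.
#
# An annotation set mirrors what a stereology workstation exports for one
# subject/region: serial section ids, layer contours, typed marker points,
# blood vessels, sulcus landmarks, per-section alignment transforms and the
# sampling design used to place the markers. All coordinates are planar
# micrometres.

MARKER_STRUCTURES <- c("neuropil_thread", "neuritic_thread_cluster", "neuron")
LAYER_LABELS <- c("I", "II", "III", "IV-VI", "WM")
GREY_LAYERS <- c("I", "II", "III", "IV-VI")
REGION_LABELS <- c("prefrontal", "parietal")

IDENTITY_AFFINE <- c(a = 1, b = 0, c = 0, d = 1, tx = 0, ty = 0)

#' Assemble an annotation set
#'
#' @param subject_id character scalar.
#' @param region `"prefrontal"` or `"parietal"`.
#' @param sections character vector of section ids in serial (anatomical)
#'   order; the order is declared, never inferred from the ids.
#' @param layers tibble with columns `section_id`, `layer` (one of I, II,
#'   III, IV-VI, WM) and `polygon` (list column; each element a list of
#'   open rings, ring 1 the outer boundary). Winding is normalized here.
#' @param markers tibble with columns `section_id`, `x`, `y`, `structure`.
#' @param vessels tibble with columns `section_id`, `x`, `y`, `diameter`
#'   (µm), or `NULL`.
#' @param sulci tibble with columns `section_id`, `fundus_x`, `fundus_y`,
#'   `mouth_ax`, `mouth_ay`, `mouth_bx`, `mouth_by`, `depth_fraction`, or
#'   `NULL`.
#' @param transforms tibble with columns `section_id`, `a`, `b`, `c`, `d`,
#'   `tx`, `ty`; defaults to the identity for every section.
#' @param design a [sampling_design()].
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(subject_id, region, sections,
                           layers, markers,
                           vessels = NULL, sulci = NULL,
                           transforms = NULL,
                           design = sampling_design()) {
  sections <- as.character(sections)
  layers <- tibble::as_tibble(layers)
  layers$polygon <- lapply(layers$polygon, normalize_polygon)
  markers <- tibble::as_tibble(markers)
  if (is.null(vessels)) {
    vessels <- tibble::tibble(section_id = character(), x = numeric(),
                              y = numeric(), diameter = numeric())
  }
  if (is.null(sulci)) {
    sulci <- tibble::tibble(section_id = character(),
                            fundus_x = numeric(), fundus_y = numeric(),
                            mouth_ax = numeric(), mouth_ay = numeric(),
                            mouth_bx = numeric(), mouth_by = numeric(),
                            depth_fraction = numeric())
  }
  if (is.null(transforms)) {
    transforms <- tibble::tibble(section_id = sections,
                                 a = 1, b = 0, c = 0, d = 1, tx = 0, ty = 0)
  }
  structure(
    list(subject_id = as.character(subject_id),
         region = as.character(region),
         sections = sections,
         layers = layers,
         markers = tibble::as_tibble(markers),
         vessels = tibble::as_tibble(vessels),
         sulci = tibble::as_tibble(sulci),
         transforms = tibble::as_tibble(transforms),
         design = design),
    class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> subject %s, region %s\n", x$subject_id, x$region))
  cat(sprintf("  %d sections, %d layer polygons, %d markers, %d vessels, %d sulci\n",
              length(x$sections), nrow(x$layers), nrow(x$markers),
              nrow(x$vessels), nrow(x$sulci)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Validation

new_finding <- function(code, message, id) {
  tibble::tibble(code = code, message = message, id = as.character(id))
}

#' Validate an annotation set against its structural invariants
#'
#' Violations are returned as data, not raised: unknown marker structures,
#' non-finite coordinates, references to undeclared sections, non-simple or
#' zero-area layer polygons, overlapping layer interiors within a section,
#' non-positive vessel diameters, degenerate sulci, out-of-range depth
#' fractions and singular alignment transforms. Findings are ordered
#' deterministically (by code, then offending id).
#'
#' @param set an [annotation_set()].
#' @return A `validation_report`: list with tibbles `errors` and `warnings`
#'   (columns `code`, `message`, `id`).
#' @export
validate_annotation_set <- function(set) {
  errors <- list()
  warnings <- list()
  known <- set$sections

  if (!set$region %in% REGION_LABELS) {
    errors[[length(errors) + 1L]] <- new_finding(
      "BAD_REGION", sprintf("region '%s' is not one of %s", set$region,
                            paste(REGION_LABELS, collapse = ", ")), set$region)
  }

  m <- set$markers
  if (nrow(m) > 0) {
    bad <- which(!m$structure %in% MARKER_STRUCTURES)
    for (i in bad) {
      errors[[length(errors) + 1L]] <- new_finding(
        "BAD_STRUCTURE",
        sprintf("marker row %d has unknown structure '%s'", i, m$structure[i]),
        paste0("marker:", i))
    }
    bad <- which(!is.finite(m$x) | !is.finite(m$y))
    for (i in bad) {
      errors[[length(errors) + 1L]] <- new_finding(
        "BAD_COORD", sprintf("marker row %d has non-finite coordinates", i),
        paste0("marker:", i))
    }
    bad <- which(!m$section_id %in% known)
    for (i in bad) {
      errors[[length(errors) + 1L]] <- new_finding(
        "UNKNOWN_SECTION",
        sprintf("marker row %d references undeclared section '%s'", i, m$section_id[i]),
        paste0("marker:", i))
    }
  }

  v <- set$vessels
  if (nrow(v) > 0) {
    bad <- which(!(v$diameter > 0) | !is.finite(v$diameter))
    for (i in bad) {
      errors[[length(errors) + 1L]] <- new_finding(
        "BAD_DIAMETER",
        sprintf("vessel row %d has non-positive diameter %s", i, v$diameter[i]),
        paste0("vessel:", i))
    }
    bad <- which(!v$section_id %in% known)
    for (i in bad) {
      errors[[length(errors) + 1L]] <- new_finding(
        "UNKNOWN_SECTION",
        sprintf("vessel row %d references undeclared section '%s'", i, v$section_id[i]),
        paste0("vessel:", i))
    }
  }

  L <- set$layers
  if (nrow(L) > 0) {
    for (i in seq_len(nrow(L))) {
      lid <- paste0("layer:", L$section_id[i], ":", L$layer[i])
      if (!L$layer[i] %in% LAYER_LABELS) {
        errors[[length(errors) + 1L]] <- new_finding(
          "BAD_LAYER", sprintf("unknown layer label '%s'", L$layer[i]), lid)
      }
      if (!L$section_id[i] %in% known) {
        errors[[length(errors) + 1L]] <- new_finding(
          "UNKNOWN_SECTION",
          sprintf("layer polygon references undeclared section '%s'", L$section_id[i]), lid)
      }
      poly <- L$polygon[[i]]
      ok <- length(poly) >= 1 && nrow(poly[[1]]) >= 3 &&
        all(vapply(poly, function(r) all(is.finite(r)), logical(1)))
      if (!ok || polygon_area(poly) <= 0 || !ring_is_simple(poly[[1]])) {
        errors[[length(errors) + 1L]] <- new_finding(
          "BAD_POLYGON", "layer polygon is degenerate, non-simple or has zero area", lid)
      }
    }
    # pairwise interior overlap within a section
    for (sec in unique(L$section_id)) {
      idx <- which(L$section_id == sec)
      if (length(idx) < 2) next
      for (a in seq_along(idx)[-length(idx)]) {
        for (b in seq.int(a + 1L, length(idx))) {
          ia <- idx[a]; ib <- idx[b]
          pa <- L$polygon[[ia]]; pb <- L$polygon[[ib]]
          if (length(pa) < 1 || length(pb) < 1) next
          if (polygons_interiors_overlap(pa, pb)) {
            errors[[length(errors) + 1L]] <- new_finding(
              "LAYER_OVERLAP",
              sprintf("layers %s and %s overlap in section %s",
                      L$layer[ia], L$layer[ib], sec),
              paste0("layer:", sec, ":", L$layer[ia], "+", L$layer[ib]))
          }
        }
      }
    }
  }

  s <- set$sulci
  if (nrow(s) > 0) {
    for (i in seq_len(nrow(s))) {
      sid <- paste0("sulcus:", s$section_id[i])
      if (!(s$depth_fraction[i] > 0 && s$depth_fraction[i] <= 1)) {
        errors[[length(errors) + 1L]] <- new_finding(
          "BAD_DEPTH_FRACTION",
          sprintf("depth_fraction %s outside (0, 1]", s$depth_fraction[i]), sid)
      }
      da <- sqrt((s$fundus_x[i] - s$mouth_ax[i])^2 + (s$fundus_y[i] - s$mouth_ay[i])^2)
      db <- sqrt((s$fundus_x[i] - s$mouth_bx[i])^2 + (s$fundus_y[i] - s$mouth_by[i])^2)
      if (da == 0 || db == 0) {
        errors[[length(errors) + 1L]] <- new_finding(
          "DEGENERATE_SULCUS", "fundus coincides with a mouth point", sid)
      }
      if (!s$section_id[i] %in% known) {
        errors[[length(errors) + 1L]] <- new_finding(
          "UNKNOWN_SECTION",
          sprintf("sulcus references undeclared section '%s'", s$section_id[i]), sid)
      }
    }
  }

  tr <- set$transforms
  if (nrow(tr) > 0) {
    det <- tr$a * tr$d - tr$b * tr$c
    for (i in which(abs(det) <= 1e-9)) {
      errors[[length(errors) + 1L]] <- new_finding(
        "SINGULAR_TRANSFORM",
        sprintf("transform for section '%s' has |det| <= 1e-9", tr$section_id[i]),
        paste0("transform:", tr$section_id[i]))
    }
  }
  missing_tr <- setdiff(set$sections, tr$section_id)
  for (sec in missing_tr) {
    warnings[[length(warnings) + 1L]] <- new_finding(
      "MISSING_TRANSFORM", sprintf("section '%s' has no alignment transform", sec),
      paste0("transform:", sec))
  }

  bind_findings <- function(lst) {
    if (length(lst) == 0) {
      return(tibble::tibble(code = character(), message = character(), id = character()))
    }
    out <- dplyr::bind_rows(lst)
    out[order(out$code, out$id), ]
  }
  structure(list(errors = bind_findings(errors), warnings = bind_findings(warnings)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d errors, %d warnings\n",
              nrow(x$errors), nrow(x$warnings)))
  if (nrow(x$errors) > 0) print(x$errors)
  invisible(x)
}

#' Does a validation report contain no errors?
#' @param report a `validation_report`.
#' @return Logical scalar.
#' @export
is_valid <- function(report) nrow(report$errors) == 0

# ---------------------------------------------------------------------------
# Alignment

#' Apply per-section alignment transforms to every coordinate
#'
#' Maps markers, vessels, layer polygons and sulcus landmarks of each
#' section through that section's affine (2x2 linear part plus
#' translation). Vessel diameters are rescaled by the linear part's
#' isotropic length factor `sqrt(|det|)`. The input set is not modified.
#'
#' @param set an [annotation_set()]; every section must have a transform.
#' @return A new `annotation_set` in aligned coordinates, with all
#'   transforms reset to the identity.
#' @export
apply_alignment <- function(set) {
  tr <- set$transforms
  missing_tr <- setdiff(unique(c(set$markers$section_id, set$vessels$section_id,
                                 set$layers$section_id, set$sulci$section_id,
                                 set$sections)),
                        tr$section_id)
  if (length(missing_tr) > 0) {
    stop("no alignment transform for section(s): ",
         paste(missing_tr, collapse = ", "))
  }
  coef_for <- function(sec) {
    r <- tr[tr$section_id == sec, ][1, ]
    c(a = r$a, b = r$b, c = r$c, d = r$d, tx = r$tx, ty = r$ty)
  }
  out <- set
  if (nrow(set$markers) > 0) {
    for (sec in unique(set$markers$section_id)) {
      cf <- coef_for(sec)
      i <- set$markers$section_id == sec
      xy <- apply_affine(cbind(set$markers$x[i], set$markers$y[i]), cf)
      out$markers$x[i] <- xy[, 1]; out$markers$y[i] <- xy[, 2]
    }
  }
  if (nrow(set$vessels) > 0) {
    for (sec in unique(set$vessels$section_id)) {
      cf <- coef_for(sec)
      i <- set$vessels$section_id == sec
      xy <- apply_affine(cbind(set$vessels$x[i], set$vessels$y[i]), cf)
      out$vessels$x[i] <- xy[, 1]; out$vessels$y[i] <- xy[, 2]
      scale <- sqrt(abs(cf[["a"]] * cf[["d"]] - cf[["b"]] * cf[["c"]]))
      out$vessels$diameter[i] <- set$vessels$diameter[i] * scale
    }
  }
  if (nrow(set$layers) > 0) {
    for (i in seq_len(nrow(set$layers))) {
      cf <- coef_for(set$layers$section_id[i])
      out$layers$polygon[[i]] <- normalize_polygon(
        lapply(set$layers$polygon[[i]], apply_affine, coef = cf))
    }
  }
  if (nrow(set$sulci) > 0) {
    for (i in seq_len(nrow(set$sulci))) {
      cf <- coef_for(set$sulci$section_id[i])
      pts <- apply_affine(rbind(c(set$sulci$fundus_x[i], set$sulci$fundus_y[i]),
                                c(set$sulci$mouth_ax[i], set$sulci$mouth_ay[i]),
                                c(set$sulci$mouth_bx[i], set$sulci$mouth_by[i])), cf)
      out$sulci$fundus_x[i] <- pts[1, 1]; out$sulci$fundus_y[i] <- pts[1, 2]
      out$sulci$mouth_ax[i] <- pts[2, 1]; out$sulci$mouth_ay[i] <- pts[2, 2]
      out$sulci$mouth_bx[i] <- pts[3, 1]; out$sulci$mouth_by[i] <- pts[3, 2]
    }
  }
  out$transforms <- tibble::tibble(section_id = tr$section_id,
                                   a = 1, b = 0, c = 0, d = 1, tx = 0, ty = 0)
  out
}

# ---------------------------------------------------------------------------
# Bundle I/O: config.yaml + geometry.geojson + markers.csv + vessels.csv +
# transforms.csv in one directory.

closed_ring <- function(ring) rbind(ring, ring[1, , drop = FALSE])

#' Write an annotation set as a plain-text bundle
#'
#' Produces `config.yaml` (subject, region, declared section order, design
#' constants), `geometry.geojson` (layer polygons and sulcus landmarks),
#' `markers.csv`, `vessels.csv` and `transforms.csv` under `dir`.
#'
#' @param set an [annotation_set()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_annotation_set <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(subject_id = set$subject_id,
              region = set$region,
              sections = as.list(set$sections),
              design = unclass(set$design))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))

  feats <- list()
  if (nrow(set$layers) > 0) {
    for (i in seq_len(nrow(set$layers))) {
      coords <- lapply(set$layers$polygon[[i]], function(r) {
        r <- closed_ring(as.matrix(r))
        lapply(seq_len(nrow(r)), function(k) c(r[k, 1], r[k, 2]))
      })
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        properties = list(role = "layer",
                          section_id = set$layers$section_id[i],
                          layer = set$layers$layer[i]),
        geometry = list(type = "Polygon", coordinates = coords))
    }
  }
  if (nrow(set$sulci) > 0) {
    for (i in seq_len(nrow(set$sulci))) {
      s <- set$sulci[i, ]
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        properties = list(role = "sulcus",
                          section_id = s$section_id,
                          depth_fraction = s$depth_fraction),
        geometry = list(type = "MultiPoint",
                        coordinates = list(c(s$fundus_x, s$fundus_y),
                                           c(s$mouth_ax, s$mouth_ay),
                                           c(s$mouth_bx, s$mouth_by))))
    }
  }
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, file.path(dir, "geometry.geojson"),
                       auto_unbox = TRUE, digits = NA)

  utils::write.csv(set$markers, file.path(dir, "markers.csv"), row.names = FALSE)
  utils::write.csv(set$vessels, file.path(dir, "vessels.csv"), row.names = FALSE)
  utils::write.csv(set$transforms, file.path(dir, "transforms.csv"), row.names = FALSE)
  invisible(dir)
}

#' Load an annotation set from a plain-text bundle
#'
#' Reads the files written by [write_annotation_set()]. Marker rows with a
#' structure label outside the recognized taxonomy are rejected with an
#' error naming the label and row. With `validate = TRUE` (default) the
#' loaded set must pass [validate_annotation_set()]; any errors abort with
#' the full finding list.
#'
#' @param dir bundle directory.
#' @param validate run full validation after loading?
#' @return An [annotation_set()].
#' @export
load_annotation_set <- function(dir, validate = TRUE) {
  need <- file.path(dir, c("config.yaml", "geometry.geojson", "markers.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0) {
    stop("annotation bundle incomplete; missing: ",
         paste(basename(missing), collapse = ", "))
  }
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  design <- do.call(sampling_design, cfg$design)

  gj <- jsonlite::read_json(file.path(dir, "geometry.geojson"),
                            simplifyVector = FALSE)
  layers_l <- list(); sulci_l <- list()
  for (f in gj$features) {
    role <- f$properties$role
    if (identical(role, "layer")) {
      rings <- lapply(f$geometry$coordinates, function(ring) {
        m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
        m
      })
      layers_l[[length(layers_l) + 1L]] <- tibble::tibble(
        section_id = f$properties$section_id,
        layer = f$properties$layer,
        polygon = list(rings))
    } else if (identical(role, "sulcus")) {
      pts <- f$geometry$coordinates
      sulci_l[[length(sulci_l) + 1L]] <- tibble::tibble(
        section_id = f$properties$section_id,
        fundus_x = pts[[1]][[1]], fundus_y = pts[[1]][[2]],
        mouth_ax = pts[[2]][[1]], mouth_ay = pts[[2]][[2]],
        mouth_bx = pts[[3]][[1]], mouth_by = pts[[3]][[2]],
        depth_fraction = f$properties$depth_fraction)
    }
  }
  layers <- if (length(layers_l) > 0) dplyr::bind_rows(layers_l) else
    tibble::tibble(section_id = character(), layer = character(), polygon = list())
  sulci <- if (length(sulci_l) > 0) dplyr::bind_rows(sulci_l) else NULL

  markers <- tibble::as_tibble(utils::read.csv(
    file.path(dir, "markers.csv"), colClasses = c(section_id = "character")))
  if (nrow(markers) == 0) {
    markers <- tibble::tibble(section_id = character(), x = numeric(),
                              y = numeric(), structure = character())
  }
  if (nrow(markers) > 0) {
    bad <- which(!markers$structure %in% MARKER_STRUCTURES)
    if (length(bad) > 0) {
      stop(sprintf("markers.csv row %d: unknown structure label '%s' (expected %s)",
                   bad[1], markers$structure[bad[1]],
                   paste(MARKER_STRUCTURES, collapse = ", ")))
    }
  }
  vessels <- NULL
  if (file.exists(file.path(dir, "vessels.csv"))) {
    vessels <- tibble::as_tibble(utils::read.csv(
      file.path(dir, "vessels.csv"), colClasses = c(section_id = "character")))
    if (nrow(vessels) == 0) vessels <- NULL
  }
  transforms <- NULL
  if (file.exists(file.path(dir, "transforms.csv"))) {
    transforms <- tibble::as_tibble(utils::read.csv(
      file.path(dir, "transforms.csv"), colClasses = c(section_id = "character")))
    if (nrow(transforms) == 0) transforms <- NULL
  }

  set <- annotation_set(subject_id = cfg$subject_id, region = cfg$region,
                        sections = unlist(cfg$sections),
                        layers = layers, markers = markers, vessels = vessels,
                        sulci = sulci, transforms = transforms, design = design)
  if (validate) {
    rep <- validate_annotation_set(set)
    if (!is_valid(rep)) {
      stop("annotation bundle failed validation:\n",
           paste(sprintf("  [%s] %s (%s)", rep$errors$code, rep$errors$message,
                         rep$errors$id), collapse = "\n"))
    }
  }
  set
}
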