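# End-to-end orchestration: validate -> align -> layer counts ->
# fractionator + CE -> Cavalieri volumes -> layer densities -> sulcal/gyral
# partition densities -> vessel association -> heatmaps, with long-format
# tables mirroring the standard reporting layout (individual x region x
# layer).

default_pipeline_config <- function() {
  list(unit_scale_layer = "per_cm3",
       unit_scale_partition = "per_mm3",
       heatmap_cell = 250,
       heatmap_bandwidth = 250,
       heatmap_structure = "neuropil_thread",
       vessel_threshold = 100,
       vessel_min_diameter = 30,
       vessel_structures = NULL,
       ce_limit = 0.15,
       out_dir = NULL,
       verbose = FALSE)
}

# Polynomial rolling hash over the deparsed config, for the provenance block.
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full quantification pipeline on one or more annotation sets
#'
#' Each set is validated (all findings reported in batch before
#' aborting), aligned, and quantified: per-layer per-structure
#' fractionator population estimates with Gundersen CEs, Cavalieri layer
#' volumes, volume-adjusted layer densities, sulcal/gyral partition
#' densities (when a sulcus is annotated), perivascular vessel
#' association, and a pooled marker heatmap. Multiple sets are analysed
#' independently and concatenated into long-format tables.
#'
#' @param sets an [annotation_set()], a list of them, or a character
#'   vector of bundle directories for [load_annotation_set()].
#' @param config named list overriding the defaults: `unit_scale_layer`
#'   (`"per_cm3"`), `unit_scale_partition` (`"per_mm3"`),
#'   `heatmap_cell`/`heatmap_bandwidth` (µm), `heatmap_structure`,
#'   `vessel_threshold` (100 µm), `vessel_min_diameter` (30 µm),
#'   `vessel_structures` (`NULL` = pooled), `ce_limit` (0.15),
#'   `out_dir` (write CSV/JSON artifacts when set), `verbose`.
#' @return Object of class `report_bundle`: list with tibbles
#'   `layer_density`, `partition_density`, `vessel`, `ce` (flagged via
#'   [flag_high_ce()]), `comparisons`, a named `heatmaps` list, an
#'   `unassigned` tibble, and a `provenance` list.
#' @export
run_pipeline <- function(sets, config = list()) {
  cfg <- utils::modifyList(default_pipeline_config(), config)
  if (inherits(sets, "annotation_set")) sets <- list(sets)
  if (is.character(sets)) sets <- lapply(sets, load_annotation_set)
  say <- function(...) if (isTRUE(cfg$verbose)) message(sprintf(...))

  layer_rows <- list(); part_rows <- list(); vessel_rows <- list()
  ce_rows <- list(); heatmaps <- list(); unassigned_rows <- list()

  for (set in sets) {
    stopifnot(inherits(set, "annotation_set"))
    tag <- paste(set$subject_id, set$region, sep = "_")
    rep <- validate_annotation_set(set)
    if (!is_valid(rep)) {
      stop("stage validate: set ", tag, " failed with ", nrow(rep$errors),
           " error(s):\n",
           paste(sprintf("  [%s] %s (%s)", rep$errors$code,
                         rep$errors$message, rep$errors$id), collapse = "\n"))
    }
    say("validate: %s ok (%d markers, %d vessels)", tag,
        nrow(set$markers), nrow(set$vessels))
    aligned <- apply_alignment(set)
    design <- aligned$design
    assigned <- assign_markers_to_layers(aligned$markers, aligned$layers)
    unassigned_rows[[length(unassigned_rows) + 1L]] <- tibble::tibble(
      subject_id = set$subject_id, region = set$region,
      n_markers = nrow(assigned),
      n_unassigned = attr(assigned, "n_unassigned"))
    say("align+assign: %s, %d/%d markers in a layer", tag,
        nrow(assigned) - attr(assigned, "n_unassigned"), nrow(assigned))

    # layer-wise fractionator estimates, volumes and densities
    present_layers <- intersect(LAYER_LABELS, unique(aligned$layers$layer))
    for (lay in present_layers) {
      li <- which(aligned$layers$layer == lay)
      areas <- vapply(aligned$layers$polygon[li], polygon_area, numeric(1))
      names(areas) <- aligned$layers$section_id[li]
      vol <- cavalieri_volume(areas, design$section_period)
      if (!(vol$volume > 0)) next
      for (st in MARKER_STRUCTURES) {
        in_cell <- assigned$layer == lay & assigned$structure == st
        counts <- vapply(aligned$sections, function(sec) {
          sum(in_cell & assigned$section_id == sec)
        }, numeric(1))
        est <- fractionator_estimate(counts, design)
        layer_rows[[length(layer_rows) + 1L]] <- layer_density(
          est, vol, unit_scale = cfg$unit_scale_layer,
          subject_id = set$subject_id, region = set$region,
          partition_label = lay, structure = st)
        ce_rows[[length(ce_rows) + 1L]] <- tibble::tibble(
          subject_id = set$subject_id, region = set$region,
          layer = lay, structure = st,
          raw_count = est$raw_count, ce = est$ce)
      }
    }

    # sulcal/gyral partition densities
    if (nrow(aligned$sulci) > 0) {
      part <- partition_sulcal_gyral(aligned$markers, aligned$layers,
                                     aligned$sulci)
      for (st in MARKER_STRUCTURES) {
        part_rows[[length(part_rows) + 1L]] <- regional_density(
          part, design, structure = st,
          unit_scale = cfg$unit_scale_partition,
          subject_id = set$subject_id, region = set$region)
      }
      say("partition: %s sulcal area %.2f mm2", tag,
          sum(part$areas$sulcal_area) / 1e6)
    }

    # perivascular association
    if (nrow(aligned$vessels) > 0) {
      va <- vessel_association(aligned$markers, aligned$vessels,
                               threshold = cfg$vessel_threshold,
                               min_diameter = cfg$vessel_min_diameter,
                               structures = cfg$vessel_structures)
      vessel_rows[[length(vessel_rows) + 1L]] <- tibble::tibble(
        subject_id = set$subject_id, region = set$region,
        n_vessels = va$n_vessels, n_associated = va$n_associated,
        pct_associated = va$pct_associated,
        mean_distance = va$mean_distance,
        threshold = va$threshold, min_diameter = va$min_diameter)
      say("vessels: %s %d/%d associated", tag, va$n_associated, va$n_vessels)
    }

    heatmaps[[tag]] <- density_heatmap(aligned$markers,
                                       cell = cfg$heatmap_cell,
                                       bandwidth = cfg$heatmap_bandwidth,
                                       structure = cfg$heatmap_structure)
  }

  empty_density <- tibble::tibble(subject_id = character(), region = character(),
                                  partition_label = character(),
                                  structure = character(), density = numeric(),
                                  unit_scale = character(),
                                  population = numeric(), volume_um3 = numeric())
  layer_density_tab <- if (length(layer_rows)) dplyr::bind_rows(layer_rows) else empty_density
  bundle <- structure(list(
    layer_density = layer_density_tab,
    partition_density = if (length(part_rows)) dplyr::bind_rows(part_rows) else empty_density,
    vessel = if (length(vessel_rows)) dplyr::bind_rows(vessel_rows) else
      tibble::tibble(subject_id = character(), region = character(),
                     n_vessels = integer(), n_associated = integer(),
                     pct_associated = numeric(), mean_distance = numeric(),
                     threshold = numeric(), min_diameter = numeric()),
    ce = flag_high_ce(if (length(ce_rows)) dplyr::bind_rows(ce_rows) else
      tibble::tibble(subject_id = character(), region = character(),
                     layer = character(), structure = character(),
                     raw_count = numeric(), ce = numeric()),
      limit = cfg$ce_limit),
    comparisons = density_comparisons(layer_density_tab),
    heatmaps = heatmaps,
    unassigned = if (length(unassigned_rows)) dplyr::bind_rows(unassigned_rows) else
      tibble::tibble(subject_id = character(), region = character(),
                     n_markers = integer(), n_unassigned = integer()),
    provenance = list(package = "stereotau",
                      package_version = as.character(utils::packageVersion("stereotau")),
                      r_version = R.version.string,
                      config = cfg[setdiff(names(cfg), "out_dir")],
                      config_hash = config_hash(cfg[setdiff(names(cfg), "out_dir")]),
                      subjects = vapply(sets, function(s) s$subject_id, character(1)))),
    class = "report_bundle")

  if (!is.null(cfg$out_dir)) write_report_bundle(bundle, cfg$out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %d layer-density rows, %d partition rows, %d vessel summaries, %d heatmaps\n",
              nrow(x$layer_density), nrow(x$partition_density),
              nrow(x$vessel), length(x$heatmaps)))
  invisible(x)
}

#' Write a report bundle's tables to disk
#'
#' CSV tables plus long-format heatmap CSVs and a provenance JSON.
#' Re-running the pipeline on identical inputs reproduces the files
#' byte-for-byte (no timestamps are embedded).
#'
#' @param bundle a `report_bundle`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  w(bundle$layer_density, "layer_densities.csv")
  w(bundle$partition_density, "partition_densities.csv")
  w(bundle$vessel, "vessel_association.csv")
  w(bundle$ce, "ce_table.csv")
  w(bundle$comparisons, "comparisons.csv")
  w(bundle$unassigned, "unassigned_markers.csv")
  for (tag in names(bundle$heatmaps)) {
    hm <- bundle$heatmaps[[tag]]
    w(as.data.frame(hm, which = "counts"), paste0("heatmap_", tag, ".csv"))
  }
  jsonlite::write_json(bundle$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Flag imprecise population estimates
#'
#' Mirrors the conventional acceptability rule for the Gundersen CE:
#' rows at or above `limit`, or with an undefined CE (too few counts),
#' are flagged.
#'
#' @param ce_table tibble with a `ce` column (and any id columns).
#' @param limit CE acceptability limit as a proportion (default 0.15).
#' @return The table with logical `flagged` and character `reason`
#'   columns.
#' @export
flag_high_ce <- function(ce_table, limit = 0.15) {
  ce_table <- tibble::as_tibble(ce_table)
  ce_table$flagged <- is.na(ce_table$ce) | ce_table$ce >= limit
  ce_table$reason <- ifelse(is.na(ce_table$ce), "insufficient counts",
                            ifelse(ce_table$ce >= limit,
                                   sprintf("ce >= %g", limit), ""))
  ce_table
}

#' Pairwise density ratios between subjects
#'
#' For every region x layer x structure cell, the ratio of each ordered
#' pair of subjects' densities — the derived quantities behind
#' "x times more numerous" comparisons. Ratios with a zero denominator
#' are `Inf`; cells missing a subject are skipped.
#'
#' @param layer_density_table density tibble as produced by
#'   [run_pipeline()] (or [reference_layer_densities()]).
#' @return Tibble with `region`, `partition_label`, `structure`,
#'   `subject_num`, `subject_den`, `ratio`.
#' @export
density_comparisons <- function(layer_density_table) {
  tab <- tibble::as_tibble(layer_density_table)
  out <- list()
  cells <- unique(tab[, c("region", "partition_label", "structure")])
  for (i in seq_len(nrow(cells))) {
    sub <- tab[tab$region == cells$region[i] &
                 tab$partition_label == cells$partition_label[i] &
                 tab$structure == cells$structure[i], , drop = FALSE]
    subs <- unique(sub$subject_id)
    if (length(subs) < 2) next
    for (a in subs) for (b in subs) {
      if (a == b) next
      da <- sub$density[sub$subject_id == a][1]
      db <- sub$density[sub$subject_id == b][1]
      out[[length(out) + 1L]] <- tibble::tibble(
        region = cells$region[i], partition_label = cells$partition_label[i],
        structure = cells$structure[i],
        subject_num = a, subject_den = b,
        ratio = if (db == 0) Inf else da / db)
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(region = character(), partition_label = character(),
                          structure = character(), subject_num = character(),
                          subject_den = character(), ratio = numeric()))
  }
  dplyr::bind_rows(out)
}
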