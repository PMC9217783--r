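# Published reference measurements bundled as plain-text tables.

#' Reported layer densities of tau-immunoreactive structures in muskoxen
#'
#' Estimated population per cm³ of pSer202 tau-immunoreactive neuropil
#' threads, neuritic thread clusters and neurons, by cortical layer
#' (I, II, III, IV-VI, white matter) in prefrontal and parietal cortex of
#' three muskox specimens (old male, middle-aged female, old female).
#' The table feeds [density_comparisons()] for between-subject ratio
#' analyses; it is a reported reference, not a quantity this package
#' recomputes (that would require the original coordinate exports).
#'
#' @return Tibble with `subject_id`, `region`, `partition_label`,
#'   `structure`, `density`, `unit_scale`.
#' @export
reference_layer_densities <- function() {
  path <- system.file("extdata", "muskox_layer_densities.csv",
                      package = "stereotau", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path))
}

#' Reported perivascular association summaries
#'
#' Counts of vessels larger than 30 µm in diameter, the number and
#' percentage with a pSer202 tau-immunoreactive structure within 100 µm
#' of the vessel edge, and the mean vessel-tau edge distance, for the
#' three muskox specimens and a human chronic traumatic encephalopathy
#' comparison case. Note the old-male row is internally inconsistent
#' (8/190 = 4.21%, printed as 4.07%); it is carried as printed.
#'
#' @return Tibble with `subject_id`, `n_vessels`, `n_associated`,
#'   `pct_reported`, `mean_distance_um`.
#' @export
reference_vessel_summaries <- function() {
  path <- system.file("extdata", "muskox_vessel_association.csv",
                      package = "stereotau", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path))
}
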