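# In-code fixtures: tiny hand-built annotation sets.

square_ring <- function(x0, y0, w, h) {
  rbind(c(x0, y0), c(x0 + w, y0), c(x0 + w, y0 + h), c(x0, y0 + h))
}

# Two sections, five stacked layer bands each (1000 µm wide, 200 µm tall
# bands from the top down: I, II, III, IV-VI, WM), 5 markers per section,
# one vessel and one sulcus per section.
tiny_annotation_set <- function(markers = NULL) {
  sections <- c("s01", "s02")
  bands <- c("I", "II", "III", "IV-VI", "WM")
  layer_rows <- list()
  for (sec in sections) {
    for (b in seq_along(bands)) {
      layer_rows[[length(layer_rows) + 1L]] <- tibble::tibble(
        section_id = sec, layer = bands[b],
        polygon = list(list(square_ring(0, -200 * b, 1000, 200))))
    }
  }
  if (is.null(markers)) {
    markers <- tibble::tibble(
      section_id = rep(sections, each = 5),
      x = rep(c(100, 300, 500, 700, 900), 2),
      y = rep(c(-100, -300, -500, -700, -900), 2),
      structure = rep(c("neuropil_thread", "neuropil_thread",
                        "neuritic_thread_cluster", "neuron",
                        "neuropil_thread"), 2))
  }
  vessels <- tibble::tibble(section_id = sections, x = c(500, 400),
                            y = c(-500, -600), diameter = c(40, 60))
  sulci <- tibble::tibble(section_id = sections,
                          fundus_x = 500, fundus_y = -950,
                          mouth_ax = 200, mouth_ay = -10,
                          mouth_bx = 800, mouth_by = -10,
                          depth_fraction = 1 / 3)
  annotation_set(subject_id = "tiny", region = "prefrontal",
                 sections = sections, layers = dplyr::bind_rows(layer_rows),
                 markers = markers, vessels = vessels, sulci = sulci)
}

# Vessel fixture with an exact number of associated vessels: `n_assoc`
# vessels get a marker 40 µm from their edge, the rest have none nearby.
vessel_fixture <- function(n_vessels, n_assoc, diameter = 50) {
  stopifnot(n_assoc <= n_vessels)
  vx <- seq_len(n_vessels) * 1000
  vessels <- tibble::tibble(section_id = "s01", x = vx, y = 0,
                            diameter = diameter)
  markers <- tibble::tibble(section_id = "s01",
                            x = vx[seq_len(n_assoc)] + diameter / 2 + 40,
                            y = 0, structure = "neuropil_thread")
  list(markers = markers, vessels = vessels)
}
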