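test_that("markers are assigned to the containing layer", {
  set <- tiny_annotation_set()
  out <- assign_markers_to_layers(set$markers, set$layers)
  # fixture markers sit at the centroid of successive bands
  expect_equal(out$layer[1:5], c("I", "II", "III", "IV-VI", "WM"))
  expect_equal(attr(out, "n_unassigned"), 0)

  stray <- tibble::tibble(section_id = "s01", x = 5000, y = 5000,
                          structure = "neuron")
  out <- assign_markers_to_layers(stray, set$layers)
  expect_equal(out$layer, "unassigned")
  expect_equal(attr(out, "n_unassigned"), 1)
})

test_that("layer assignment matches the brute-force oracle on 1e4 points", {
  set <- tiny_annotation_set()
  layers1 <- set$layers[set$layers$section_id == "s01", ]
  set.seed(13)
  n <- 10000
  mk <- tibble::tibble(section_id = "s01",
                       x = runif(n, -100, 1100), y = runif(n, -1100, 100),
                       structure = "neuropil_thread")
  got <- assign_markers_to_layers(mk, layers1)$layer
  want <- rep("unassigned", n)
  for (i in seq_len(nrow(layers1))) {
    hit <- oracle_point_in_polygon(mk$x, mk$y, layers1$polygon[[i]])
    want[hit & want == "unassigned"] <- layers1$layer[i]
  }
  expect_identical(got, want)
})

test_that("sulcal partition applies the bottom-third rule", {
  # straight slot sulcus of depth 300 µm in a 1000 x 1000 ribbon
  layers <- tibble::tibble(
    section_id = "s01", layer = "I",
    polygon = list(list(square_ring(-500, -1000, 1000, 1000))))
  sulci <- tibble::tibble(section_id = "s01", fundus_x = 0, fundus_y = -900,
                          mouth_ax = -30, mouth_ay = -900 + sqrt(300^2 - 30^2),
                          mouth_bx = 30, mouth_by = -900 + sqrt(300^2 - 30^2),
                          depth_fraction = 1 / 3)
  mk <- tibble::tibble(section_id = "s01", x = c(0, 0), y = c(-850, -750),
                       structure = "neuropil_thread")
  part <- partition_sulcal_gyral(mk, layers, sulci, grey_layers = "I")
  # 50 µm from the fundus is sulcal (50 <= 100), 150 µm is gyral
  expect_equal(part$labels$label, c("sulcal", "gyral"))
  expect_equal(part$labels$distance_to_fundus, c(50, 150))

  # depth_fraction = 1: anything within the full depth is sulcal
  sulci$depth_fraction <- 1
  part <- partition_sulcal_gyral(mk, layers, sulci, grey_layers = "I")
  expect_equal(part$labels$label, c("sulcal", "sulcal"))

  # partition completeness: sulcal + gyral = all in-ribbon, disjoint by construction
  set.seed(21)
  mk2 <- tibble::tibble(section_id = "s01", x = runif(500, -600, 600),
                        y = runif(500, -1100, 100), structure = "neuron")
  sulci$depth_fraction <- 1 / 3
  part <- partition_sulcal_gyral(mk2, layers, sulci, grey_layers = "I")
  in_ribbon <- point_in_polygon(mk2$x, mk2$y, layers$polygon[[1]])
  expect_equal(sum(part$labels$label %in% c("sulcal", "gyral")), sum(in_ribbon))
  expect_equal(sum(part$labels$label == "unassigned"), sum(!in_ribbon))
})

test_that("sulcal compartment area matches a grid-integration oracle", {
  geom <- make_cortex_geometry(synthetic_params(seed = 2, n_sections = 1))
  part <- partition_sulcal_gyral(
    tibble::tibble(section_id = character(), x = numeric(), y = numeric(),
                   structure = character()),
    geom$layers, geom$sulci)
  s <- geom$sulci[1, ]
  radius <- s$depth_fraction * mean(c(
    sqrt((s$fundus_x - s$mouth_ax)^2 + (s$fundus_y - s$mouth_ay)^2),
    sqrt((s$fundus_x - s$mouth_bx)^2 + (s$fundus_y - s$mouth_by)^2)))
  grey <- geom$layers[geom$layers$layer != "WM", ]
  oracle <- sum(vapply(grey$polygon, function(p) {
    oracle_circle_polygon_area(p, c(s$fundus_x, s$fundus_y), radius, n_grid = 500)
  }, numeric(1)))
  expect_equal(sum(part$areas$sulcal_area), oracle, tolerance = 0.01)
})

test_that("regional densities follow the fractionator arithmetic chain", {
  d <- sampling_design()
  # 10 sulcal markers over 0.5 mm2 x 10 sections at 0.5 mm period
  part <- list(
    labels = tibble::tibble(label = c(rep("sulcal", 10), rep("gyral", 0)),
                            structure = "neuropil_thread"),
    areas = tibble::tibble(section_id = sprintf("s%02d", 1:10),
                           sulcal_area = 0.5e6, gyral_area = 1e6))
  dens <- regional_density(part, d, structure = "neuropil_thread")
  sul <- dens[dens$partition_label == "sulcal", ]
  expect_equal(sul$population, 10 * 10 * 15 / 11, tolerance = 1e-12)
  expect_equal(sul$volume_um3, 0.5e6 * 10 * 500)
  expect_equal(sul$density, (10 * 10 * 15 / 11) / 2.5, tolerance = 1e-12)
  # zero markers in a compartment give density 0
  expect_equal(dens$density[dens$partition_label == "gyral"], 0)

  # doubling all areas halves both densities
  part2 <- part
  part2$areas$sulcal_area <- part2$areas$sulcal_area * 2
  part2$areas$gyral_area <- part2$areas$gyral_area * 2
  dens2 <- regional_density(part2, d, structure = "neuropil_thread")
  expect_equal(dens2$density, dens$density / 2)

  part$areas$sulcal_area <- 0
  expect_error(regional_density(part, d), "zero sulcal area")
})

test_that("vessel association applies the diameter and distance rules", {
  fx <- vessel_fixture(10, 3)
  va <- vessel_association(fx$markers, fx$vessels)
  expect_equal(va$n_vessels, 10)
  expect_equal(va$n_associated, 3)
  expect_equal(va$pct_associated, 30)
  expect_equal(va$mean_distance, 40)

  # 25 µm vessel is excluded by the strict > 30 µm rule
  v <- tibble::tibble(section_id = "s01", x = 0, y = 0, diameter = 25)
  m <- tibble::tibble(section_id = "s01", x = 10, y = 0,
                      structure = "neuropil_thread")
  va <- vessel_association(m, v)
  expect_equal(va$n_vessels, 0)
  expect_true(is.na(va$pct_associated))

  # marker inside the lumen: edge distance floors at 0
  v$diameter <- 40
  va <- vessel_association(m, v)
  expect_equal(va$detail$edge_distance, 0)
  expect_equal(va$n_associated, 1)

  expect_error(vessel_association(m, dplyr::mutate(v, diameter = -1)), "positive")
})

test_that("vessel association matches the all-pairs oracle and is order-invariant", {
  set.seed(31)
  n <- 1000
  vessels <- tibble::tibble(section_id = sample(c("s01", "s02"), n, TRUE),
                            x = runif(n, 0, 5000), y = runif(n, 0, 5000),
                            diameter = rlnorm(n, log(35), 0.5))
  markers <- tibble::tibble(section_id = sample(c("s01", "s02"), n, TRUE),
                            x = runif(n, 0, 5000), y = runif(n, 0, 5000),
                            structure = "neuropil_thread")
  va <- vessel_association(markers, vessels)
  or <- oracle_vessel_association(markers, vessels)
  expect_equal(va$n_vessels, or$n_vessels)
  expect_equal(va$n_associated, or$n_associated)
  expect_equal(va$pct_associated, or$pct)
  expect_equal(va$mean_distance, or$mean_distance)

  perm_m <- markers[sample(n), ]
  perm_v <- vessels[sample(n), ]
  va2 <- vessel_association(perm_m, perm_v)
  expect_equal(va2$n_associated, va$n_associated)
  expect_equal(va2$pct_associated, va$pct_associated)
  expect_equal(va2$mean_distance, va$mean_distance)
})

test_that("heatmaps conserve marker counts and respect rigid alignment", {
  one <- tibble::tibble(section_id = "s01", x = 333, y = -777,
                        structure = "neuropil_thread")
  hm <- density_heatmap(one, cell = 250)
  expect_equal(sum(hm$counts), 1)
  expect_equal(sum(hm$counts == 1), 1)

  set.seed(41)
  mk <- tibble::tibble(section_id = "s01", x = runif(500, 0, 2000),
                       y = runif(500, 0, 1000), structure = "neuropil_thread")
  hm <- density_heatmap(mk, cell = 250)
  expect_equal(sum(hm$counts), 500)
  expect_equal(sum(hm$smoothed), 500, tolerance = 1e-6)

  # translating markers and origin together leaves the counts unchanged
  hm2 <- density_heatmap(dplyr::mutate(mk, x = x + 12345, y = y - 999),
                         cell = 250,
                         origin = hm$origin + c(12345, -999))
  expect_identical(hm2$counts, hm$counts)

  expect_error(density_heatmap(mk, cell = 0), "positive")
})

test_that("uniform markers produce uniform heatmap bins", {
  # chi-square uniformity on interior bins, many seeded runs
  rejected <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    mk <- tibble::tibble(section_id = "s01", x = runif(4000, 0, 2000),
                         y = runif(4000, 0, 2000), structure = "neuropil_thread")
    hm <- density_heatmap(mk, cell = 250, bandwidth = NULL,
                          origin = c(0, 0))
    counts <- as.vector(hm$counts[1:8, 1:8])
    p <- stats::chisq.test(counts)$p.value
    if (p < 0.001) rejected <- rejected + 1L
  }
  expect_lte(rejected, 1L)  # >= 95% of runs not rejected
})
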