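test_that("sampling fractions follow the design", {
  d <- sampling_design()  # 50 µm cut / 500 µm period, 100% grid, 11/15 µm
  fr <- sampling_fractions(d)
  expect_equal(unname(fr), c(0.1, 1, 11 / 15))

  exhaustive <- sampling_design(cut_thickness = 500, section_period = 500,
                                mounted_thickness = 500,
                                dissector_height = 500, guard_top = 0,
                                guard_bottom = 0)
  expect_equal(unname(sampling_fractions(exhaustive)), c(1, 1, 1))

  expect_equal(sampling_fractions(sampling_design(grid_fraction = 0.25))[["asf"]],
               0.25)
})

test_that("inadmissible designs are rejected", {
  expect_error(sampling_design(dissector_height = 14), "guard")
  expect_error(sampling_design(mounted_thickness = 60), "cut thickness")
  expect_error(sampling_design(section_period = 40), "period")
  expect_error(sampling_design(grid_fraction = 0), "grid_fraction")
  expect_error(sampling_design(grid_fraction = 1.5), "grid_fraction")
})

test_that("fractionator estimate scales raw counts by inverse fractions", {
  d <- sampling_design()
  expect_equal(fractionator_estimate(rep(0, 10), d)$estimate, 0)
  est <- fractionator_estimate(c(10, 5, 5, 10, 5, 5, 5, 5, 0, 0), d)
  expect_equal(est$raw_count, 50)
  expect_equal(est$estimate, 50 * 10 * 15 / 11)
  expect_error(fractionator_estimate(c(3, -1), d), "non-negative")
  expect_error(fractionator_estimate(numeric(0), d), "at least one")

  # monotone: adding a marker to any section never decreases the estimate
  set.seed(1)
  for (rep in 1:20) {
    q <- rpois(10, 4)
    i <- sample(10, 1)
    q2 <- q; q2[i] <- q2[i] + 1
    expect_gte(fractionator_estimate(q2, d)$estimate,
               fractionator_estimate(q, d)$estimate)
  }
})

test_that("Gundersen CE matches hand evaluations and handles edge cases", {
  # flat series: smoothness variance clamps to zero, noise term remains
  expect_equal(gundersen_ce(rep(5, 10), m = 1), sqrt(50) / 50, tolerance = 1e-14)
  expect_equal(gundersen_ce(rep(1, 100), m = 1), 0.1, tolerance = 1e-14)
  expect_true(is.na(gundersen_ce(c(0, 0, 0))))
  expect_true(is.na(gundersen_ce(c(5, 5))))
  expect_error(gundersen_ce(c(1, -2, 3)), "non-negative")

  # direct re-evaluation of the variance formula, both smoothness classes
  ce_direct <- function(q, denom) {
    A <- sum(q^2); B <- sum(q[-length(q)] * q[-1])
    C <- sum(q[1:(length(q) - 2)] * q[-(1:2)])
    n <- sum(q)
    sqrt(n + max(0, (3 * (A - n) - 4 * B + C) / denom)) / n
  }
  set.seed(3)
  for (rep in 1:20) {
    q <- rpois(10, 20)
    if (sum(q) == 0) next
    expect_equal(gundersen_ce(q, m = 1), ce_direct(q, 240))
    expect_equal(gundersen_ce(q, m = 0), ce_direct(q, 12))
    # scale invariance enters only through the noise term, as the formula says
    k <- sample(2:9, 1)
    expect_equal(gundersen_ce(k * q, m = 1), ce_direct(k * q, 240))
  }
})

test_that("Cavalieri volumes are summed areas times spacing", {
  v <- cavalieri_volume(rep(1e6, 10), 500)
  expect_equal(v$volume, 5e9)   # ten 1 mm2 sections every 500 µm = 5 mm3
  expect_equal(cavalieri_volume(12345, 500)$volume, 12345 * 500)
  expect_error(cavalieri_volume(numeric(0), 500), "at least one")
  expect_error(cavalieri_volume(1e6, 0), "positive")

  # cylinder along the sectioning axis as a closed-form solid
  r <- 5000; len <- 10000; spacing <- 500
  set.seed(5)
  offset <- runif(1, 0, spacing)
  z <- seq(offset, len, by = spacing)
  areas <- rep(pi * r^2, length(z))
  expect_equal(cavalieri_volume(areas, spacing)$volume, pi * r^2 * len,
               tolerance = 0.05)
})

test_that("density records convert volumes and units correctly", {
  d <- sampling_design()
  est <- fractionator_estimate(c(10, 5, 5, 10, 5, 5, 5, 5, 0, 0), d)
  vol <- cavalieri_volume(rep(1e6, 10), 500)  # 5 mm3
  row <- layer_density(est, vol, unit_scale = "per_mm3")
  expect_equal(row$density, est$estimate / 5, tolerance = 1e-12)
  row_cm <- layer_density(est, vol, unit_scale = "per_cm3")
  expect_equal(row_cm$density, 1000 * row$density)
  expect_equal(layer_density(0, vol)$density, 0)
  expect_error(layer_density(est, 0), "positive")
})

test_that("dissector window and counting frame subsample as designed", {
  d <- sampling_design()
  # particles dead-centre in a section's dissector window are counted
  z <- c(25, 525, 1025)  # mid-section for phase 0
  expect_equal(sum(section_dissector_counts(z, d, phase = 0)), 3)
  # particles inside a guard zone are not
  zg <- 50 * 1 / 15  # mounted depth 1 µm < 2 µm top guard
  expect_equal(sum(section_dissector_counts(zg, d, phase = 0)), 0)
  # particles between sections are not
  expect_equal(sum(section_dissector_counts(250, d, phase = 0)), 0)

  # frame subsampling: exhaustive grid counts everything
  set.seed(11)
  xy <- cbind(runif(5000, 0, 7000), runif(5000, 0, 7000))
  expect_true(all(frame_counted(xy, d)))
  # quarter grid counts about a quarter, with forbidden-edge handling
  d4 <- sampling_design(grid_fraction = 0.25)
  frac <- mean(frame_counted(xy, d4))
  expect_equal(frac, 0.25, tolerance = 0.1)
  # inclusion edge counted, forbidden edge excluded
  expect_true(frame_counted(rbind(c(0, 0)), d4))
  expect_false(frame_counted(rbind(c(700, 0)), d4))
})
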