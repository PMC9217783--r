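test_that("a bundle round-trips through write and load", {
  set <- tiny_annotation_set()
  dir <- withr::local_tempdir()
  write_annotation_set(set, dir)
  back <- load_annotation_set(dir)
  expect_equal(back$subject_id, set$subject_id)
  expect_equal(back$region, set$region)
  expect_equal(back$sections, set$sections)
  expect_equal(back$markers, set$markers)
  expect_equal(back$vessels, set$vessels)
  expect_equal(back$sulci, set$sulci, tolerance = 1e-12)
  expect_equal(unclass(back$design), unclass(set$design))
  expect_equal(nrow(back$layers), nrow(set$layers))
  for (i in seq_len(nrow(set$layers))) {
    expect_equal(back$layers$polygon[[i]], set$layers$polygon[[i]],
                 tolerance = 1e-12)
  }
  # writing the loaded set again reproduces the files byte-for-byte
  dir2 <- withr::local_tempdir()
  write_annotation_set(back, dir2)
  for (f in list.files(dir)) {
    expect_identical(readLines(file.path(dir2, f)), readLines(file.path(dir, f)),
                     label = f)
  }
})

test_that("loading handles fixture shape, empty markers and bad labels", {
  set <- tiny_annotation_set()
  dir <- withr::local_tempdir()
  write_annotation_set(set, dir)
  back <- load_annotation_set(dir)
  expect_equal(length(back$sections), 2)
  expect_equal(nrow(back$layers), 10)
  expect_equal(nrow(back$markers), 10)

  # empty marker table loads as a valid, marker-free set
  empty <- tiny_annotation_set(markers = tibble::tibble(
    section_id = character(), x = numeric(), y = numeric(),
    structure = character()))
  dir2 <- withr::local_tempdir()
  write_annotation_set(empty, dir2)
  back2 <- load_annotation_set(dir2)
  expect_equal(nrow(back2$markers), 0)
  expect_true(is_valid(validate_annotation_set(back2)))

  # unknown structure label is rejected with the label named
  m <- set$markers
  m$structure[3] <- "axon"
  dir3 <- withr::local_tempdir()
  write_annotation_set(tiny_annotation_set(markers = m), dir3)
  expect_error(load_annotation_set(dir3), "axon")

  expect_error(load_annotation_set(withr::local_tempdir()), "missing")
})

test_that("validation reports typed findings for constructed violations", {
  expect_true(is_valid(validate_annotation_set(tiny_annotation_set())))

  set <- tiny_annotation_set()
  # 50%-overlapping layer polygons
  set$layers$polygon[[2]] <- list(square_ring(0, -300, 1000, 200))
  rep <- validate_annotation_set(set)
  expect_true("LAYER_OVERLAP" %in% rep$errors$code)

  set <- tiny_annotation_set()
  set$vessels$diameter[1] <- -5
  rep <- validate_annotation_set(set)
  expect_true("BAD_DIAMETER" %in% rep$errors$code)

  set <- tiny_annotation_set()
  set$markers$section_id[1] <- "s99"
  rep <- validate_annotation_set(set)
  expect_true("UNKNOWN_SECTION" %in% rep$errors$code)

  set <- tiny_annotation_set()
  set$markers$structure[2] <- "plaque"
  rep <- validate_annotation_set(set)
  expect_true("BAD_STRUCTURE" %in% rep$errors$code)

  set <- tiny_annotation_set()
  set$sulci$depth_fraction[1] <- 2
  rep <- validate_annotation_set(set)
  expect_true("BAD_DEPTH_FRACTION" %in% rep$errors$code)

  set <- tiny_annotation_set()
  set$transforms$a[1] <- 0; set$transforms$d[1] <- 0
  set$transforms$b[1] <- 0; set$transforms$c[1] <- 0
  rep <- validate_annotation_set(set)
  expect_true("SINGULAR_TRANSFORM" %in% rep$errors$code)

  # findings are deterministically ordered
  rep2 <- validate_annotation_set(set)
  expect_identical(rep$errors, rep2$errors)
})

test_that("alignment applies per-section affines exactly", {
  set <- tiny_annotation_set()
  # identity is the identity
  out <- apply_alignment(set)
  expect_equal(out$markers, set$markers)
  expect_equal(out$layers$polygon, set$layers$polygon)

  # pure translation on one section shifts exactly that section
  set$transforms$tx[set$transforms$section_id == "s02"] <- 100
  set$transforms$ty[set$transforms$section_id == "s02"] <- -50
  out <- apply_alignment(set)
  s1 <- set$markers$section_id == "s01"
  expect_equal(out$markers$x[s1], set$markers$x[s1])
  expect_equal(out$markers$x[!s1], set$markers$x[!s1] + 100)
  expect_equal(out$markers$y[!s1], set$markers$y[!s1] - 50)
  # vessel diameters untouched by a rigid motion
  expect_equal(out$vessels$diameter, set$vessels$diameter)

  # rotation by 90 degrees about the origin: (10, 0) -> (0, 10)
  set <- tiny_annotation_set(markers = tibble::tibble(
    section_id = "s01", x = 10, y = 0, structure = "neuron"))
  set$transforms[set$transforms$section_id == "s01",
                 c("a", "b", "c", "d")] <- list(0, -1, 1, 0)
  out <- apply_alignment(set)
  expect_equal(c(out$markers$x, out$markers$y), c(0, 10), tolerance = 1e-12)

  # missing transform is an error naming the section
  set <- tiny_annotation_set()
  set$transforms <- set$transforms[-2, ]
  expect_error(apply_alignment(set), "s02")
})
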