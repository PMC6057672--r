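test_that("a fixture raster with five disjoint coccoliths yields five retained masks", {
  set.seed(31)
  img <- render_plm(sample_shapes(5, "A2"), width = 600, height = 600)
  seg <- segment_particles(img)
  expect_identical(sum(seg$particles$retained), 5L)
  expect_true(all(seg$particles$isolated))
})

test_that("a border-touching coccolith is flagged and excluded", {
  set.seed(32)
  sh <- sample_shapes(1, "A2")
  img <- render_plm(sh, optics = quiet_optics(), width = 200, height = 200,
                    positions = tibble::tibble(x_um = 0.5, y_um = 5))
  seg <- segment_particles(img)
  expect_identical(sum(seg$particles$retained), 0L)
  expect_true(any(seg$particles$touching_border))
})

test_that("hull-overlapping particles are flagged not-isolated", {
  # a particle lodged inside the concavity of an L-shaped neighbour: two
  # disjoint connected components whose convex hulls intersect
  raster <- matrix(400, 64, 64)
  raster[10:40, 10:14] <- 20000
  raster[36:40, 10:40] <- 20000          # the L
  raster[15:25, 22:32] <- 20000          # block inside the L's hull
  img <- structure(list(raster = raster, optics = quiet_optics(),
                        ground_truth = tibble::tibble()),
                   class = "plm_image")
  seg <- segment_particles(img, threshold_policy = "fixed",
                           threshold_value = 10000)
  expect_identical(nrow(seg$particles), 2L)
  expect_true(all(!seg$particles$isolated))
  expect_identical(sum(seg$particles$retained), 0L)
})

test_that("a blank raster segments to an empty particle list", {
  img <- render_plm(sample_shapes(0, "A1"), optics = quiet_optics(),
                    width = 64, height = 64)
  seg <- segment_particles(img, threshold_policy = "fixed",
                           threshold_value = 1000)
  expect_identical(nrow(seg$particles), 0L)
  expect_identical(nrow(measure_particles(seg, img)), 0L)
})

test_that("an all-saturated raster is rejected as uncalibratable", {
  img <- render_plm(sample_shapes(0, "A1"),
                    optics = plm_optics(background_level = 65535, noise_sd = 0),
                    width = 32, height = 32)
  expect_error(segment_particles(img), "saturated")
})

test_that("segmentation is idempotent: same raster, same masks", {
  set.seed(34)
  img <- render_plm(sample_shapes(4, "A3a"), width = 550, height = 550)
  s1 <- segment_particles(img)
  s2 <- segment_particles(img)
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$particles, s2$particles)
})

test_that("a rendered uniform disc measures its diameter within one pixel", {
  d_um <- 3
  img <- render_plm(disc_shape(d_um, t = 0.5), optics = quiet_optics(),
                    width = 128, height = 128,
                    positions = tibble::tibble(x_um = 3.2, y_um = 3.2))
  m <- measure_plm(img)
  expect_equal(m$apparent_length_um, d_um, tolerance = 0.05 / d_um)
})

test_that("measured mass tracks ground truth within 2% on rendered coccoliths", {
  set.seed(35)
  img <- render_plm(sample_shapes(5, "A2"), width = 600, height = 600)
  m <- match_ground_truth(measure_plm(img), img)
  expect_identical(nrow(m), 5L)
  expect_lt(median(abs(m$mass_pg - m$true_mass) / m$true_mass), 0.02)
})

test_that("the dim distal shield makes apparent length underestimate DSL", {
  set.seed(36)
  img <- render_plm(sample_shapes(5, "A1"), width = 600, height = 600)
  m <- match_ground_truth(measure_plm(img), img)
  expect_true(all(m$apparent_length_um < m$distal_shield_length))
})

test_that("mass is invariant to a joint rescaling of gain and grey", {
  # doubling grey_gain doubles recorded grey above background; the
  # thickness estimate, hence the mass, must not change
  set.seed(37)
  sh <- sample_shapes(3, "A2")
  img1 <- render_plm(sh, optics = quiet_optics(grey_gain = 19000),
                     width = 500, height = 500)
  set.seed(37)
  sh2 <- sample_shapes(3, "A2")
  img2 <- render_plm(sh2, optics = quiet_optics(grey_gain = 38000),
                     width = 500, height = 500)
  m1 <- measure_plm(img1, threshold_policy = "fixed", threshold_value = 6000)
  m2 <- measure_plm(img2, threshold_policy = "fixed", threshold_value = 11600)
  expect_equal(sort(m1$mass_pg), sort(m2$mass_pg), tolerance = 1e-3)
})

test_that("SEM-style measurement derives the central-area + tube length", {
  rec <- tibble::tibble(distal_shield_length = 3.5, tube_width = 0.5,
                        slit_length = 0.4, central_area_closure = 0.2)
  m <- measure_sem(rec)
  expect_equal(m$ca_tube_length, 3.5 - 2 * 0.4)
  expect_equal(m$total_length, 3.5)

  rec$slit_length <- 0
  expect_equal(measure_sem(rec)$ca_tube_length, 3.5)

  bad <- tibble::tibble(distal_shield_length = 1.0, tube_width = 0.2,
                        slit_length = 0.6, central_area_closure = 0.2)
  expect_error(measure_sem(bad), "negative")
})
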