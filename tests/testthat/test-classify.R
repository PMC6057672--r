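test_that("the four canonical variety calls are reproduced", {
  m <- tibble::tibble(
    slit_length = c(1.3, 1.0, 0.7, 0.7),
    tube_width = c(1.0, 1.0, 1.0, 1.0),
    central_area_closure = c(0.1, 0.1, 0.95, 0.1)
  )
  out <- classify_varieties(m, classification_policy(epsilon = 0.1))
  expect_identical(as.character(out$variety), c("A1", "A2", "A3a", "A3b"))
})

test_that("closure precedence: a closed central area overrides SL/TW", {
  # SL far above TW would read A1, but the closed centre decides
  m <- tibble::tibble(slit_length = 2, tube_width = 0.5,
                      central_area_closure = 0.9)
  expect_identical(as.character(classify_varieties(m)$variety), "A3a")
})

test_that("band edges resolve to the middle class", {
  pol <- classification_policy(epsilon = 0.1)
  m <- tibble::tibble(slit_length = c(1.1, 0.9), tube_width = 1,
                      central_area_closure = 0.2)
  expect_identical(as.character(classify_varieties(m, pol)$variety),
                   c("A2", "A2"))
})

test_that("classification partitions any valid measurement space", {
  # exclusive and exhaustive over randomized inputs, against an
  # independently restated rule
  set.seed(51)
  pol <- classification_policy(epsilon = 0.12, closure_cut = 0.8)
  m <- tibble::tibble(
    slit_length = runif(500, 0, 2),
    tube_width = runif(500, 0.05, 1.5),
    central_area_closure = runif(500)
  )
  got <- as.character(classify_varieties(m, pol)$variety)
  expect_false(anyNA(got))
  expected <- ifelse(m$central_area_closure >= 0.8, "A3a",
              ifelse(m$slit_length > m$tube_width * 1.12, "A1",
              ifelse(m$slit_length < m$tube_width * 0.88, "A3b", "A2")))
  expect_identical(got, expected)
})

test_that("generator-labelled coccoliths are recovered at >= 99%", {
  set.seed(52)
  p <- variety_params(margin = 0.15)
  shapes <- purrr::map_dfr(c("A1", "A2", "A3a", "A3b"),
                           function(v) sample_shapes(250, v, p))
  sem <- measure_sem(shapes, noise_sd = 0)
  got <- classify_varieties(sem, classification_policy(epsilon = 0.15))
  expect_gte(mean(as.character(got$variety) == shapes$variety), 0.99)
})

test_that("invalid tube widths and empty samples are rejected", {
  expect_error(classify_varieties(
    tibble::tibble(slit_length = 1, tube_width = 0,
                   central_area_closure = 0.2)),
    "tube width")
  # closed centre makes the SL/TW ratio irrelevant, so TW = 0 is tolerable
  ok <- classify_varieties(
    tibble::tibble(slit_length = 1, tube_width = 0,
                   central_area_closure = 0.9))
  expect_identical(as.character(ok$variety), "A3a")
  expect_error(tabulate_varieties(character()), "empty")
})

test_that("variety percentages are over Type A only and sum to 100", {
  tab <- tabulate_varieties(rep(c("A1", "A2", "A3b"), c(30, 54, 16)))
  expect_equal(tab$percent, c(30, 54, 0, 16))
  expect_equal(sum(tab$percent), 100, tolerance = 1e-9)
  expect_identical(attr(tab, "n_total"), 100L)

  all_a2 <- tabulate_varieties(rep("A2", 7))
  expect_equal(all_a2$percent[all_a2$variety == "A2"], 100)
  expect_error(tabulate_varieties(c("A1", "BC")), "outside")
})
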