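test_that("noiseless calibration pairs are fitted to machine precision", {
  x <- seq(2, 6, by = 0.5)
  fit <- fit_length_correction(
    tibble::tibble(apparent_length = x,
                   sem_total_length = 0.585 * x + 0.4537))
  expect_equal(fit$slope, 0.585, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.4537, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  ident <- fit_length_correction(
    tibble::tibble(apparent_length = x, sem_total_length = x))
  expect_equal(ident$slope, 1, tolerance = 1e-12)
  expect_equal(ident$intercept, 0, tolerance = 1e-12)
})

test_that("degenerate calibration inputs are rejected", {
  expect_error(fit_length_correction(
    tibble::tibble(apparent_length = 3, sem_total_length = 3.5)),
    "At least 2")
  expect_error(fit_length_correction(
    tibble::tibble(apparent_length = c(3, 3, 3),
                   sem_total_length = c(3.1, 3.2, 3.3))),
    "identical")
})

test_that("calibration refit recovers generating coefficients within 3 SE", {
  set.seed(41)
  x <- runif(500, 3, 6)
  y <- 0.585 * x + 0.4537 + rnorm(500, 0, 0.02)
  fit <- fit_length_correction(
    tibble::tibble(apparent_length = x, sem_total_length = y))
  se <- tidy(fit)$std.error
  expect_lt(abs(fit$slope - 0.585), 3 * se[2])
  expect_lt(abs(fit$intercept - 0.4537), 3 * se[1])
})

test_that("length correction applies the linear model and flags misuse", {
  expect_equal(correct_length(3.0), 0.585 * 3 + 0.4537)  # 2.2087
  ident <- fit_length_correction(
    tibble::tibble(apparent_length = 1:5, sem_total_length = 1:5))
  expect_equal(correct_length(2.7, ident), 2.7)
  expect_error(correct_length(0), "positive")
  down <- fit_length_correction(
    tibble::tibble(apparent_length = c(1, 2), sem_total_length = c(-1, -2)))
  expect_warning(res <- correct_length(1.5, down), "non-positive")
  expect_true(is.na(res))
})

test_that("normalized mass follows k_s * L^3 * rho_c", {
  expect_equal(normalized_mass(3.45), 0.02 * 3.45^3 * 2.7)  # 2.2174 pg
  expect_equal(normalized_mass(1), 0.054)
  expect_error(normalized_mass(-1), "positive")
  expect_equal(normalized_mass(2, calcite_constants(k_s = 0.05, rho_c = 2)),
               0.05 * 8 * 2)
})

test_that("the calcification index reproduces the worked province values", {
  expect_equal(calcification_index(4.76, 3.45), 2.14, tolerance = 0.02)
  expect_equal(calcification_index(3.77, 3.25), 2.01, tolerance = 0.02)
  # a population at exactly the normalized mass indexes to 1
  expect_equal(calcification_index(normalized_mass(3.2), 3.2), 1.0)
  expect_error(calcification_index(-1, 3), "positive")
})

test_that("the index is scale invariant for geometrically similar coccoliths", {
  # mass proportional to length cubed: the index must not depend on size
  lengths <- seq(2, 5, by = 0.5)
  masses <- 0.045 * lengths^3
  ci <- calcification_index(masses, lengths)
  expect_equal(ci, rep(ci[1], length(ci)), tolerance = 1e-12)
})

test_that("the index is monotone in mass and antitone in length", {
  expect_true(all(diff(calcification_index(seq(2, 6, 0.5), 3.3)) > 0))
  expect_true(all(diff(calcification_index(4, seq(2.5, 4, 0.25))) < 0))
})
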