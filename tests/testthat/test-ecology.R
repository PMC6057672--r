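test_that("sample summaries aggregate retained coccoliths correctly", {
  particles <- tibble::tibble(
    station = c(1, 1, 1, 2), depth_m = 25,
    mass_pg = c(3, 4, 5, 6), apparent_length_um = c(2.8, 3.0, 3.2, 3.4),
    retained = c(TRUE, TRUE, FALSE, TRUE)
  )
  s <- summarize_samples(particles)
  expect_identical(nrow(s), 2L)
  expect_equal(s$m_s_pg, c(3.5, 6))
  expect_equal(s$l_c_um[1], 0.585 * 2.9 + 0.4537)
  expect_equal(s$c_i, s$m_s_pg / (0.02 * s$l_c_um^3 * 2.7))

  single <- summarize_samples(particles[4, ])
  expect_equal(single$m_s_pg, 6)

  none <- dplyr::mutate(particles, retained = FALSE)
  expect_error(summarize_samples(none), "No retained")
})

test_that("summary mean mass sits within 3 SE of the generator mean", {
  set.seed(71)
  sh <- sample_shapes(400, "A2")
  plm <- emulate_plm_measurements(dplyr::mutate(sh, station = 1, depth_m = 25))
  s <- summarize_samples(plm)
  se <- sd(plm$mass_pg) / sqrt(nrow(plm))
  expect_lt(abs(s$m_s_pg - mean(sh$true_mass)), 3 * se + 0.03 * mean(sh$true_mass))
})

test_that("spearman handles perfect monotone association and ties", {
  x <- 1:8
  expect_equal(spearman_cor(x, 2 * x + 3)$rho, 1.0)
  expect_equal(spearman_cor(x, rev(x))$rho, -1.0)

  # tie-corrected rho against an explicit midrank Pearson oracle
  xt <- c(1, 2, 2, 3, 4, 4)
  yt <- c(5, 5, 6, 7, 7, 8)
  rx <- c(1, 2.5, 2.5, 4, 5.5, 5.5)   # midranks written out by hand
  ry <- c(1.5, 1.5, 3, 4.5, 4.5, 6)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_cor(xt, yt)$rho, oracle, tolerance = 1e-12)
  expect_equal(spearman_cor(xt, yt)$rho,
               cor(xt, yt, method = "spearman"), tolerance = 1e-12)
})

test_that("small-sample p-values are exact permutation probabilities", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  res <- spearman_cor(x, y)
  # brute-force oracle: enumerate all 120 orderings of y
  perms <- coccolithr:::permutations_all(5)
  rhos <- apply(perms, 1, function(p) cor(x, y[p], method = "spearman"))
  expect_equal(res$p_value, mean(abs(rhos) >= abs(res$rho) - 1e-12),
               tolerance = 1e-12)
  # a perfect ranking has permutation probability 2/n! two-sided
  expect_equal(spearman_cor(x, x)$p_value, 2 / factorial(5), tolerance = 1e-12)
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(72)
  x <- rnorm(15); y <- rnorm(15)
  base <- spearman_cor(x, y)
  expect_equal(spearman_cor(exp(x), y)$rho, base$rho, tolerance = 1e-12)
  expect_equal(spearman_cor(x, y^3 + 5 * y)$rho, base$rho, tolerance = 1e-12)
  expect_equal(spearman_cor(rank(x), y)$p_value, base$p_value,
               tolerance = 1e-12)
})

test_that("constant inputs yield an undefined, flagged correlation", {
  res <- spearman_cor(rep(1, 6), 1:6)
  expect_true(is.na(res$rho))
  expect_true(is.na(res$significant))
})

test_that("the significance flag and stars follow the p-value", {
  set.seed(73)
  d <- tibble::tibble(a = 1:12, b = (1:12) + rnorm(12, 0, 0.1), c = rnorm(12))
  out <- spearman_battery(d, "a", c("b", "c"))
  expect_identical(out$significant, out$p_value <= 0.05)
  expect_identical(out$stars[out$p_value <= 0.01], "**")
  adj <- spearman_battery(d, "a", c("b", "c"), adjust = "BH")
  expect_true(all(adj$p_value >= out$p_value - 1e-15))
})

test_that("cca eigenvalues match a brute-force constrained-CA oracle", {
  set.seed(74)
  Y <- matrix(rpois(12, 8) + 1, 4, 3,
              dimnames = list(paste0("s", 1:4), paste0("t", 1:3)))
  E <- data.frame(e1 = rnorm(4), e2 = runif(4))

  # explicit construction: chi-square residuals, row-weighted projection
  # onto the predictors, eigen-decomposition of the fitted matrix
  P <- Y / sum(Y)
  r <- rowSums(P); cc <- colSums(P)
  Qbar <- (P - r %o% cc) / sqrt(r %o% cc)
  Es <- scale(as.matrix(E))
  Ec <- sweep(Es, 2, colSums(Es * r), "-")
  Z <- sqrt(r) * Ec
  H <- Z %*% solve(crossprod(Z)) %*% t(Z)
  ev <- eigen(crossprod(H %*% Qbar), symmetric = TRUE)$values
  ev <- ev[ev > 1e-12]

  res <- cca_ordination(Y, E)
  expect_equal(res$eigenvalues, ev, tolerance = 1e-10)
  expect_equal(sum(res$percent_constrained), 100, tolerance = 1e-9)
})

test_that("cca eigenvalue structure is valid and order-invariant", {
  set.seed(75)
  Y <- matrix(rpois(30, 6) + 1, 6, 5)
  E <- data.frame(a = rnorm(6), b = runif(6), c = rnorm(6))
  res <- cca_ordination(Y, E)
  expect_true(all(res$eigenvalues >= 0 & res$eigenvalues <= 1))
  expect_true(all(diff(res$eigenvalues) <= 1e-12))
  expect_true(all(abs(res$env_axis_scores) <= 1 + 1e-10))

  perm <- sample(6)
  res_p <- cca_ordination(Y[perm, ], E[perm, , drop = FALSE])
  expect_equal(res_p$eigenvalues, res$eigenvalues, tolerance = 1e-10)
})

test_that("a single constraining variable carries all constrained inertia", {
  set.seed(76)
  Y <- matrix(rpois(20, 5) + 1, 5, 4)
  E <- data.frame(grad = 1:5)
  res <- cca_ordination(Y, E)
  expect_identical(length(res$eigenvalues), 1L)
  expect_equal(res$percent_constrained, 100)
})

test_that("duplicated environmental columns are dropped, results unchanged", {
  set.seed(77)
  Y <- matrix(rpois(20, 5) + 1, 5, 4)
  E1 <- data.frame(grad = c(2, 5, 1, 4, 3))
  E2 <- data.frame(grad = E1$grad, dup = 2 * E1$grad + 1)
  expect_warning(res2 <- cca_ordination(Y, E2), "collinear")
  res1 <- cca_ordination(Y, E1)
  expect_equal(res2$eigenvalues, res1$eigenvalues, tolerance = 1e-10)
})

test_that("all-zero rows are removed with a warning", {
  Y <- rbind(matrix(rpois(12, 5) + 1, 3, 4), 0)
  E <- data.frame(g = 1:4)
  expect_warning(res <- cca_ordination(Y, E), "all-zero")
  expect_identical(nrow(res$site_scores), 3L)
})
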