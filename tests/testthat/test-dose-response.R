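test_that("concentration grids are vehicle-anchored 1:2 series with mid-range IC50", {
  g <- concentration_grid(-6)
  expect_length(g, 10)
  expect_equal(g[1], 0)
  expect_equal(g[-1][-1] / g[-1][-9], rep(2, 8)) # geometric, ratio 2
  expect_equal(g[10] / g[2], 2^8) # 256-fold span
  expect_equal(sqrt(g[6] * g[7]), 1e-6) # IC50 between doses 5 and 6
  expect_error(concentration_grid(-6, dilution = 1))
  expect_error(concentration_grid(Inf))
})

test_that("hill_response has the standard anchors", {
  expect_equal(hill_response(1e-6, 1e-6, e_max = 1), 0.5)
  expect_equal(hill_response(0, 1e-6), 0)
  expect_equal(hill_response(1e3, 1e-6, e_max = 0.8), 0.8, tolerance = 1e-6)
})

test_that("reference models obey their algebra on a dense grid", {
  expect_equal(bliss_expected(0.5, 0.5), 0.75)
  expect_equal(bliss_expected(0, 0.3), 0.3) # identity element
  expect_equal(bliss_expected(1, 0.3), 1) # absorbing element
  expect_equal(hsa_expected(0.3, 0.7), 0.7)
  expect_error(bliss_expected(-0.1, 0.5))
  expect_error(hsa_expected(0.2, 1.4))
  s <- seq(0, 1, by = 0.01)
  grid <- expand.grid(a = s, b = s)
  bl <- bliss_expected(grid$a, grid$b)
  hs <- hsa_expected(grid$a, grid$b)
  expect_true(all(bl >= 0 & bl <= 1)) # closed on [0,1]
  expect_true(all(hs <= bl + 1e-12)) # HSA never exceeds Bliss
  expect_equal(bl, bliss_expected(grid$b, grid$a)) # commutative
  # monotone in each argument
  expect_true(all(diff(bliss_expected(s, 0.4)) >= 0))
  # associative
  expect_equal(
    bliss_expected(bliss_expected(0.2, 0.5), 0.7),
    bliss_expected(0.2, bliss_expected(0.5, 0.7))
  )
})

test_that("excess surfaces recover known offsets over the Bliss expectation", {
  a <- tibble::tibble(id = "A", log_ic50 = -6)
  b <- tibble::tibble(id = "B", log_ic50 = -7)
  m <- simulate_matrix(a, b, gamma = 1, noise_sd = 0)
  expect_equal(excess_surface(m, "bliss")$summary, 0)
  m2 <- simulate_matrix(a, b, gamma = 0.5, noise_sd = 0)
  expect_equal(excess_surface(m2, "bliss")$summary, 0.125) # kappa*(1-gamma)
  # flat offset on nonzero-dose cells
  m3 <- m
  m3$response[-1, -1] <- pmin(m3$response[-1, -1] + 0.1, 1)
  expect_equal(excess_surface(m3, "bliss")$summary, 0.1)
  expect_error(excess_surface(m, "zip"))
})

test_that("simulated blocks are deterministic and track gamma monotonically", {
  a <- tibble::tibble(id = "A", log_ic50 = -6.5)
  b <- tibble::tibble(id = "B", log_ic50 = -6)
  m1 <- simulate_matrix(a, b, gamma = 0.8, noise_sd = 0.02, seed = 9)
  m2 <- simulate_matrix(a, b, gamma = 0.8, noise_sd = 0.02, seed = 9)
  expect_identical(m1$response, m2$response)
  gammas <- seq(0.2, 1.8, by = 0.2)
  summaries <- vapply(gammas, function(g) {
    excess_surface(simulate_matrix(a, b, gamma = g, noise_sd = 0.01, seed = 3), "bliss")$summary
  }, numeric(1))
  expect_lt(cor(gammas, summaries, method = "spearman"), 0)
})

test_that("excess-Bliss separates synergistic from additive mechanism groups", {
  # independent oracle: simulate 50 pairs per group directly from the block
  # generator and compare group means of the excess summary
  set.seed(21)
  ic <- runif(50, -7.5, -6)
  summ <- function(gamma_vec) {
    vapply(seq_len(50), function(i) {
      a <- tibble::tibble(id = "A", log_ic50 = ic[i])
      b <- tibble::tibble(id = "B", log_ic50 = ic[i] - 0.4)
      excess_surface(
        simulate_matrix(a, b, gamma = gamma_vec[i], noise_sd = 0.02, seed = i),
        "bliss"
      )$summary
    }, numeric(1))
  }
  syn <- summ(rep(0.6, 50)) # mechanism effect -0.4
  add <- summ(rep(1.0, 50)) # no effect
  expect_gt(mean(syn), mean(add))
})
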