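test_that("single-compartment residence time is the reciprocal exit rate", {
  p <- ref_params(k = 1)
  p$exit[c("scln", "mln", "pp")] <- 0.5
  expect_equal(unname(mean_residence_time(p, "scln")), 2)
  expect_equal(unname(mean_residence_time(p, "lung")), 1 / 2.17)
})

test_that("a k-stage chain takes k times longer than one stage", {
  p1 <- ref_params(k = 1)
  p3 <- ref_params(k = 3)
  expect_equal(unname(mean_residence_time(p3, "mln")),
               3 * unname(mean_residence_time(p1, "mln")))
})

test_that("chain residence matches Monte-Carlo first-passage times", {
  set.seed(404)
  m <- 0.01
  k <- 3
  # independent oracle: passage through 3 serial exponential stages
  passage <- rexp(1e5, m) + rexp(1e5, m) + rexp(1e5, m)
  p <- ref_params(k = 3)
  p$exit[c("scln", "mln", "pp")] <- m
  expect_equal(unname(mean_residence_time(p, "pp")), k / m)
  expect_equal(mean(passage), k / m, tolerance = 0.02)
})

test_that("blood residence uses the total exit rate including removal", {
  p <- ref_params()
  expect_equal(unname(mean_residence_time(p, "blood")),
               1 / (sum(p$entry) + p$removal))
  p0 <- recirc_params(
    entry = c(lung = 0, liver = 0, spleen = 0, scln = 0, mln = 0, pp = 0),
    exit = p$exit, removal = 0
  )
  expect_error(mean_residence_time(p0, "blood"), "zero")
})

test_that("residence-time densities are gamma with shape k and integrate to 1", {
  p <- ref_params(k = 2)
  m <- p$exit[["scln"]]
  grid <- seq(0, 20000, by = 1)
  d <- residence_time_distribution(p, "scln", grid)
  # mode of a shape-2 gamma is (k - 1)/m
  expect_equal(grid[which.max(d$density)], (2 - 1) / m, tolerance = 0.01)
  expect_equal(sum(d$density), 1, tolerance = 1e-4) # unit-step quadrature
  # exponential (mode at zero) for single-compartment organs
  dsp <- residence_time_distribution(p, "spleen", grid)
  expect_equal(which.max(dsp$density), 1L)
  expect_error(residence_time_distribution(p, "scln", numeric(0)), "empty")
})
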