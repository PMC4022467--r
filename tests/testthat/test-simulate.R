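test_that("with no outflow from blood the bolus stays in the blood", {
  p <- recirc_params(
    entry = c(lung = 0, liver = 0, spleen = 0, scln = 0, mln = 0, pp = 0),
    exit = c(lung = 1, liver = 1, spleen = 0.01, ln = 0.003),
    removal = 0
  )
  tr <- simulate_trajectory(p, c(0, 10, 100, 1000))
  expect_equal(tr$blood, rep(100, 4))
  expect_equal(tr$lung + tr$liver + tr$spleen + tr$scln + tr$mln + tr$pp,
               rep(0, 4))
})

test_that("label is conserved to 1e-6 across random parameter sets and modes", {
  set.seed(101)
  for (i in 1:20) {
    p <- rand_params(cannulation = i %% 2 == 0)
    if (p$cannulation) p$exit_decline <- stats::runif(1, 0, 1e-3)
    tr <- simulate_trajectory(p, c(0, 1, 10, 60, 600, 2700))
    expect_lt(max(abs(tr$total - 100)), 1e-6)
    expect_true(all(as.matrix(tr[, setdiff(names(tr), "time")]) > -1e-9))
  }
})

test_that("solution matches the matrix-exponential oracle to 1e-8", {
  set.seed(202)
  times <- sort(stats::runif(20, 0.5, 2000))
  for (i in 1:5) {
    p <- rand_params(k = 2, cannulation = i > 3)
    tr <- simulate_trajectory(p, times, rtol = 1e-11, atol = 1e-14)
    ora <- oracle_trajectory(p, times)
    sim <- as.matrix(tr[, state_cols <- colnames(oracle_matrix(p))])
    rel <- abs(sim - ora) / pmax(abs(ora), 1)
    expect_lt(max(rel), 1e-8)
  }
})

test_that("the system is linear: scaling the bolus scales every pool", {
  p <- ref_params()
  k <- p$n_subcompartments
  init <- numeric(7 + 3 * k)
  init[1] <- 100
  tr1 <- simulate_trajectory(p, c(1, 10, 100), init = init)
  tr2 <- simulate_trajectory(p, c(1, 10, 100), init = init / 4)
  for (col in c("blood", "lung", "spleen", "scln", "mln", "pp")) {
    expect_equal(tr2[[col]], tr1[[col]] / 4, tolerance = 1e-8)
  }
})

test_that("measured liver signal is the sum of live and dead pools", {
  tr <- simulate_trajectory(ref_params(), c(10, 1440))
  expect_equal(tr$liver, tr$liver_live + tr$liver_dead)
  expect_true(all(tr$liver_dead >= 0))
  expect_gt(tr$liver_dead[2], tr$liver_dead[1]) # dead pool only accumulates
})

test_that("invalid inputs fail loudly, never silently", {
  p <- ref_params()
  expect_error(simulate_trajectory(p, c(-1, 10)), "non-negative")
  expect_error(simulate_trajectory(p, c(10, 5)), "increasing")
  expect_error(simulate_trajectory(p, c(1, NaN)), "finite")
  bad <- p
  bad$entry[["lung"]] <- Inf
  expect_error(simulate_trajectory(recirc_params(bad$entry, bad$exit), 1:3))
})

test_that("cannulation collects MLN efflux plus the thoracic share of SCLN", {
  p <- ref_params()
  p$cannulation <- TRUE
  tr <- simulate_trajectory(p, c(0, 60, 2700))
  expect_equal(tr$duct_collected[1], 0)
  expect_true(all(diff(tr$duct_collected) > 0))
  # without cannulation nothing is collected
  p$cannulation <- FALSE
  tr0 <- simulate_trajectory(p, c(0, 60, 2700))
  expect_equal(tr0$duct_collected, rep(0, 3))
  expect_equal(tr0$duct_rate, rep(0, 3))
})
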