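test_that("zero-noise generation equals the forward simulation exactly", {
  p <- ref_params()
  d <- generate_migration_dataset(p, noise = noise_spec(sd_migration = 0))
  tr <- simulate_trajectory(p, migration_sampling_times())
  for (org in recirc_organs()) {
    expect_equal(d$percent[d$organ == org], tr[[org]], tolerance = 1e-10)
  }
  expect_equal(attr(d, "n_clamped"), 0L)
  dc <- generate_cannulation_dataset(p, f = 0.5, nu = 0,
                                     noise = noise_spec(sd_cannulation = 0))
  pc <- predict_cannulation(p, f = 0.5, nu = 0, horizon = 2700, step = 90)
  expect_equal(dc$rate, pc$duct_rate[match(dc$time, pc$time)], tolerance = 1e-10)
})

test_that("equal seeds reproduce identical datasets; unequal seeds differ", {
  p <- ref_params()
  d1 <- generate_migration_dataset(p, noise = noise_spec(seed = 7))
  d2 <- generate_migration_dataset(p, noise = noise_spec(seed = 7))
  d3 <- generate_migration_dataset(p, noise = noise_spec(seed = 8))
  expect_identical(d1$percent, d2$percent)
  expect_false(identical(d1$percent, d3$percent))
  n1 <- generate_stimulated_node_dataset(p, sd = 0.05, seed = 5)
  n2 <- generate_stimulated_node_dataset(p, sd = 0.05, seed = 5)
  expect_identical(n1$percent, n2$percent)
})

test_that("negative noisy percents are clamped to zero and counted", {
  p <- ref_params()
  # huge noise forces negatives
  d <- generate_migration_dataset(p, noise = noise_spec(sd_migration = 50,
                                                        seed = 9))
  expect_true(all(d$percent >= 0))
  expect_gt(attr(d, "n_clamped"), 0)
  # generated data satisfy the dataset invariants
  expect_silent(recirc:::validate_migration_data(d))
})

test_that("cannulation output decreases with the exit-decline rate", {
  p <- ref_params()
  quiet <- noise_spec(sd_cannulation = 0)
  d0 <- generate_cannulation_dataset(p, f = 0.5, nu = 0, noise = quiet)
  d1 <- generate_cannulation_dataset(p, f = 0.5, nu = 6e-4, noise = quiet)
  expect_lt(sum(d1$rate), sum(d0$rate))
  # and the late-time rates are suppressed most
  expect_lt(utils::tail(d1$rate, 1), utils::tail(d0$rate, 1))
})

test_that("the sampling grids match the experimental designs", {
  expect_length(migration_sampling_times(), 13)
  expect_equal(migration_sampling_times()[1:5], c(1, 2, 5, 10, 30))
  expect_equal(max(migration_sampling_times()), 24 * 60)
  expect_equal(diff(cannulation_sampling_times())[1], 90)
  expect_equal(max(cannulation_sampling_times()), 45 * 60)
})
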