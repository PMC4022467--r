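test_that("duct routing is symmetric between SCLN and MLN paths", {
  # with no SCLN traffic, the curve cannot depend on f
  p <- ref_params()
  p$entry[["scln"]] <- 0
  c0 <- predict_cannulation(p, f = 0, nu = 0, horizon = 600, step = 30)
  c1 <- predict_cannulation(p, f = 1, nu = 0, horizon = 600, step = 30)
  expect_equal(c0$duct_rate, c1$duct_rate, tolerance = 1e-9)
  expect_equal(c0$cumulative, c1$cumulative, tolerance = 1e-9)
})

test_that("cumulative duct output is nondecreasing, bounded, and mass-balanced", {
  p <- ref_params()
  pc <- predict_cannulation(p, nu = 0, horizon = 2700, step = 15)
  expect_true(all(diff(pc$cumulative) >= 0))
  expect_lt(max(pc$cumulative), 100)
  # mass balance: collected = 100 - everything still in the system or removed
  pp <- p
  pp$cannulation <- TRUE
  pp$exit_decline <- 0
  tr <- simulate_trajectory(pp, c(0, 2700))
  still_there <- tr$blood + tr$lung + tr$liver + tr$spleen + tr$scln +
    tr$mln + tr$pp + tr$removed
  expect_equal(tr$duct_collected, 100 - still_there, tolerance = 1e-6)
  expect_equal(utils::tail(pc$cumulative, 1), tr$duct_collected[2],
               tolerance = 1e-6)
})

test_that("trapezoid integral of the duct rate reproduces the collected pool", {
  pc <- predict_cannulation(ref_params(), nu = 0, horizon = 2700, step = 5)
  # duct_rate is %/h, time in minutes
  integ <- cumsum(c(0, diff(pc$time) / 60 * (utils::head(pc$duct_rate, -1) +
                                               utils::tail(pc$duct_rate, -1)) / 2))
  expect_equal(utils::tail(integ, 1), utils::tail(pc$cumulative, 1),
               tolerance = 1e-3)
})

test_that("an identity scenario leaves the steady state unchanged", {
  p <- ref_params()
  expect_equal(steady_state(apply_scenario(p, scenario_control())),
               steady_state(p))
  expect_error(scenario("bad", entry = c(kidney = 2)), "unknown organ")
  expect_error(scenario("bad", exit = c(lung = -1)), "> 0")
})

test_that("perturbation scenarios match brute-force long-run simulation", {
  p <- ref_params()
  for (sc in list(scenario_lung_inflammation(), scenario_blocked_ln_entry(),
                  scenario_blocked_ln_exit())) {
    pp <- apply_scenario(p, sc)
    pp$removal <- 0
    ss <- steady_state(pp)
    tr <- simulate_trajectory(pp, c(0, 1e7))
    sim <- c(tr$blood[2], tr$lung[2], tr$liver[2], tr$spleen[2],
             tr$scln[2], tr$mln[2], tr$pp[2])
    sim <- 100 * sim / sum(sim)
    expect_lt(max(abs(ss$percent - sim)), 0.1)
  }
})

test_that("scenario_table reports all scenarios over the seven organs", {
  tab <- scenario_table(ref_params())
  expect_equal(nrow(tab), 4 * 7)
  sums <- tapply(tab$percent, tab$scenario, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
})

test_that("identical node data give identical per-node estimates", {
  p <- ref_params()
  d <- generate_stimulated_node_dataset(p, entry_ratio = 1, exit_ratio = 1,
                                        sd = 0)
  set.seed(21)
  fit <- fit_stimulated_node(d, p, k = 2, n_starts = 1)
  expect_equal(fit$estimates[["s_stimulated"]], fit$estimates[["s_control"]],
               tolerance = 1e-4)
  expect_equal(fit$estimates[["m_stimulated"]], fit$estimates[["m_control"]],
               tolerance = 1e-4)
  expect_equal(fit$entry_ratio, 1, tolerance = 1e-4)
})

test_that("noiseless stimulated-node data invert to the generating ratios", {
  p <- ref_params()
  d <- generate_stimulated_node_dataset(p, entry = 5e-4, exit = 0.0034,
                                        entry_ratio = 4, exit_ratio = 1, sd = 0)
  set.seed(22)
  fit <- fit_stimulated_node(d, p, k = 2, n_starts = 1)
  expect_equal(fit$entry_ratio, 4, tolerance = 0.01)
  expect_equal(fit$estimates[["s_control"]], 5e-4, tolerance = 0.01)
  expect_equal(fit$estimates[["m_stimulated"]], 0.0034, tolerance = 0.01)
})

test_that("stimulated-node decomposition recovers a 4-fold entry increase from noisy data", {
  p <- ref_params()
  d <- generate_stimulated_node_dataset(p, entry_ratio = 4, sd = 0.05, seed = 33)
  set.seed(23)
  full <- fit_stimulated_node(d, p, k = 2, n_starts = 2)
  expect_lt(abs(full$entry_ratio / 4 - 1), 0.1)
  shared <- fit_stimulated_node(d, p, k = 2, shared_exit = TRUE, n_starts = 2)
  cmp <- compare_models(full, shared, method = "f_test")
  expect_gt(cmp$p.value, 0.05) # equal exits are not rejected under equal-exit truth
  expect_error(fit_stimulated_node(d[d$time > 800, ], p), "fewer than 4")
})

test_that("complete blockade with one stage reveals the exact exit rate", {
  p <- ref_params(k = 1)
  bl <- simulate_entry_blockade(p, efficacy = 1, t_max = 2880)
  expect_equal(bl$apparent_rate, bl$true_exit_rate, tolerance = 1e-6)
  expect_gt(bl$r_squared, 0.9999)
  expect_true(all(diff(bl$curve$content) <= 1e-10))
})

test_that("partial blockade biases the apparent egress rate downward", {
  p <- ref_params(k = 1)
  bl <- simulate_entry_blockade(p, efficacy = 0.7, t_max = 2880)
  expect_lt(bl$apparent_rate, bl$true_exit_rate)
  expect_error(simulate_entry_blockade(p, efficacy = 1.2), "\\[0, 1\\]")
})

test_that("two-stage decay under full blockade still looks single-exponential", {
  p <- ref_params(k = 2)
  bl <- simulate_entry_blockade(p, efficacy = 1, t_max = 2880)
  expect_gt(bl$r_squared, 0.98)
  expect_true(all(diff(bl$curve$content) <= 1e-10))
})

test_that("pass-count arithmetic matches a geometric Monte-Carlo oracle", {
  p <- ref_params()
  # p = 0.5 means one failed pass on average
  ph <- p
  ph$entry[] <- c(lung = 1, liver = 0, spleen = 1, scln = 0, mln = 0, pp = 0)
  expect_equal(expected_vascular_passes(ph), 1)
  passes <- expected_vascular_passes(p)
  prob <- sum(p$entry[c("spleen", "scln", "mln", "pp")]) / sum(p$entry)
  set.seed(24)
  expect_equal(passes, mean(stats::rgeom(1e6, prob)), tolerance = 0.01)
  p0 <- ph
  p0$entry[] <- c(lung = 1, liver = 1, spleen = 0, scln = 0, mln = 0, pp = 0)
  expect_error(expected_vascular_passes(p0), "zero")
})
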