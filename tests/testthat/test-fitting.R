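test_that("noiseless data are inverted to the generating parameters", {
  p <- ref_params()
  d <- generate_migration_dataset(p, noise = noise_spec(sd_migration = 0))
  set.seed(11)
  fit <- fit_migration(d, k = 2, n_starts = 3)
  expect_true(fit$converged)
  expect_lt(fit$ssr, 1e-6)
  expect_lt(max(abs(tidy(fit)$estimate / ref_truth() - 1)), 0.01)
  # optimizer deviance trace is monotone non-increasing
  expect_true(all(diff(fit$rsstrace) <= 1e-12))
})

test_that("data generated without LN/spleen traffic yield near-zero entries", {
  p <- recirc_params(
    entry = c(lung = 1.8, liver = 0, spleen = 0, scln = 0, mln = 0, pp = 0),
    exit = c(lung = 2.2, liver = 1, spleen = 0.01, ln = 0.003),
    removal = 0
  )
  d <- generate_migration_dataset(p, noise = noise_spec(sd_migration = 0))
  set.seed(12)
  fit <- fit_migration(d, k = 2, n_starts = 3, fix = list(mu = 0, phi = 0))
  est <- tidy(fit)
  lung <- est$estimate[est$term == "s_lung"]
  others <- est$estimate[est$term %in% c("s_liver", "s_spleen", "s_scln",
                                         "s_mln", "s_pp")]
  expect_equal(lung, 1.8, tolerance = 0.01)
  expect_true(all(others < 1e-3))
})

test_that("a missing organ or malformed records are reported by name", {
  d <- generate_migration_dataset(ref_params(),
                                  noise = noise_spec(sd_migration = 0))
  expect_error(fit_migration(d[d$organ != "spleen", ]), "spleen")
  dd <- d
  dd$organ[1] <- "kidney"
  expect_error(fit_migration(dd), "kidney")
  expect_error(fit_migration(rbind(d, d[1, ])), "one record per")
})

test_that("parameters can be fixed and the mask is honoured", {
  d <- generate_migration_dataset(ref_params(),
                                  noise = noise_spec(sd_migration = 0))
  set.seed(13)
  fit <- fit_migration(d, k = 2, n_starts = 2,
                       fix = list(mu = 0.0048, phi = 0.5))
  expect_equal(fit$n_free, 10)
  expect_equal(fit$params$removal, 0.0048)
  expect_equal(fit$params$dying_fraction, 0.5)
  expect_false("mu" %in% tidy(fit)$term)
})

test_that("identical SSR gives F = 0 and p = 1; non-nested fits error", {
  d <- generate_migration_dataset(ref_params(),
                                  noise = noise_spec(sd_migration = 1, seed = 2))
  set.seed(14)
  f1 <- fit_migration(d, k = 2, n_starts = 1, start = ref_params())
  f2 <- f1
  f2$n_free <- f1$n_free - 1
  f2$free <- f1$free[-1]
  cmp <- compare_models(f1, f2, method = "f_test")
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p.value, 1)
  # reversing roles (reduced has more parameters) is not a valid nesting
  expect_error(compare_models(f2, f1, method = "f_test"), "fewer|subset")
  d2 <- d
  d2$percent <- d2$percent + 1
  f3 <- f1
  f3$data <- d2
  expect_error(compare_models(f1, f3), "same data")
})

test_that("shared LN/PP exit nests inside organ-specific exits", {
  d <- generate_migration_dataset(ref_params(),
                                  noise = noise_spec(sd_migration = 1, seed = 3))
  set.seed(15)
  shared <- fit_migration(d, k = 2, n_starts = 1, start = ref_params())
  full <- fit_migration(d, k = 2, shared_ln_exit = FALSE, n_starts = 1,
                        start = ref_params())
  expect_equal(full$n_free, 14)
  cmp <- compare_models(full, shared, method = "f_test")
  expect_equal(cmp$df1, 2)
  # the data were generated under the shared-exit truth: no improvement
  expect_gt(cmp$p.value, 0.05)
  aic <- compare_models(full, shared, method = "aic")
  expect_lt(aic$aic_reduced, aic$aic_full + 4)
})

test_that("bootstrap on perfect data gives zero-width intervals and is seed-stable", {
  p <- ref_params()
  d <- generate_migration_dataset(p, noise = noise_spec(sd_migration = 0))
  set.seed(16)
  fit <- fit_migration(d, k = 2, n_starts = 1, start = p)
  b1 <- bootstrap_ci(fit, n_boot = 5, seed = 99)
  expect_lt(max(b1$ci$conf.high - b1$ci$conf.low), 1e-4)
  expect_true(all(b1$ci$conf.low <= b1$ci$estimate + 1e-8) &&
                all(b1$ci$estimate <= b1$ci$conf.high + 1e-8))
  b2 <- bootstrap_ci(fit, n_boot = 5, seed = 99)
  expect_identical(b1$boot, b2$boot)
})

test_that("joint fit with nu fixed at 0 agrees with the migration-only fit", {
  p <- ref_params()
  dm <- generate_migration_dataset(p, noise = noise_spec(sd_migration = 0))
  dc <- generate_cannulation_dataset(p, f = 0.5, nu = 0,
                                     noise = noise_spec(sd_cannulation = 0))
  set.seed(17)
  mig <- fit_migration(dm, k = 2, n_starts = 1, start = p)
  jf <- joint_fit(dm, dc, k = 2, fix = list(nu = 0, f = 0.5), start = p,
                  n_starts = 1, maxit = 600)
  mig_est <- tidy(mig)
  joint_est <- tidy(jf)
  shared_terms <- intersect(mig_est$term, joint_est$term)
  rel <- abs(joint_est$estimate[match(shared_terms, joint_est$term)] /
               mig_est$estimate[match(shared_terms, mig_est$term)] - 1)
  expect_lt(max(rel), 0.05)
})

test_that("joint fit recovers the cannulation-induced exit decline", {
  p <- ref_params()
  nu_true <- log(2.3) / 1440
  dm <- generate_migration_dataset(p, noise = noise_spec(seed = 5))
  dc <- generate_cannulation_dataset(p, f = 0.5, nu = nu_true,
                                     noise = noise_spec(sd_cannulation = 0.2, seed = 6))
  set.seed(18)
  jf <- joint_fit(dm, dc, k = 2, fix = list(f = 0.5), n_starts = 1)
  expect_true(jf$converged)
  expect_lt(abs(jf$params$exit_decline / nu_true - 1), 0.2)
  expect_gt(jf$sigma2, 0)
  expect_gt(jf$sigma1, jf$sigma2) # migration data are noisier by design
})
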