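# Parameter estimation: nonlinear least squares on migration data,
# generalized likelihood on migration + cannulation data, model comparison,
# and residual-bootstrap confidence intervals.
#
# All rates are optimized on the log scale and fractions on the logit scale,
# which enforces positivity/boundedness without constrained optimizers.

FRACTION_PARS <- c("phi", "f")

# ---- transformation between a recirc_params object and a free-parameter
# ---- vector theta (log/logit scale) -----------------------------------------

free_parameter_names <- function(shared_ln_exit = TRUE, with_nu = FALSE,
                                 with_f = FALSE) {
  nm <- c(paste0("s_", tissue_organs()),
          "m_lung", "m_liver", "m_spleen",
          if (shared_ln_exit) "m_ln" else c("m_scln", "m_mln", "m_pp"),
          "mu", "phi")
  if (with_nu) nm <- c(nm, "nu")
  if (with_f) nm <- c(nm, "f")
  nm
}

# value of a named scalar parameter from a params object
get_par <- function(params, name) {
  if (grepl("^s_", name)) return(params$entry[[sub("^s_", "", name)]])
  if (name == "m_ln") return(params$exit[["scln"]])
  if (grepl("^m_", name)) return(params$exit[[sub("^m_", "", name)]])
  switch(name,
    mu = params$removal, phi = params$dying_fraction,
    f = params$thoracic_fraction, nu = params$exit_decline,
    stop("unknown parameter ", name, call. = FALSE)
  )
}

set_par <- function(params, name, value) {
  if (grepl("^s_", name)) {
    params$entry[[sub("^s_", "", name)]] <- value
  } else if (name == "m_ln") {
    params$exit[c("scln", "mln", "pp")] <- value
  } else if (grepl("^m_", name)) {
    params$exit[[sub("^m_", "", name)]] <- value
  } else {
    field <- switch(name, mu = "removal", phi = "dying_fraction",
                    f = "thoracic_fraction", nu = "exit_decline")
    params[[field]] <- value
  }
  params
}

encode_theta <- function(params, free) {
  vapply(free, function(nm) {
    v <- get_par(params, nm)
    if (nm %in% FRACTION_PARS) {
      stats::qlogis(min(max(v, 1e-8), 1 - 1e-8))
    } else {
      log(max(v, 1e-12))
    }
  }, numeric(1))
}

decode_theta <- function(theta, base_params, free) {
  p <- base_params
  for (i in seq_along(free)) {
    nm <- free[i]
    v <- if (nm %in% FRACTION_PARS) stats::plogis(theta[i]) else exp(theta[i])
    p <- set_par(p, nm, v)
  }
  p
}

# Data-driven starting point. Entry rates from the early-time uptake
# fractions (at the first sampled time the label found in each organ is
# roughly proportional to its entry rate); the overall blood-exit scale from
# the initial blood decline; lung/liver/spleen exit rates from
# quasi-equilibrium organ/blood ratios. Multi-start jitter explores around
# this point.
data_start_params <- function(data, k) {
  val <- function(organ, time) {
    d <- data[data$organ == organ, ]
    if (nrow(d) == 0) return(NA_real_)
    d$percent[which.min(abs(d$time - time))]
  }
  t1 <- min(data$time[data$time > 0])
  tlast <- max(data$time)
  tmid <- sort(unique(data$time))
  tmid <- tmid[which.min(abs(tmid - 30))]

  b1 <- val("blood", t1)
  total_rate <- if (is.finite(b1) && b1 > 0 && b1 < 100) {
    -log(b1 / 100) / t1
  } else {
    1
  }
  uptake <- vapply(tissue_organs(), val, numeric(1), time = t1)
  uptake[!is.finite(uptake) | uptake <= 0] <- 1e-3
  s <- total_rate * uptake / sum(uptake)
  s <- pmax(s, 1e-5)

  bmid <- max(val("blood", tmid), 1e-3)
  blate <- max(val("blood", tlast), 1e-3)
  ratio_exit <- function(organ, time, bb, fallback) {
    v <- val(organ, time)
    if (!is.finite(v) || v <= 0) return(fallback)
    max(s[[organ]] * bb / v, 1e-6)
  }
  m <- c(lung = ratio_exit("lung", tmid, bmid, 1),
         liver = ratio_exit("liver", tmid, bmid, 1),
         spleen = ratio_exit("spleen", tlast, blate, 0.01),
         scln = 0.003, mln = 0.003, pp = 0.003)

  recirc_params(
    entry = s, exit = m,
    removal = 0.002, dying_fraction = 0.5, thoracic_fraction = 0.5,
    n_subcompartments = k, exit_decline = 5e-4
  )
}

# ---- data validation ---------------------------------------------------------

validate_migration_data <- function(data, require_all_organs = TRUE) {
  need <- c("organ", "time", "percent")
  if (!all(need %in% names(data))) {
    stop("migration data must have columns organ, time, percent", call. = FALSE)
  }
  bad <- !data$organ %in% recirc_organs()
  if (any(bad)) {
    stop(sprintf("unknown organ label(s) %s in row(s) %s",
                 paste(unique(data$organ[bad]), collapse = ", "),
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  if (require_all_organs) {
    missing <- setdiff(recirc_organs(), unique(data$organ))
    if (length(missing)) {
      stop("migration data missing organ(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  if (any(!is.finite(data$time)) || any(data$time < 0)) {
    stop("times must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(data$percent)) || any(data$percent < 0)) {
    stop("percents must be finite and >= 0", call. = FALSE)
  }
  if (anyDuplicated(data[, c("organ", "time")])) {
    stop("at most one record per (organ, time) pair", call. = FALSE)
  }
  invisible(data)
}

validate_cannulation_data <- function(data) {
  need <- c("time", "rate")
  if (!all(need %in% names(data))) {
    stop("cannulation data must have columns time, rate", call. = FALSE)
  }
  if (any(!is.finite(data$time)) || any(data$time < 0)) {
    stop("times must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(data$rate)) || any(data$rate < 0)) {
    stop("rates must be finite and >= 0", call. = FALSE)
  }
  if (anyDuplicated(data$time)) {
    stop("duplicate cannulation times", call. = FALSE)
  }
  invisible(data)
}

# ---- model predictions for the two data layouts ------------------------------

# evaluate quietly: extreme parameter draws during multi-start can make the
# solver print Fortran diagnostics before failing; the failure itself is
# handled by the penalty in the residual functions
quiet_try <- function(expr) {
  utils::capture.output(res <- suppressWarnings(try(expr, silent = TRUE)))
  res
}

predict_migration_percent <- function(params, data, rtol = 1e-8, atol = 1e-10) {
  params$cannulation <- FALSE
  tt <- sort(unique(data$time))
  tr <- simulate_trajectory(params, tt, rtol = rtol, atol = atol)
  idx <- match(data$time, tt)
  vapply(seq_len(nrow(data)), function(i) {
    tr[[data$organ[i]]][idx[i]]
  }, numeric(1))
}

predict_cannulation_rate <- function(params, data, rtol = 1e-8, atol = 1e-10) {
  params$cannulation <- TRUE
  tt <- sort(unique(data$time))
  tr <- simulate_trajectory(params, tt, rtol = rtol, atol = atol)
  tr$duct_rate[match(data$time, tt)]
}

# ---- migration-only least squares -------------------------------------------

#' Fit the recirculation model to migration data
#'
#' Nonlinear least squares (Levenberg-Marquardt, log/logit parameterization,
#' multi-start) of the compartment model to a long-format migration dataset
#' of (organ, time, percent of injected label recovered). The liver
#' observable is fitted as live plus dead cells. In the default shared-exit
#' model the SCLN, MLN and PP chains share one per-stage transit rate, giving
#' 12 free parameters: 6 entry rates, exit rates for lung/liver/spleen and
#' the shared LN/PP rate, the blood removal rate and the dying fraction.
#'
#' @param data Tibble with columns `organ`, `time` (minutes), `percent`,
#'   covering all seven organs.
#' @param k Number of LN/PP sub-compartments (1-3).
#' @param shared_ln_exit If `TRUE` (default) a single exit rate is shared by
#'   SCLN, MLN and PP; otherwise each has its own.
#' @param fix Named list of parameters to hold fixed at the given values
#'   (names as in the free-parameter vector, e.g. `list(mu = 0, phi = 0)`).
#' @param start Optional [recirc_params] giving starting values.
#' @param n_starts Number of jittered starts (the first start is unjittered).
#' @param jitter_sd Log-scale standard deviation of start jitter.
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#'
#' @return An object of class `recirc_fit` with the estimated parameters
#'   (`$params`), sum of squared residuals (`$ssr`), per-record residuals
#'   (`$residuals`), convergence flag and bookkeeping. Non-convergence after
#'   all restarts is flagged (`$converged = FALSE`), not raised.
#' @seealso [joint_fit()], [bootstrap_ci()], [compare_models()]
#' @export
fit_migration <- function(data, k = 2, shared_ln_exit = TRUE, fix = NULL,
                          start = NULL, n_starts = 5, jitter_sd = 1,
                          maxiter = 200) {
  data <- tibble::as_tibble(data)
  validate_migration_data(data)
  if (!k %in% 1:3) stop("`k` must be 1, 2 or 3", call. = FALSE)
  free <- setdiff(free_parameter_names(shared_ln_exit), names(fix))
  base <- if (is.null(start)) data_start_params(data, k) else start
  base$n_subcompartments <- as.integer(k)
  for (nm in names(fix)) base <- set_par(base, nm, fix[[nm]])

  resid_fn <- function(theta) {
    p <- decode_theta(theta, base, free)
    pred <- quiet_try(predict_migration_percent(p, data))
    if (inherits(pred, "try-error") || any(!is.finite(pred))) {
      return(rep(1e6, nrow(data)))
    }
    pred - data$percent
  }

  run <- run_multistart_lm(resid_fn, encode_theta(base, free), n_starts,
                           jitter_sd, maxiter)
  best <- run$best
  params_hat <- decode_theta(best$par, base, free)
  residuals <- tibble::tibble(
    data,
    fitted = predict_migration_percent(params_hat, data)
  )
  residuals$residual <- residuals$fitted - residuals$percent

  structure(list(
    params = params_hat,
    theta = best$par,
    free = free,
    fixed = fix,
    ssr = best$deviance,
    residuals = residuals,
    data = data,
    k = k,
    shared_ln_exit = shared_ln_exit,
    n = nrow(data),
    n_free = length(free),
    converged = run$converged,
    message = best$message,
    rsstrace = best$rsstrace,
    objective = "ssr",
    start = base,
    n_starts = n_starts
  ), class = "recirc_fit")
}

# multi-start Levenberg-Marquardt driver
run_multistart_lm <- function(resid_fn, theta0, n_starts, jitter_sd, maxiter) {
  best <- NULL
  converged <- FALSE
  for (i in seq_len(max(1, n_starts))) {
    th <- if (i == 1) theta0 else theta0 + stats::rnorm(length(theta0), 0, jitter_sd)
    fit <- try(minpack.lm::nls.lm(
      par = th, fn = resid_fn,
      # epsfcn keeps finite-difference steps well above the ODE solver's
      # error floor; without it the numeric Jacobian is noise and the
      # Levenberg-Marquardt trust region collapses prematurely
      control = minpack.lm::nls.lm.control(
        maxiter = maxiter, ftol = 1e-12, ptol = 1e-12, epsfcn = 1e-6)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) next
    ok <- fit$info %in% 1:4
    if (is.null(best) || fit$deviance < best$deviance) {
      best <- fit
      converged <- ok
    }
  }
  if (is.null(best)) stop("all optimizer starts failed", call. = FALSE)
  list(best = best, converged = converged)
}

# ---- joint generalized-likelihood fit ---------------------------------------

#' Joint fit to migration and cannulation data
#'
#' Maximizes the generalized log-likelihood for two datasets with normal
#' errors of different variances: with the variances profiled at their
#' maximum-likelihood values (`sigma_i^2 = SSR_i / n_i`), the objective
#' reduces (up to constants) to minimizing
#' `n1 * log(SSR1) + n2 * log(SSR2)`. Migration records are predicted with
#' the thoracic duct intact; cannulation records are predicted in
#' cannulation mode, where LN/PP transit rates decline as
#' `exp(-nu * t)` and the duct output rate (percent of transferred cells per
#' hour) is the observable. `nu` is an additional free parameter; the
#' thoracic-duct routing fraction `f` is fixed at 0.5 by default.
#'
#' @inheritParams fit_migration
#' @param migration Migration dataset (columns `organ`, `time`, `percent`).
#' @param cannulation Cannulation dataset (columns `time` in minutes, `rate`
#'   in percent per hour).
#' @param free_f If `TRUE`, the thoracic-duct fraction `f` is estimated
#'   rather than fixed.
#' @param start Optional [recirc_params] starting values; by default a
#'   migration-only fit seeds the joint optimization.
#' @param n_starts Jittered restarts of the joint optimizer.
#' @param maxit Iteration cap for each `optim` run.
#'
#' @return An object of class `c("recirc_joint_fit", "recirc_fit")`, with
#'   dataset-specific `$ssr1`, `$ssr2`, profiled error SDs `$sigma1`,
#'   `$sigma2`, and the maximized log-likelihood `$logLik`.
#' @export
joint_fit <- function(migration, cannulation, k = 2, shared_ln_exit = TRUE,
                      free_f = FALSE, fix = NULL, start = NULL,
                      n_starts = 2, jitter_sd = 0.3, maxit = 1500) {
  migration <- tibble::as_tibble(migration)
  cannulation <- tibble::as_tibble(cannulation)
  validate_migration_data(migration)
  validate_cannulation_data(cannulation)
  if (nrow(migration) == 0 || nrow(cannulation) == 0) {
    stop("both datasets must be nonempty", call. = FALSE)
  }

  free <- setdiff(free_parameter_names(shared_ln_exit, with_nu = TRUE,
                                       with_f = free_f),
                  names(fix))
  if (is.null(start)) {
    pre <- fit_migration(migration, k = k, shared_ln_exit = shared_ln_exit,
                         fix = fix[setdiff(names(fix), c("nu", "f"))],
                         n_starts = 3)
    base <- pre$params
    base$exit_decline <- 5e-4
  } else {
    base <- start
  }
  base$n_subcompartments <- as.integer(k)
  for (nm in names(fix)) base <- set_par(base, nm, fix[[nm]])

  n1 <- nrow(migration)
  n2 <- nrow(cannulation)
  objective <- function(theta) {
    p <- decode_theta(theta, base, free)
    pred1 <- quiet_try(predict_migration_percent(p, migration))
    pred2 <- quiet_try(predict_cannulation_rate(p, cannulation))
    if (inherits(pred1, "try-error") || inherits(pred2, "try-error") ||
        any(!is.finite(c(pred1, pred2)))) {
      return(1e10)
    }
    ssr1 <- sum((pred1 - migration$percent)^2)
    ssr2 <- sum((pred2 - cannulation$rate)^2)
    n1 * log(max(ssr1, 1e-300)) + n2 * log(max(ssr2, 1e-300))
  }

  theta0 <- encode_theta(base, free)
  best <- NULL
  for (i in seq_len(max(1, n_starts))) {
    th <- if (i == 1) theta0 else theta0 + stats::rnorm(length(theta0), 0, jitter_sd)
    o1 <- stats::optim(th, objective, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-12))
    o2 <- try(stats::optim(o1$par, objective, method = "BFGS",
                           control = list(maxit = 200, reltol = 1e-12)),
              silent = TRUE)
    cand <- if (!inherits(o2, "try-error") && o2$value <= o1$value) o2 else o1
    if (is.null(best) || cand$value < best$value) best <- cand
  }

  params_hat <- decode_theta(best$par, base, free)
  pred1 <- predict_migration_percent(params_hat, migration)
  p2 <- params_hat
  pred2 <- predict_cannulation_rate(p2, cannulation)
  ssr1 <- sum((pred1 - migration$percent)^2)
  ssr2 <- sum((pred2 - cannulation$rate)^2)
  sigma1 <- sqrt(ssr1 / n1)
  sigma2 <- sqrt(ssr2 / n2)
  logLik <- -(n1 / 2) * (log(2 * pi * sigma1^2) + 1) -
    (n2 / 2) * (log(2 * pi * sigma2^2) + 1)

  res1 <- tibble::tibble(migration, fitted = pred1,
                         residual = pred1 - migration$percent)
  res2 <- tibble::tibble(cannulation, fitted = pred2,
                         residual = pred2 - cannulation$rate)

  structure(list(
    params = params_hat,
    theta = best$par,
    free = free,
    fixed = fix,
    ssr = ssr1 + ssr2,
    ssr1 = ssr1, ssr2 = ssr2,
    sigma1 = sigma1, sigma2 = sigma2,
    logLik = logLik,
    residuals = res1,
    residuals_cannulation = res2,
    data = migration,
    data_cannulation = cannulation,
    k = k,
    shared_ln_exit = shared_ln_exit,
    n = n1 + n2, n1 = n1, n2 = n2,
    n_free = length(free),
    converged = best$convergence == 0,
    objective = "loglik",
    start = base,
    n_starts = n_starts
  ), class = c("recirc_joint_fit", "recirc_fit"))
}

# ---- model comparison --------------------------------------------------------

# shared-exit <-> organ-specific-exit counts as nested (equality constraint)
is_nested <- function(full, reduced) {
  expansions <- list(
    m_ln = c("m_scln", "m_mln", "m_pp"),
    m_node = c("m_stimulated", "m_control")
  )
  rf <- reduced$free
  ff <- full$free
  for (shared in names(expansions)) {
    if (shared %in% rf && all(expansions[[shared]] %in% ff)) {
      rf <- setdiff(rf, shared)
    }
  }
  all(rf %in% ff)
}

#' Compare two fitted models (F-test or AIC)
#'
#' For nested least-squares fits on the same data, the F statistic is
#' `((SSR_r - SSR_f)/(df_r - df_f)) / (SSR_f/df_f)` with
#' `df = n - n_free`, and the p-value comes from the F distribution. The
#' AIC uses the least-squares convention `n * log(SSR/n) + 2p` with the
#' additive constant dropped (for joint fits, the profiled dataset-wise sum
#' `n1 log(SSR1/n1) + n2 log(SSR2/n2) + 2p`); AIC comparisons are only
#' meaningful within the same data.
#'
#' @param fit_full,fit_reduced Two `recirc_fit` objects on the same data;
#'   for `method = "f_test"` the reduced model's free parameters must nest
#'   inside the full model's.
#' @param method `"f_test"` or `"aic"`.
#' @return A one-row tibble: for the F-test, `statistic`, `df1`, `df2`,
#'   `p.value` and the two SSRs; for AIC, the two AICs and `delta_aic`
#'   (reduced minus full; positive favours the full model).
#' @export
compare_models <- function(fit_full, fit_reduced,
                           method = c("f_test", "aic")) {
  method <- match.arg(method)
  stopifnot(inherits(fit_full, "recirc_fit"), inherits(fit_reduced, "recirc_fit"))
  same_data <- isTRUE(all.equal(as.data.frame(fit_full$data),
                                as.data.frame(fit_reduced$data)))
  if (!same_data) stop("fits are not on the same data", call. = FALSE)

  if (method == "f_test") {
    if (fit_full$objective != "ssr" || fit_reduced$objective != "ssr") {
      stop("F-test requires least-squares fits", call. = FALSE)
    }
    if (!is_nested(fit_full, fit_reduced)) {
      stop("models are not nested (reduced free parameters must be a subset)",
           call. = FALSE)
    }
    df_f <- fit_full$n - fit_full$n_free
    df_r <- fit_reduced$n - fit_reduced$n_free
    d <- df_r - df_f
    if (d <= 0) stop("reduced model must have fewer free parameters", call. = FALSE)
    Fstat <- ((fit_reduced$ssr - fit_full$ssr) / d) / (fit_full$ssr / df_f)
    Fstat <- max(Fstat, 0)
    tibble::tibble(
      method = "f_test", statistic = Fstat, df1 = d, df2 = df_f,
      p.value = stats::pf(Fstat, d, df_f, lower.tail = FALSE),
      ssr_full = fit_full$ssr, ssr_reduced = fit_reduced$ssr
    )
  } else {
    tibble::tibble(
      method = "aic",
      aic_full = ls_aic(fit_full),
      aic_reduced = ls_aic(fit_reduced),
      delta_aic = ls_aic(fit_reduced) - ls_aic(fit_full)
    )
  }
}

ls_aic <- function(fit) {
  if (inherits(fit, "recirc_joint_fit")) {
    fit$n1 * log(fit$ssr1 / fit$n1) + fit$n2 * log(fit$ssr2 / fit$n2) +
      2 * fit$n_free
  } else {
    fit$n * log(fit$ssr / fit$n) + 2 * fit$n_free
  }
}

# ---- residual bootstrap ------------------------------------------------------

#' Residual-bootstrap confidence intervals
#'
#' Resamples residuals with replacement (within each dataset for joint
#' fits), adds them to the fitted values, refits from the point estimate and
#' takes 2.5/97.5 percentiles of the bootstrap estimates. Residuals are
#' inflated by `sqrt(n / (n - p))` before resampling to undo the variance
#' deflation of least-squares residuals. Reproducible under a fixed seed.
#' Refit failures are counted; more than 10% failures sets a warning flag on
#' the result.
#'
#' @param fit A converged `recirc_fit` (migration-only or joint).
#' @param n_boot Number of bootstrap replicates (1000 for production use;
#'   reduce for quick checks).
#' @param seed Optional integer seed.
#' @param maxiter Iteration cap per refit (refits are warm-started).
#' @return The fit with added elements `$ci` (tibble of `term`, `estimate`,
#'   `conf.low`, `conf.high`), `$boot` (replicate-by-parameter matrix),
#'   `$boot_failures` and `$boot_warning`.
#' @export
bootstrap_ci <- function(fit, n_boot = 1000, seed = NULL, maxiter = 50) {
  stopifnot(inherits(fit, "recirc_fit"))
  if (!is.null(seed)) set.seed(seed)
  joint <- inherits(fit, "recirc_joint_fit")

  # residuals are inflated to undo least-squares variance deflation, and
  # resampled pseudo-data are clamped at zero like real percent data
  infl <- sqrt(fit$n / (fit$n - fit$n_free))
  draw <- function() {
    d1 <- fit$residuals
    r1 <- infl * d1$residual
    d1$percent <- pmax(d1$fitted + sample(r1, nrow(d1), replace = TRUE), 0)
    if (!joint) return(list(mig = d1))
    d2 <- fit$residuals_cannulation
    r2 <- infl * d2$residual
    d2$rate <- pmax(d2$fitted + sample(r2, nrow(d2), replace = TRUE), 0)
    list(mig = d1, can = d2)
  }

  refit_one <- function(dat) {
    if (inherits(fit, "recirc_node_fit")) {
      d <- dat$mig
      d$percent <- pmax(d$percent, 0)
      return(fit_stimulated_node(
        d[c("node", "time", "percent")], fit$global_params, k = fit$k,
        shared_exit = fit$shared_exit, start = as.list(fit$estimates),
        n_starts = 1, maxiter = maxiter, .chain = fit$chain))
    }
    if (joint) {
      joint_fit(dat$mig[names(fit$data)], dat$can[names(fit$data_cannulation)],
                k = fit$k, shared_ln_exit = fit$shared_ln_exit,
                free_f = "f" %in% fit$free, fix = fit$fixed,
                start = fit$params, n_starts = 1, maxit = 400)
    } else {
      fit_migration(dat$mig[names(fit$data)], k = fit$k,
                    shared_ln_exit = fit$shared_ln_exit, fix = fit$fixed,
                    start = fit$params, n_starts = 1, maxiter = maxiter)
    }
  }

  est <- natural_estimates(fit)
  boot <- matrix(NA_real_, nrow = n_boot, ncol = length(est),
                 dimnames = list(NULL, names(est)))
  failures <- 0L
  for (b in seq_len(n_boot)) {
    rb <- try(refit_one(draw()), silent = TRUE)
    if (inherits(rb, "try-error")) {
      failures <- failures + 1L
      next
    }
    boot[b, ] <- natural_estimates(rb)
  }
  qs <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  fit$ci <- tibble::tibble(
    term = names(est), estimate = unname(est),
    conf.low = qs[1, ], conf.high = qs[2, ]
  )
  fit$boot <- boot
  fit$boot_failures <- failures
  fit$boot_warning <- failures > 0.1 * n_boot
  if (fit$boot_warning) {
    warning(sprintf("%d of %d bootstrap refits failed", failures, n_boot),
            call. = FALSE)
  }
  fit
}

# free-parameter estimates on the natural (rate/fraction) scale
natural_estimates <- function(fit) {
  if (!is.null(fit$estimates)) return(fit$estimates)
  vapply(fit$free, function(nm) get_par(fit$params, nm), numeric(1))
}

#' @export
print.recirc_fit <- function(x, ...) {
  kind <- if (inherits(x, "recirc_joint_fit")) "joint generalized-likelihood"
          else "least-squares"
  cat(sprintf("Recirculation model %s fit (k = %d, %d free parameters)\n",
              kind, x$k, x$n_free))
  cat(sprintf("  n = %d, SSR = %.6g, converged: %s\n", x$n, x$ssr, x$converged))
  if (inherits(x, "recirc_joint_fit")) {
    cat(sprintf("  sigma1 = %.4g, sigma2 = %.4g, logLik = %.4f\n",
                x$sigma1, x$sigma2, x$logLik))
  }
  est <- natural_estimates(x)
  print(tibble::tibble(term = names(est), estimate = unname(est)), n = Inf)
  invisible(x)
}
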