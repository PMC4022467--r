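# Synthetic datasets with the statistical structure the analysis assumes:
# model trajectories at the experimental sampling grids plus i.i.d. normal
# noise with dataset-specific standard deviations. Percents cannot be
# negative, so negative noisy values are clamped to zero and counted.

#' Noise specification for synthetic datasets
#'
#' The error model is additive i.i.d. normal noise with dataset-specific
#' standard deviations: `sd_migration` (percent units) for organ
#' percentages and `sd_cannulation` (percent per hour) for duct output
#' rates. The published organ series are means over at least five animals,
#' and per-time-point SDs were never printed; the migration default (0.5)
#' is calibrated so that synthetic datasets determine the entry rates with
#' the same precision as the published confidence intervals, and the
#' cannulation default resembles the scatter of the digitized duct-output
#' series. Both are conventions, not measured values.
#'
#' @param sd_migration SD of migration-percent noise, percent units.
#' @param sd_cannulation SD of duct-rate noise, percent per hour.
#' @param seed Optional integer seed; equal seeds give identical datasets.
#' @param clamp_negative Clamp negative noisy values to zero (default);
#'   the number of clamped records is attached to the generated dataset as
#'   attribute `"n_clamped"`.
#' @return An object of class `recirc_noise`.
#' @export
noise_spec <- function(sd_migration = 0.5, sd_cannulation = 0.2, seed = NULL,
                       clamp_negative = TRUE) {
  if (sd_migration < 0 || sd_cannulation < 0) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  structure(list(sd_migration = sd_migration,
                 sd_cannulation = sd_cannulation,
                 seed = seed, clamp_negative = clamp_negative),
            class = "recirc_noise")
}

with_noise_seed <- function(noise, expr) {
  if (is.null(noise$seed)) return(force(expr))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(noise$seed)
  force(expr)
}

clamp_percent <- function(x, clamp) {
  n_clamped <- sum(x < 0)
  if (clamp) x <- pmax(x, 0)
  list(x = x, n_clamped = n_clamped)
}

#' Generate a synthetic migration dataset
#'
#' Simulates the adoptive-transfer experiment: organ percentages of the
#' seven measured series (liver reported as live plus dead cells) at the
#' sampling grid, plus normal noise.
#'
#' @param params A [recirc_params] object (the data-generating truth).
#' @param times Sampling times in minutes; defaults to the 13-point
#'   experimental grid ([migration_sampling_times()]).
#' @param noise A [noise_spec()].
#' @return A tibble with columns `organ`, `time`, `percent` satisfying the
#'   migration-dataset invariants; attribute `"n_clamped"` counts clamped
#'   negatives and `"truth"` stores the generating parameters.
#' @examples
#' d <- generate_migration_dataset(reference_params(),
#'                                 noise = noise_spec(seed = 1))
#' head(d)
#' @export
generate_migration_dataset <- function(params,
                                       times = migration_sampling_times(),
                                       noise = noise_spec()) {
  stopifnot(inherits(params, "recirc_params"), inherits(noise, "recirc_noise"))
  params$cannulation <- FALSE
  tr <- simulate_trajectory(params, sort(unique(times)))
  d <- trajectory_observables(tr)
  d$percent <- with_noise_seed(noise, {
    d$percent + stats::rnorm(nrow(d), 0, noise$sd_migration)
  })
  cl <- clamp_percent(d$percent, noise$clamp_negative)
  d$percent <- cl$x
  attr(d, "n_clamped") <- cl$n_clamped
  attr(d, "truth") <- params
  d
}

#' Generate a synthetic cannulation dataset
#'
#' Simulates thoracic-duct collection: the duct output rate (percent of
#' transferred cells per hour) at 90-minute intervals over 45 hours by
#' default, plus normal noise.
#'
#' @inheritParams generate_migration_dataset
#' @param f Thoracic-duct routing fraction.
#' @param nu Cannulation-induced exit-decline rate (per minute).
#' @param times Collection times in minutes; defaults to
#'   [cannulation_sampling_times()].
#' @return A tibble with columns `time`, `rate`; attributes as above.
#' @export
generate_cannulation_dataset <- function(params,
                                         f = params$thoracic_fraction,
                                         nu = params$exit_decline,
                                         times = cannulation_sampling_times(),
                                         noise = noise_spec()) {
  stopifnot(inherits(params, "recirc_params"), inherits(noise, "recirc_noise"))
  check_fraction(f, "f")
  check_scalar_rate(nu, "nu")
  params$cannulation <- TRUE
  params$thoracic_fraction <- f
  params$exit_decline <- nu
  tt <- sort(unique(times))
  tr <- simulate_trajectory(params, tt)
  d <- tibble::tibble(time = tr$time, rate = tr$duct_rate)
  d$rate <- with_noise_seed(noise, {
    d$rate + stats::rnorm(nrow(d), 0, noise$sd_cannulation)
  })
  cl <- clamp_percent(d$rate, noise$clamp_negative)
  d$rate <- cl$x
  attr(d, "n_clamped") <- cl$n_clamped
  attr(d, "truth") <- params
  d
}

#' Generate a synthetic stimulated/control popliteal-node dataset
#'
#' Simulates accumulation of label in an antigen-stimulated and a resting
#' popliteal node, modelled as auxiliary chains fed by the blood trajectory
#' of `params`. The stimulated node's entry and exit rates are the control
#' rates multiplied by `entry_ratio` and `exit_ratio`.
#'
#' @inheritParams generate_migration_dataset
#' @param entry Control-node entry rate from blood (per minute).
#' @param exit Control-node per-stage exit rate (per minute).
#' @param entry_ratio,exit_ratio Stimulated/control rate ratios (> 0).
#' @param sd Noise SD in percent units (node percentages are small, so the
#'   default is smaller than the whole-organ migration noise).
#' @param seed,clamp_negative As in [noise_spec()].
#' @return A tibble with columns `node`, `time`, `percent`.
#' @export
generate_stimulated_node_dataset <- function(params,
                                             entry = 5e-4, exit = 0.0034,
                                             entry_ratio = 4, exit_ratio = 1,
                                             times = migration_sampling_times(),
                                             sd = 0.05, seed = NULL,
                                             clamp_negative = TRUE) {
  stopifnot(inherits(params, "recirc_params"))
  if (entry_ratio <= 0 || exit_ratio <= 0) {
    stop("ratios must be > 0", call. = FALSE)
  }
  k <- params$n_subcompartments
  tt <- sort(unique(times))
  bf <- blood_interpolator(params, max(tt))
  d <- dplyr::bind_rows(
    tibble::tibble(node = "stimulated", time = tt,
                   percent = simulate_node_chain(entry * entry_ratio,
                                                 exit * exit_ratio, k, tt, bf)),
    tibble::tibble(node = "control", time = tt,
                   percent = simulate_node_chain(entry, exit, k, tt, bf))
  )
  noise <- noise_spec(sd_migration = sd, seed = seed,
                      clamp_negative = clamp_negative)
  d$percent <- with_noise_seed(noise, {
    d$percent + stats::rnorm(nrow(d), 0, sd)
  })
  cl <- clamp_percent(d$percent, clamp_negative)
  d$percent <- cl$x
  attr(d, "n_clamped") <- cl$n_clamped
  attr(d, "truth") <- list(entry = entry, exit = exit,
                           entry_ratio = entry_ratio, exit_ratio = exit_ratio)
  d
}
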