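# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a recirculation model fit
#'
#' One row per free parameter with the estimate on the natural scale and,
#' if [bootstrap_ci()] has been run on the fit, the 95% bootstrap interval.
#'
#' @param x A `recirc_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` and (when available)
#'   `conf.low`, `conf.high`.
#' @export
tidy.recirc_fit <- function(x, ...) {
  if (!is.null(x$ci)) return(x$ci)
  est <- if (inherits(x, "recirc_node_fit")) x$estimates else natural_estimates(x)
  tibble::tibble(term = names(est), estimate = unname(est))
}

#' Glance at a recirculation model fit
#'
#' @param x A `recirc_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the objective value(s), sample sizes,
#'   degrees of freedom, AIC and convergence flag.
#' @export
glance.recirc_fit <- function(x, ...) {
  out <- tibble::tibble(
    ssr = x$ssr, n = x$n, n_free = x$n_free,
    df.residual = x$n - x$n_free,
    aic = ls_aic(x), converged = x$converged
  )
  if (inherits(x, "recirc_joint_fit")) {
    out$ssr_migration <- x$ssr1
    out$ssr_cannulation <- x$ssr2
    out$sigma_migration <- x$sigma1
    out$sigma_cannulation <- x$sigma2
    out$logLik <- x$logLik
  }
  out
}

#' Plot a simulated trajectory
#'
#' Organ percentages over time; time on a log axis by default since the
#' dynamics span minutes to days.
#'
#' @param object A `recirc_trajectory` from [simulate_trajectory()].
#' @param log_time Use a log10 time axis (drops t = 0).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recirc_trajectory <- function(object, log_time = TRUE, ...) {
  d <- trajectory_observables(object)
  if (log_time) d <- dplyr::filter(d, .data$time > 0)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$percent,
                                       colour = .data$organ)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time after transfer (min)",
                  y = "percent of transferred cells", colour = "organ") +
    ggplot2::theme_minimal()
  if (log_time) p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot a migration-data fit
#'
#' Observed organ percentages (points) with model fits (lines).
#'
#' @param object A `recirc_fit` from [fit_migration()] or [joint_fit()].
#' @param log_time Use a log10 time axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recirc_fit <- function(object, log_time = TRUE, ...) {
  grid <- exp(seq(log(max(min(object$data$time), 0.5)),
                  log(max(object$data$time)), length.out = 120))
  p <- object$params
  p$cannulation <- FALSE
  tr <- simulate_trajectory(p, grid)
  lines <- trajectory_observables(tr)
  pts <- object$data
  gg <- ggplot2::ggplot(pts, ggplot2::aes(.data$time, .data$percent,
                                          colour = .data$organ)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = lines) +
    ggplot2::labs(x = "time after transfer (min)",
                  y = "percent of transferred cells", colour = "organ") +
    ggplot2::theme_minimal()
  if (log_time) gg <- gg + ggplot2::scale_x_log10()
  gg
}

#' Plot a predicted cannulation output curve
#'
#' @param object A `recirc_cannulation` from [predict_cannulation()].
#' @param ... Unused.
#' @return A ggplot object showing the duct output rate over time.
#' @export
autoplot.recirc_cannulation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time / 60, .data$duct_rate)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time since cannulation (h)",
                  y = "duct output (% of transferred cells per h)") +
    ggplot2::theme_minimal()
}
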