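# Forward simulation of the compartment model.

#' Simulate the recirculation trajectory
#'
#' Integrates the compartment model forward in time from a bolus of 100% of
#' labelled cells in the blood (or a user-supplied initial state). The
#' trajectory tracks the blood, lung, live and dead liver pools, spleen, the
#' LN/PP sub-compartment chains, the cumulative removed pool and — in
#' cannulation mode — the cumulative label collected from the thoracic duct.
#'
#' Integration uses a stiff-capable solver (`deSolve::lsoda`) with a compiled
#' right-hand side; tolerances default to `rtol = 1e-9`, `atol = 1e-12`
#' because the rate constants span three orders of magnitude.
#'
#' @param params A [recirc_params] object.
#' @param times Numeric vector of output times in minutes, sorted,
#'   non-negative.
#' @param init Optional full initial state vector (advanced use; names as in
#'   the trajectory columns). Defaults to 100% of label in blood.
#' @param rtol,atol Solver tolerances.
#'
#' @return A tibble of class `recirc_trajectory` with one row per time and
#'   columns `time`, the individual states, organ totals (`liver` =
#'   live + dead, `scln`/`mln`/`pp` = chain sums), `duct_rate` (instantaneous
#'   thoracic-duct output in percent of transferred cells per hour) and
#'   `total` (accounting check; equals 100 up to integration tolerance).
#' @examples
#' tr <- simulate_trajectory(reference_params(), times = c(0, 1, 10, 60, 1440))
#' tr[, c("time", "blood", "lung", "spleen", "scln")]
#' @export
simulate_trajectory <- function(params, times, init = NULL,
                                rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(params, "recirc_params"))
  if (length(times) < 1 || any(!is.finite(times))) {
    stop("`times` must be finite", call. = FALSE)
  }
  if (any(times < 0)) stop("`times` must be non-negative", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  k <- params$n_subcompartments
  nms <- state_names(k)
  if (is.null(init)) {
    init <- stats::setNames(numeric(length(nms)), nms)
    init["blood"] <- 100
  } else {
    if (length(init) != length(nms)) {
      stop("`init` must have length ", length(nms), call. = FALSE)
    }
    init <- stats::setNames(as.numeric(init), nms)
  }

  prepend0 <- times[1] > 0
  solve_times <- if (prepend0) c(0, times) else times
  out <- deSolve::ode(
    y = init, times = solve_times, func = "derivs",
    parms = parms_vector(params), dllname = "recirc",
    initfunc = "initparms", method = "lsoda",
    rtol = rtol, atol = atol
  )
  diag_ok <- attr(out, "istate")[1]
  if (!is.null(diag_ok) && diag_ok < 0) {
    stop("ODE solver failed to meet the requested tolerance", call. = FALSE)
  }
  out <- as.data.frame(out)
  if (anyNA(out)) stop("ODE solution contains non-finite values", call. = FALSE)
  if (prepend0) out <- out[-1, , drop = FALSE]

  tr <- tibble::as_tibble(out)
  tr <- dplyr::rename(tr, !!!c(time = "time"))
  scln_cols <- paste0("scln", seq_len(k))
  mln_cols <- paste0("mln", seq_len(k))
  pp_cols <- paste0("pp", seq_len(k))
  e <- if (params$cannulation) exp(-params$exit_decline * tr$time) else 1
  tr$liver <- tr$liver_live + tr$liver_dead
  tr$scln <- rowSums(tr[, scln_cols, drop = FALSE])
  tr$mln <- rowSums(tr[, mln_cols, drop = FALSE])
  tr$pp <- rowSums(tr[, pp_cols, drop = FALSE])
  # instantaneous duct output, percent of transferred cells per hour
  tr$duct_rate <- if (params$cannulation) {
    60 * e * (params$exit[["mln"]] * tr[[mln_cols[k]]] +
                params$thoracic_fraction * params$exit[["scln"]] * tr[[scln_cols[k]]])
  } else {
    0
  }
  tr$total <- tr$blood + tr$lung + tr$liver + tr$spleen +
    tr$scln + tr$mln + tr$pp + tr$removed + tr$duct_collected
  attr(tr, "params") <- params
  class(tr) <- c("recirc_trajectory", class(tr))
  tr
}

#' The 13-point organ-sampling grid of the migration experiments
#'
#' Sampling times (minutes) at which organs were harvested after adoptive
#' transfer: 1, 2, 5, 10 and 30 minutes, then 1, 2.5, 6, 9, 12, 15, 18 and
#' 24 hours.
#'
#' @return Numeric vector of 13 times in minutes.
#' @export
migration_sampling_times <- function() {
  c(1, 2, 5, 10, 30, 60, 150, 360, 540, 720, 900, 1080, 1440)
}

#' The 90-minute cannulation collection grid over 45 hours
#'
#' @return Numeric vector of times in minutes (90-minute intervals).
#' @export
cannulation_sampling_times <- function() {
  seq(90, 45 * 60, by = 90)
}

# Organ observables (the seven measured series) from a trajectory, long form.
trajectory_observables <- function(tr) {
  tr |>
    dplyr::select(dplyr::all_of(c("time", recirc_organs()))) |>
    tidyr::pivot_longer(-"time", names_to = "organ", values_to = "percent") |>
    dplyr::arrange(.data$organ, .data$time)
}
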