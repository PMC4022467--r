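# Closed-form steady state and residence-time arithmetic.

#' Closed-form steady-state distribution of label across organs
#'
#' With removal switched off (no loss from the system, the convention used
#' for long-run predictions) and no cannulation, the linear flow network
#' admits a closed-form balance solution. Relative to the blood content `B`,
#' each single-compartment organ holds `entry/exit * B`; each of the `k`
#' stages of a LN/PP chain holds `throughput/exit * B`, where the MLN
#' throughput includes the Peyer's-patch efflux (PP drains into MLN, not
#' into blood). Percentages are normalized so that the seven organs total
#' 100%.
#'
#' @param params A [recirc_params] object. `removal` and `cannulation` are
#'   ignored (forced to 0 / off).
#' @return A tibble with columns `organ` and `percent`.
#' @examples
#' steady_state(reference_params())
#' @export
steady_state <- function(params) {
  stopifnot(inherits(params, "recirc_params"))
  s <- params$entry
  m <- params$exit
  k <- params$n_subcompartments
  thru <- c(lung = s[["lung"]], liver = s[["liver"]], spleen = s[["spleen"]],
            scln = s[["scln"]], mln = s[["mln"]] + s[["pp"]], pp = s[["pp"]])
  bad <- names(thru)[thru > 0 & m[names(thru)] == 0]
  if (length(bad)) {
    stop("unbounded accumulation: zero exit rate with positive inflow for ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  stages <- c(lung = 1, liver = 1, spleen = 1, scln = k, mln = k, pp = k)
  content <- ifelse(thru > 0, stages * thru / m[names(thru)], 0)
  w <- c(blood = 1, content)
  tibble::tibble(
    organ = recirc_organs(),
    percent = 100 * unname(w[recirc_organs()]) / sum(w)
  )
}

#' Mean residence time of lymphocytes in an organ
#'
#' For single-compartment organs (lung, liver, spleen) the mean residence
#' time is the reciprocal exit rate `1/m`; for the LN/PP chains it is `k/m`
#' (a `k`-stage chain with per-stage rate `m` has gamma-distributed transit
#' times with mean `k/m`); for blood it is the reciprocal of the total exit
#' rate from blood, `1/(sum(entry) + removal)`.
#'
#' @param params A [recirc_params] object.
#' @param organ Character vector of organs among
#'   `c("blood", "lung", "liver", "spleen", "scln", "mln", "pp")`.
#' @return Named numeric vector of mean residence times in minutes.
#' @examples
#' mean_residence_time(reference_params(), c("blood", "lung", "scln")) / 60
#' @export
mean_residence_time <- function(params, organ = recirc_organs()) {
  stopifnot(inherits(params, "recirc_params"))
  organ <- match.arg(organ, recirc_organs(), several.ok = TRUE)
  k <- params$n_subcompartments
  vapply(organ, function(o) {
    if (o == "blood") {
      denom <- sum(params$entry) + params$removal
      if (denom <= 0) stop("total exit rate from blood is zero", call. = FALSE)
      1 / denom
    } else {
      m <- params$exit[[o]]
      if (m <= 0) stop("zero exit rate for ", o, call. = FALSE)
      if (o %in% c("scln", "mln", "pp")) k / m else 1 / m
    }
  }, numeric(1))
}

#' Residence-time distribution in an organ
#'
#' Transit times through a `k`-stage chain with per-stage rate `m` follow a
#' gamma distribution with shape `k` and rate `m`; single-compartment organs
#' have exponential (shape 1) residence times.
#'
#' @param params A [recirc_params] object.
#' @param organ One of `lung`, `liver`, `spleen`, `scln`, `mln`, `pp`.
#' @param t_grid Non-empty numeric vector of times (minutes).
#' @return A tibble with columns `time` and `density` (per minute).
#' @examples
#' residence_time_distribution(reference_params(), "scln", 0:100 * 20)
#' @export
residence_time_distribution <- function(params, organ, t_grid) {
  stopifnot(inherits(params, "recirc_params"))
  organ <- match.arg(organ, tissue_organs())
  if (length(t_grid) == 0) stop("`t_grid` is empty", call. = FALSE)
  m <- params$exit[[organ]]
  if (m <= 0) stop("zero exit rate for ", organ, call. = FALSE)
  shape <- if (organ %in% c("scln", "mln", "pp")) params$n_subcompartments else 1
  tibble::tibble(
    time = as.numeric(t_grid),
    density = stats::dgamma(as.numeric(t_grid), shape = shape, rate = m)
  )
}

# Full steady-state *state vector* (stage-resolved), scaled to total 100.
# Used to pre-equilibrate the system for blockade simulations.
steady_state_init <- function(params) {
  s <- params$entry
  m <- params$exit
  k <- params$n_subcompartments
  per_stage <- function(thru, mm) if (thru > 0) thru / mm else 0
  y <- c(
    blood = 1,
    lung = per_stage(s[["lung"]], m[["lung"]]),
    liver_live = per_stage(s[["liver"]], m[["liver"]]),
    liver_dead = 0,
    spleen = per_stage(s[["spleen"]], m[["spleen"]]),
    rep(per_stage(s[["scln"]], m[["scln"]]), k),
    rep(per_stage(s[["mln"]] + s[["pp"]], m[["mln"]]), k),
    rep(per_stage(s[["pp"]], m[["pp"]]), k),
    removed = 0, duct_collected = 0
  )
  y <- 100 * y / sum(y)
  stats::setNames(y, state_names(k))
}
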