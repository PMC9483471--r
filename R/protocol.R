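#' Configuration of a varied-FiO2 desaturation protocol
#'
#' Describes the stair-stepped SpO2 descent a study administrator induces by
#' lowering the inspired oxygen fraction: an initial resting segment followed
#' by a sequence of plateaus, one target level drawn inside each configured
#' range, connected by first-order-lag transitions. Gas physiology itself is
#' not modeled; the trajectory of the resulting SpO2 is simulated directly,
#' because only that trajectory matters to the downstream analysis.
#'
#' @param plateau_ranges list of `c(lo, hi)` SpO2 intervals (% SpO2),
#'   disjoint and ordered descending. Defaults to the four levels used in
#'   varied-FiO2 validation: above 93 (resting), 89-93, 80-88, 70-79.
#' @param plateau_hold_s seconds each plateau must be held after the
#'   transition has settled (default 30).
#' @param step_interval_s seconds allotted per plateau, transition included
#'   (default 210).
#' @param total_duration_s total recording length in seconds; the default 900
#'   (15 min) sits inside the 14-19 min session lengths typical of these
#'   protocols.
#' @param transition_time_constant_s first-order lag time constant of the
#'   SpO2 response to a step change in inspired oxygen (default 20 s).
#' @param resting_spo2 baseline SpO2 breathing room air (default 98).
#' @param seed integer seed controlling the sampled plateau targets.
#' @return A list of class `protocol_config`.
#' @export
protocol_config <- function(plateau_ranges = list(c(93, 100), c(89, 93),
                                                  c(80, 88), c(70, 79)),
                            plateau_hold_s = 30,
                            step_interval_s = 210,
                            total_duration_s = 900,
                            transition_time_constant_s = 20,
                            resting_spo2 = 98,
                            seed = 1L) {
  rng <- vapply(plateau_ranges, function(r) r, numeric(2))
  if (any(rng < 60) || any(rng > 100)) {
    stop("plateau ranges must lie within [60, 100] % SpO2")
  }
  if (length(plateau_ranges) > 1) {
    los <- rng[1, ]
    his <- rng[2, ]
    if (any(diff(his) >= 0) || any(los[-length(los)] < his[-1])) {
      stop("plateau ranges must be disjoint and ordered descending")
    }
  }
  stopifnot(plateau_hold_s > 0, step_interval_s > 0, total_duration_s > 0,
            transition_time_constant_s > 0,
            resting_spo2 >= 60, resting_spo2 <= 100)
  structure(list(plateau_ranges = plateau_ranges,
                 plateau_hold_s = plateau_hold_s,
                 step_interval_s = step_interval_s,
                 total_duration_s = total_duration_s,
                 transition_time_constant_s = transition_time_constant_s,
                 resting_spo2 = resting_spo2,
                 seed = as.integer(seed)),
            class = "protocol_config")
}

#' Construct a reference oximeter trace
#'
#' @param time_s reading timestamps in seconds (1 Hz in this package).
#' @param spo2 SpO2 readings in percent.
#' @return A data frame of class `oximeter_trace` with columns
#'   `time_s`, `spo2`.
#' @export
oximeter_trace <- function(time_s, spo2) {
  stopifnot(length(time_s) == length(spo2), all(is.finite(spo2)))
  structure(data.frame(time_s = as.numeric(time_s), spo2 = as.numeric(spo2)),
            class = c("oximeter_trace", "data.frame"))
}

#' Simulate a stair-stepped SpO2 trajectory
#'
#' Produces 1 Hz ground-truth readings for one subject: the subject rests at
#' `resting_spo2`, then descends through one plateau target per configured
#' range. Targets are drawn uniformly inside their range (seeded), transitions
#' follow a first-order lag toward the new target, and each plateau is held
#' for at least `plateau_hold_s` before the next step. Values never drop
#' below 60.
#'
#' @param protocol a [protocol_config()].
#' @return An [oximeter_trace()] with `total_duration_s` readings at 1 Hz
#'   (t = 0, 1, ..., total - 1).
#' @export
simulate_spo2_trajectory <- function(protocol) {
  stopifnot(inherits(protocol, "protocol_config"))
  n_plat <- length(protocol$plateau_ranges)
  need <- n_plat * protocol$step_interval_s
  rest_s <- protocol$total_duration_s - need
  if (rest_s < 0) {
    stop(sprintf(
      "total_duration_s = %g too short to visit all %d plateaus: need %g s (shortfall %g s)",
      protocol$total_duration_s, n_plat, need, -rest_s))
  }
  if (protocol$step_interval_s < protocol$plateau_hold_s) {
    stop("step_interval_s must be at least plateau_hold_s")
  }
  targets <- with_seed(protocol$seed, {
    vapply(protocol$plateau_ranges,
           function(r) stats::runif(1, min(r), max(r)), numeric(1))
  })
  targets <- clamp(targets, 60, 100)

  tt <- seq(0, protocol$total_duration_s - 1)
  tau <- protocol$transition_time_constant_s
  # segment boundaries: resting segment then one interval per plateau
  starts <- c(0, rest_s + protocol$step_interval_s * (seq_len(n_plat) - 1))
  ends <- c(starts[-1], protocol$total_duration_s)
  seg_target <- c(protocol$resting_spo2, targets)
  # SpO2 at each segment start, from the first-order-lag closed form
  seg_v0 <- numeric(length(starts))
  seg_v0[1] <- protocol$resting_spo2
  for (k in seq_along(starts)[-1]) {
    prev_len <- ends[k - 1] - starts[k - 1]
    seg_v0[k] <- seg_target[k - 1] +
      (seg_v0[k - 1] - seg_target[k - 1]) * exp(-prev_len / tau)
  }
  k <- findInterval(tt, starts)
  spo2 <- seg_target[k] + (seg_v0[k] - seg_target[k]) * exp(-(tt - starts[k]) / tau)
  oximeter_trace(tt, clamp(spo2, 60, 100))
}
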