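#' Parameters for the locomotor activity simulator
#'
#' Defines one animal's simulated wheel-running pattern: a nocturnal activity
#' phase of duration `alpha_h` recurring with period `tau_h`, an optional
#' mid-activity break ("siesta"), and count noise. Under constant regimes the
#' onset drift against the 24-h clock is fully determined by the period
#' (`drift_per_cycle_min = (tau_h - 24) * 60`), so either may be given and the
#' other is derived; supplying both requires them to agree.
#'
#' @param tau_h Free-running (or driven) period in hours.
#' @param drift_per_cycle_min Signed onset drift per cycle in minutes
#'   (advance negative); alternative way to specify `tau_h` under constant
#'   regimes.
#' @param alpha_h Activity-phase duration in hours; must be `< tau_h`.
#' @param onset_phase0_h First-cycle activity onset in hours after record
#'   start. Default 12 h (the former lights-off, records start at
#'   (subjective) lights-on). Ignored when masking applies.
#' @param rate_active,rate_rest Mean wheel revolutions per minute during the
#'   activity phase and at rest. `rate_active > rate_rest` required unless
#'   `arrhythmic`.
#' @param break_offset_h,break_duration_h Optional break: offset of the break
#'   start into the activity phase and its duration (hours). One break per
#'   cycle.
#' @param masking If `TRUE` and the regime is light-driven, the activity onset
#'   locks to lights-off every cycle (period 24 h, no drift).
#' @param arrhythmic If `TRUE`, activity is rate-homogeneous across the cycle
#'   (same expected total, no phase structure).
#' @param noise `"poisson"` (default), `"negbin"` (overdispersed, see
#'   `negbin_dispersion`) or `"none"` (expected counts, rounded).
#' @param negbin_dispersion Negative-binomial size parameter.
#' @param seed Integer seed; identical parameters and seed give identical
#'   output.
#' @return An object of class `sim_activity_params`.
#' @export
sim_activity_params <- function(tau_h = 24, drift_per_cycle_min = NULL,
                                alpha_h = 12, onset_phase0_h = 12,
                                rate_active = 10, rate_rest = 0.3,
                                break_offset_h = NULL, break_duration_h = NULL,
                                masking = TRUE, arrhythmic = FALSE,
                                noise = c("poisson", "negbin", "none"),
                                negbin_dispersion = 5, seed = 1L) {
  noise <- match.arg(noise)
  if (!is.null(drift_per_cycle_min)) {
    tau_from_drift <- 24 + drift_per_cycle_min / 60
    if (!missing(tau_h) && abs(tau_h - tau_from_drift) > 1e-8)
      stop("'tau_h' and 'drift_per_cycle_min' disagree: drift per cycle is (tau_h - 24 h) * 60")
    tau_h <- tau_from_drift
  }
  stopifnot_scalar(tau_h, "tau_h", 1e-3)
  stopifnot_scalar(alpha_h, "alpha_h", 1e-3)
  if (alpha_h >= tau_h) stop("'alpha_h' must be smaller than 'tau_h'")
  stopifnot_scalar(rate_active, "rate_active", 0)
  stopifnot_scalar(rate_rest, "rate_rest", 0)
  if (!arrhythmic && rate_active <= rate_rest)
    stop("'rate_active' must exceed 'rate_rest' for a rhythmic animal")
  if (!is.null(break_duration_h)) {
    stopifnot_scalar(break_offset_h, "break_offset_h", 0, alpha_h)
    stopifnot_scalar(break_duration_h, "break_duration_h", 0, alpha_h)
    if (break_offset_h + break_duration_h > alpha_h)
      stop("break must lie inside the activity phase")
  }
  structure(
    list(tau_h = tau_h, alpha_h = alpha_h, onset_phase0_h = onset_phase0_h,
         drift_per_cycle_min = (tau_h - 24) * 60,
         rate_active = rate_active, rate_rest = rate_rest,
         break_offset_h = break_offset_h, break_duration_h = break_duration_h,
         masking = isTRUE(masking), arrhythmic = isTRUE(arrhythmic),
         noise = noise, negbin_dispersion = negbin_dispersion,
         seed = as.integer(seed)),
    class = "sim_activity_params")
}

#' Simulate a wheel-running activity record with known ground truth
#'
#' Generates a binned count series for one animal under a light schedule. The
#' record starts at (subjective) lights-on, i.e. ZT0/CT0. Under light-driven
#' regimes with masking the onset locks to lights-off each 24-h cycle;
#' otherwise activity free-runs with period `tau_h`. Counts are drawn per bin
#' from the configured noise law around the rate profile (active rate inside
#' `[onset, onset + alpha)` minus any planted break, rest rate elsewhere;
#' homogeneous rate if arrhythmic).
#'
#' @param params A [sim_activity_params()].
#' @param schedule A [light_schedule()].
#' @param n_days Number of simulated days (>= 9, so at least 8 cycles remain
#'   analyzable after discarding the first day).
#' @param bin_minutes Simulation bin width in minutes (default 1; must divide
#'   60). Re-bin downstream with [bin_activity()].
#' @return A list of class `sim_activity` with elements `record` (an
#'   [activity_record()]) and `truth` (per-cycle onset/offset hours, true tau,
#'   alpha, rho, the cumulative 8-cycle onset shift `delta_8_min` against the
#'   24-h clock, planted break durations, and the expected share of activity
#'   falling in the (subjective) day window).
#' @examples
#' p <- sim_activity_params(tau_h = 23.7, alpha_h = 12, masking = FALSE, seed = 7)
#' sim <- simulate_activity(p, light_schedule("DD"), n_days = 10)
#' sim$truth$delta_8_min
#' @export
simulate_activity <- function(params, schedule, n_days = 12, bin_minutes = 1) {
  if (!inherits(params, "sim_activity_params")) stop("'params' must be sim_activity_params")
  if (n_days < 9) stop("'n_days' must be at least 9")
  if (abs(60 %% bin_minutes) > 1e-9) stop("'bin_minutes' must divide 60")

  masked <- params$masking && is_driven(schedule)
  period <- if (masked) 24 else params$tau_h
  onset0 <- if (masked) schedule$photoperiod else params$onset_phase0_h
  total_h <- n_days * 24
  bin_h <- bin_minutes / 60
  n_bins <- as.integer(round(total_h / bin_h))
  t0 <- (seq_len(n_bins) - 1) * bin_h

  onsets <- onset0 + period * (0:ceiling(total_h / period))
  onsets <- onsets[onsets < total_h]

  lambda <- rep(params$rate_rest * bin_minutes, n_bins)
  if (params$arrhythmic) {
    lam <- (params$alpha_h * params$rate_active +
            (params$tau_h - params$alpha_h) * params$rate_rest) / params$tau_h
    lambda <- rep(lam * bin_minutes, n_bins)
  } else {
    for (on in onsets) {
      act <- t0 >= on - 1e-9 & t0 < on + params$alpha_h - 1e-9
      lambda[act] <- params$rate_active * bin_minutes
      if (!is.null(params$break_duration_h)) {
        brk <- t0 >= on + params$break_offset_h - 1e-9 &
               t0 < on + params$break_offset_h + params$break_duration_h - 1e-9
        lambda[brk] <- params$rate_rest * bin_minutes
      }
    }
  }

  set.seed(params$seed)
  counts <- switch(params$noise,
    poisson = stats::rpois(n_bins, lambda),
    negbin = stats::rnbinom(n_bins, mu = lambda, size = params$negbin_dispersion),
    none = round(lambda))

  anchor <- day_anchor_clock(schedule)
  start_time <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC") + anchor * 3600
  record <- activity_record(counts, bin_minutes, start_time, schedule)

  complete <- onsets + params$alpha_h <= total_h + 1e-9
  day_share <- {
    zt <- t0 %% 24  # record starts at ZT0/CT0
    tot <- sum(lambda)
    if (tot > 0) sum(lambda[zt < 12]) / tot else NA_real_
  }
  truth <- list(
    onsets_h = onsets[complete],
    offsets_h = onsets[complete] + params$alpha_h,
    tau_h = period,
    alpha_h = if (params$arrhythmic) NA_real_ else params$alpha_h,
    rho_h = if (params$arrhythmic) NA_real_ else period - params$alpha_h,
    delta_8_min = if (params$arrhythmic) NA_real_ else (period - 24) * 60 * 8,
    break_duration_h = if (params$arrhythmic) NULL else params$break_duration_h,
    day_share = day_share,
    arrhythmic = params$arrhythmic)
  structure(list(record = record, truth = truth), class = "sim_activity")
}
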