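# Activity onsets, phase parameters and activity totals.

#' Detect per-cycle activity onsets and offsets
#'
#' Cycles of length `tau_h` are tiled from the first detected onset. Within
#' each cycle window, the onset is the start of the first run of at least
#' `min_active_bins` bins above threshold that is preceded by a quiescent
#' window of `min_quiescent_bins` bins (window mean below threshold); the
#' offset is found symmetrically from the cycle's end (the end of the last
#' qualifying run followed by such a quiescent window). The threshold is
#' `active_threshold_frac` times the record mean. Gating quiescence on the
#' window mean rather than on every single bin makes the rule robust to
#' isolated above-threshold rest bins under count noise. A small search
#' margin absorbs bin-level jitter of onsets around the tiling grid.
#'
#' @param record An [activity_record()] (typically 6-min bins).
#' @param tau_h Cycle length in hours (from [estimate_tau()]).
#' @param active_threshold_frac Threshold as a fraction of the record mean
#'   count (default 0.25).
#' @param min_active_bins Minimum run length (bins) that counts as sustained
#'   activity (default 3).
#' @param min_quiescent_bins Length (bins) of the quiescent window required
#'   before an onset / after an offset; its mean must lie below threshold
#'   (default 6).
#' @param search_margin_h Hours by which each cycle window may extend before
#'   its nominal start when searching (default 2).
#' @return An object of class `onset_series`: `onsets_h`, `offsets_h` (hours
#'   from record start, `NA` for cycles where no qualifying run was found),
#'   `cycles_used`, `missing`. More than 25% missing cycles is an error.
#' @examples
#' sched <- light_schedule("DD")
#' x <- rep(c(rep(0, 720), rep(10, 720)), 10)  # active minutes 720-1439 daily
#' rec <- activity_record(x, 1, "2024-01-01", sched)
#' detect_onsets(rec, 24)$onsets_h[1:3]  # 12, 36, 60
#' @export
detect_onsets <- function(record, tau_h, active_threshold_frac = 0.25,
                          min_active_bins = 3, min_quiescent_bins = 6,
                          search_margin_h = 2) {
  x <- record$counts
  bin_h <- record$bin_minutes / 60
  thr <- active_threshold_frac * mean(x)
  runs <- true_runs(x > thr)
  if (nrow(runs) == 0) stop("no activity above threshold; record looks arrhythmic or empty")
  # sustained runs: long enough AND clearly active (mean at least twice the
  # threshold), which suppresses chance runs of marginally supra-threshold
  # rest bins
  run_mean <- vapply(seq_len(nrow(runs)), function(i)
    mean(x[runs$start[i]:runs$end[i]]), 0)
  long <- runs$length >= min_active_bins & run_mean >= 2 * thr
  quiet_before <- vapply(runs$start, function(j) {
    if (j - min_quiescent_bins < 1) return(Inf)
    mean(x[(j - min_quiescent_bins):(j - 1L)])
  }, 0)
  quiet_after <- vapply(runs$end, function(j) {
    if (j + min_quiescent_bins > length(x)) return(Inf)
    mean(x[(j + 1L):(j + min_quiescent_bins)])
  }, 0)
  onset_ok <- long & quiet_before < thr
  offset_ok <- long & quiet_after < thr
  onset_t <- (runs$start[onset_ok] - 1) * bin_h
  offset_t <- runs$end[offset_ok] * bin_h
  if (length(onset_t) == 0) stop("no qualifying activity onset found")

  o1 <- onset_t[1]
  n_cycles <- max(1L, floor((record_duration_h(record) - o1) / tau_h))
  onsets <- offsets <- rep(NA_real_, n_cycles)
  for (k in seq_len(n_cycles)) {
    lo <- o1 + (k - 1) * tau_h - search_margin_h
    hi <- lo + tau_h
    cand <- onset_t[onset_t >= lo & onset_t < hi]
    if (length(cand) == 0) next
    onsets[k] <- cand[1]
    oc <- offset_t[offset_t > onsets[k] & offset_t <= onsets[k] + tau_h]
    if (length(oc) > 0) offsets[k] <- oc[length(oc)]
  }
  missing <- which(is.na(onsets) | is.na(offsets))
  if (length(missing) > 0.25 * n_cycles)
    stop("more than 25% of cycles have no detectable onset/offset")
  structure(list(onsets_h = onsets, offsets_h = offsets,
                 cycles_used = n_cycles - length(missing), missing = missing,
                 tau_h = tau_h),
            class = "onset_series")
}

#' @export
print.onset_series <- function(x, ...) {
  cat(sprintf("Onset series: %d usable cycles (of %d) at tau %.2f h\n",
              x$cycles_used, length(x$onsets_h), x$tau_h))
  invisible(x)
}

#' Phase parameters from an onset series
#'
#' Alpha is the mean onset-to-offset duration over the first `n_shifts`
#' usable cycles; delta is the cumulative onset shift over `n_shifts`
#' successive cycles measured against the 24-h clock (advances negative,
#' delays positive), which telescopes to
#' `onset[first + n_shifts] - onset[first] - 24 * n_shifts`; rho is
#' `tau_h - alpha` exactly.
#'
#' @param onsets An [detect_onsets()] result.
#' @param tau_h Rhythm period in hours.
#' @param n_shifts Number of successive cycle-to-cycle shifts summed into
#'   delta (default 8, requiring onsets for cycles 1 and `n_shifts + 1`).
#' @return List with `alpha_h`, `delta_h`, `rho_h`, `mean_shift_min`
#'   (= `delta_h * 60 / n_shifts`).
#' @export
derive_phase_params <- function(onsets, tau_h, n_shifts = 8) {
  on <- onsets$onsets_h
  off <- onsets$offsets_h
  usable <- which(!is.na(on) & !is.na(off))
  if (length(usable) < n_shifts) stop("fewer than 8 usable cycles")
  if (is.na(on[1]) || length(on) < n_shifts + 1 || is.na(on[n_shifts + 1]))
    stop("onsets for the first and the 9th cycle are required for delta")
  first8 <- utils::head(usable, n_shifts)
  alpha <- mean(off[first8] - on[first8])
  delta <- on[n_shifts + 1] - on[1] - 24 * n_shifts
  list(alpha_h = alpha, delta_h = delta, rho_h = tau_h - alpha,
       mean_shift_min = delta * 60 / n_shifts)
}

#' Mean activity per cycle
#'
#' Total counts over the analyzed span divided by the number of complete
#' cycles of length `tau_h` the record contains.
#'
#' @param record An [activity_record()].
#' @param tau_h Cycle length in hours.
#' @return Revolutions per cycle.
#' @export
overall_activity <- function(record, tau_h) {
  n_cycles <- floor(record_duration_h(record) / tau_h + 1e-9)
  if (n_cycles < 1) stop("record shorter than one cycle")
  nb <- floor(n_cycles * tau_h / (record$bin_minutes / 60) + 1e-9)
  sum(record$counts[seq_len(nb)]) / n_cycles
}

#' Day/night activity split
#'
#' Splits each complete 24-h cycle into the two 12-h windows anchored at
#' lights-on (ZT0-ZT12 day for light-driven regimes, including LD 16:8) or at
#' the acclimation lights-on (CT0-CT12 subjective day under DD/LL), and
#' returns per-cycle mean activity in each window.
#'
#' @param record An [activity_record()] with a schedule.
#' @return List with `day_activity`, `night_activity` (revolutions per cycle)
#'   and `percent_day` (= 100 * day / (day + night); `NA` for an all-zero
#'   record).
#' @export
split_day_night <- function(record) {
  anchor <- day_anchor_clock(record$schedule)
  if (is.na(anchor)) stop("schedule lacks a lights-on / acclimation anchor")
  bin_h <- record$bin_minutes / 60
  n_cycles <- floor(record_duration_h(record) / 24 + 1e-9)
  if (n_cycles < 1) stop("record shorter than one 24-h cycle")
  nb <- as.integer(round(n_cycles * 24 / bin_h))
  t_clock <- clock_hours(record$start_time) + bin_start_h(record)[seq_len(nb)]
  zt <- (t_clock - anchor) %% 24
  day <- zt < 12
  x <- record$counts[seq_len(nb)]
  day_act <- sum(x[day]) / n_cycles
  night_act <- sum(x[!day]) / n_cycles
  tot <- day_act + night_act
  list(day_activity = day_act, night_activity = night_act,
       percent_day = if (tot > 0) 100 * day_act / tot else NA_real_)
}

#' Activity-phase / rest-phase split on the folded waveform
#'
#' Folds the record at period `tau_h` into a mean waveform and finds the
#' half-cycle (`tau_h / 2`-long) circular window with maximal summed
#' activity; its start defines the beginning of the activity phase. Returns
#' per-cycle mean activity inside (activity phase) and outside (rest phase)
#' that window. Window-start ties are broken at the earliest phase.
#'
#' @param record An [activity_record()].
#' @param tau_h Rhythm period in hours.
#' @param rhythmic Set `FALSE` for an arrhythmic record: the split is still
#'   computed but the anchor is arbitrary and the result carries a warning
#'   flag.
#' @return List with `activity_phase_total`, `rest_phase_total` (revolutions
#'   per cycle), `window_start_h` (phase of the activity-half start) and
#'   `arbitrary_anchor` (logical flag).
#' @export
activity_rest_split <- function(record, tau_h, rhythmic = TRUE) {
  bin_h <- record$bin_minutes / 60
  nb <- as.integer(round(tau_h / bin_h))
  if (nb < 2) stop("period too short for the record's bin width")
  phase <- pmin(floor((bin_start_h(record) %% tau_h) / bin_h), nb - 1L)
  w <- as.numeric(tapply(record$counts, factor(phase, levels = 0:(nb - 1L)), mean,
                         default = 0))
  w[is.na(w)] <- 0
  half <- nb %/% 2
  w2 <- c(w, w)
  csum <- cumsum(c(0, w2))
  win <- csum[(1:nb) + half] - csum[1:nb]   # circular half-window sums
  s <- which(win >= max(win) - 1e-12)[1]    # tie -> earliest phase
  list(activity_phase_total = win[s],
       rest_phase_total = sum(w) - win[s],
       window_start_h = (s - 1) * bin_h,
       arbitrary_anchor = !isTRUE(rhythmic))
}

#' Detect mid-activity breaks
#'
#' Within each detected onset-offset span, reports maximal interior runs of
#' bins below `gap_threshold_frac` times the activity-phase mean that last at
#' least `min_gap_minutes`. Runs touching the span edges are not counted
#' (those reflect onset/offset placement, not a break).
#'
#' @param record An [activity_record()].
#' @param onsets An [detect_onsets()] result.
#' @param gap_threshold_frac Threshold fraction of the activity-phase mean
#'   (default 0.25).
#' @param min_gap_minutes Minimum break duration in minutes (default 15).
#' @return List with `per_cycle` (list of break-duration vectors, hours; empty
#'   when none) and `break_mean_h` (mean duration over all breaks, `NA` when
#'   no break was found).
#' @export
detect_breaks <- function(record, onsets, gap_threshold_frac = 0.25,
                          min_gap_minutes = 15) {
  bin_h <- record$bin_minutes / 60
  x <- record$counts
  per_cycle <- vector("list", length(onsets$onsets_h))
  for (k in seq_along(onsets$onsets_h)) {
    on <- onsets$onsets_h[k]; off <- onsets$offsets_h[k]
    per_cycle[[k]] <- numeric(0)
    if (is.na(on) || is.na(off)) next
    i0 <- as.integer(floor(on / bin_h + 1e-9)) + 1L
    i1 <- as.integer(round(off / bin_h))
    if (i1 > length(x)) i1 <- length(x)
    span <- x[i0:i1]
    thr <- gap_threshold_frac * mean(span)
    gaps <- true_runs(span < thr)
    if (nrow(gaps) == 0) next
    interior <- gaps$start > 1L & gaps$end < length(span)
    long <- gaps$length * record$bin_minutes >= min_gap_minutes - 1e-9
    per_cycle[[k]] <- gaps$length[interior & long] * bin_h
  }
  all_breaks <- unlist(per_cycle)
  list(per_cycle = per_cycle,
       break_mean_h = if (length(all_breaks)) mean(all_breaks) else NA_real_)
}
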