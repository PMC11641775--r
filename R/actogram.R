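#' Build an actogram matrix
#'
#' Cuts a record into rows of `row_period_h` hours (one plotted cycle per
#' row, trailing partial cycle dropped). In double-plot mode each row `i`
#' concatenates cycles `i` and `i + 1`, the standard raster used to read
#' onset drift by eye.
#'
#' @param record An [activity_record()].
#' @param row_period_h Row period in hours (default 24).
#' @param double_plot Concatenate consecutive cycles per row (default `TRUE`).
#' @return An object of class `actogram`: a numeric matrix (rows = plotted
#'   cycles) with attributes `row_period_h`, `double_plot`, `bin_minutes`.
#' @examples
#' sched <- light_schedule("LD12_12")
#' rec <- activity_record(rpois(14400, 1), 1, "2024-01-01 08:00:00", sched)
#' dim(build_actogram(rec, 24, double_plot = TRUE))  # 9 rows, 2880 cols
#' @export
build_actogram <- function(record, row_period_h = 24, double_plot = TRUE) {
  bin_h <- record$bin_minutes / 60
  nb <- as.integer(round(row_period_h / bin_h))
  if (abs(nb * bin_h - row_period_h) > 1e-6)
    stop("row period must be a whole number of bins")
  n_rows <- length(record$counts) %/% nb
  if (n_rows < 2) stop("record must span at least two row periods")
  m <- matrix(record$counts[seq_len(n_rows * nb)], nrow = n_rows, byrow = TRUE)
  if (double_plot) {
    m <- cbind(m[-n_rows, , drop = FALSE], m[-1, , drop = FALSE])
  }
  structure(m, row_period_h = row_period_h, double_plot = double_plot,
            bin_minutes = record$bin_minutes, animal_id = record$animal_id,
            class = c("actogram", "matrix"))
}

#' @export
plot.actogram <- function(x, max_frac = 0.95, ...) {
  m <- unclass(x)
  nr <- nrow(m)
  width_h <- ncol(m) * attr(x, "bin_minutes") / 60
  cap <- stats::quantile(m[m > 0], max_frac, names = FALSE)
  if (!is.finite(cap) || cap <= 0) cap <- 1
  graphics::plot(NULL, xlim = c(0, width_h), ylim = c(nr + 0.5, 0.5),
                 xlab = "time [h]", ylab = "cycle", yaxs = "i",
                 main = attr(x, "animal_id"), ...)
  bin_h <- attr(x, "bin_minutes") / 60
  for (r in seq_len(nr)) {
    h <- pmin(m[r, ] / cap, 1) * 0.9
    idx <- which(h > 0)
    if (length(idx))
      graphics::rect((idx - 1) * bin_h, r + 0.45, idx * bin_h, r + 0.45 - h[idx],
                     col = "black", border = NA)
  }
  invisible(x)
}

#' Full rhythm analysis of one activity record
#'
#' Runs the complete per-animal analysis: discards the first
#' `skip_first_h` hours after the lighting switch, computes the chi-square
#' periodogram over `period_range_h`, estimates tau, Qp and %Qp, classifies
#' rhythmicity, and — for rhythmic records — detects onsets/offsets at tau and
#' derives alpha, delta, rho and mid-activity breaks. Activity totals
#' (overall per tau cycle, day/night split per 24-h cycle, activity/rest
#' phase split on the folded waveform) are computed for every record. For
#' arrhythmic animals tau and all activity totals are still reported but
#' alpha, delta, rho and breaks are withheld (`NA`).
#'
#' @param record An [activity_record()] (6-min bins are the intended analysis
#'   resolution; re-bin with [bin_activity()]).
#' @param period_range_h Tested period window in hours (default `c(20, 28)`).
#' @param skip_first_h Hours discarded at the start of the record
#'   (default 24, the settling day after a lighting change).
#' @param significance_level Level of the rhythmicity scan (default 0.05).
#' @param onset_threshold_frac,min_active_bins,min_quiescent_bins Onset
#'   detector settings, see [detect_onsets()].
#' @param break_threshold_frac,min_gap_minutes Break detector settings, see
#'   [detect_breaks()].
#' @return An object of class `rhythm_params`: a list of the Table-style
#'   locomotor parameters (`tau_h`, `delta_h`, `alpha_h`, `rho_h`,
#'   `overall_activity`, `qp`, `percent_qp`, `rhythmic`, `day_activity`,
#'   `night_activity`, `percent_day`, `activity_phase_total`,
#'   `rest_phase_total`, `break_mean_h`) plus the underlying `periodogram`
#'   and `onsets` objects.
#' @examples
#' p <- sim_activity_params(tau_h = 23.7, alpha_h = 12, masking = FALSE, seed = 3)
#' sim <- simulate_activity(p, light_schedule("DD"), n_days = 12)
#' rp <- analyze_rhythm(bin_activity(sim$record, 6))
#' rp
#' @export
analyze_rhythm <- function(record, period_range_h = c(20, 28), skip_first_h = 24,
                           significance_level = 0.05,
                           onset_threshold_frac = 0.25, min_active_bins = 3,
                           min_quiescent_bins = 6,
                           break_threshold_frac = 0.25, min_gap_minutes = 15) {
  span <- if (skip_first_h > 0) window_record(record, skip_first_h) else record
  pg <- chi_square_periodogram(span, period_range_h[1], period_range_h[2])
  tau <- estimate_tau(pg)
  rhythmic <- classify_rhythmicity(pg, significance_level)

  dn <- split_day_night(span)
  ar <- activity_rest_split(span, tau, rhythmic = rhythmic)
  overall <- overall_activity(span, tau)

  alpha <- delta <- rho <- break_mean <- NA_real_
  onsets <- NULL
  if (rhythmic) {
    onsets <- tryCatch(
      detect_onsets(span, tau, onset_threshold_frac, min_active_bins,
                    min_quiescent_bins),
      error = function(e) NULL)
    if (!is.null(onsets)) {
      pp <- tryCatch(derive_phase_params(onsets, tau), error = function(e) NULL)
      if (!is.null(pp)) {
        alpha <- pp$alpha_h; delta <- pp$delta_h; rho <- pp$rho_h
      }
      break_mean <- detect_breaks(span, onsets, break_threshold_frac,
                                  min_gap_minutes)$break_mean_h
    }
  }

  structure(
    list(animal_id = record$animal_id,
         tau_h = tau, delta_h = delta, alpha_h = alpha, rho_h = rho,
         overall_activity = overall, qp = pg$peak_statistic,
         percent_qp = percent_qp(pg), rhythmic = rhythmic,
         day_activity = dn$day_activity, night_activity = dn$night_activity,
         percent_day = dn$percent_day,
         activity_phase_total = ar$activity_phase_total,
         rest_phase_total = ar$rest_phase_total,
         break_mean_h = break_mean,
         periodogram = pg, onsets = onsets),
    class = "rhythm_params")
}

rhythm_param_columns <- c("animal_id", "tau_h", "delta_h", "alpha_h", "rho_h",
                          "overall_activity", "qp", "percent_qp", "rhythmic",
                          "day_activity", "night_activity", "percent_day",
                          "activity_phase_total", "rest_phase_total",
                          "break_mean_h")

#' @export
as.data.frame.rhythm_params <- function(x, ...) {
  as.data.frame(x[rhythm_param_columns], stringsAsFactors = FALSE)
}

#' @export
print.rhythm_params <- function(x, ...) {
  cat(sprintf("Rhythm parameters for '%s' (%s)\n", x$animal_id,
              if (x$rhythmic) "rhythmic" else "arrhythmic"))
  cat(sprintf("  tau %.2f h  Qp %.1f  %%Qp %.1f\n", x$tau_h, x$qp, x$percent_qp))
  if (!is.na(x$alpha_h))
    cat(sprintf("  alpha %.2f h  rho %.2f h  delta %+.1f min (8 cycles)\n",
                x$alpha_h, x$rho_h, x$delta_h * 60))
  cat(sprintf("  overall %.0f rev/cycle  day %.0f  night %.0f  (%%day %.1f)\n",
              x$overall_activity, x$day_activity, x$night_activity, x$percent_day))
  if (!is.na(x$break_mean_h))
    cat(sprintf("  mean mid-activity break %.2f h\n", x$break_mean_h))
  invisible(x)
}
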