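dd <- light_schedule("DD")

test_that("square-wave onsets and offsets are recovered exactly", {
  rec <- square_wave_record(n_days = 10, onset_h = 12, alpha_h = 12)
  on <- detect_onsets(rec, 24)
  expect_equal(on$onsets_h[1:3], c(12, 36, 60))
  expect_equal(on$offsets_h[1:3], c(24, 48, 72))
  pp <- derive_phase_params(on, 24)
  expect_equal(pp$alpha_h, 12)
  expect_equal(pp$delta_h, 0)
  expect_equal(pp$rho_h, 12)
})

test_that("constant records are rejected by the onset detector", {
  rec <- activity_record(rep(5, 2400), 6, "2024-01-01", dd)
  expect_error(detect_onsets(rec, 24))
})

test_that("phase parameter arithmetic follows the clock-time convention", {
  # onsets recurring every 23.7 h advance 0.3 h per cycle against the clock
  on <- structure(list(onsets_h = 12 + 23.7 * (0:8),
                       offsets_h = 12 + 23.7 * (0:8) + 10,
                       cycles_used = 9L, missing = integer(0), tau_h = 23.7),
                  class = "onset_series")
  pp <- derive_phase_params(on, 23.7)
  expect_equal(pp$delta_h, -2.4)
  expect_equal(pp$mean_shift_min, -18)
  expect_equal(pp$alpha_h, 10)
  expect_equal(pp$rho_h, 23.7 - 10)
  # fewer than 9 onsets: delta undefined
  short <- structure(list(onsets_h = 12 + 23.7 * (0:6),
                          offsets_h = 22 + 23.7 * (0:6),
                          cycles_used = 7L, missing = integer(0), tau_h = 23.7),
                     class = "onset_series")
  expect_error(derive_phase_params(short, 23.7))
})

test_that("overall activity divides totals by complete cycles", {
  rec <- activity_record(rep(50, 240), 60, "2024-01-01", dd)  # 10 d, 12000 revs
  expect_equal(overall_activity(rec, 24), 1200)
  zero <- activity_record(rep(0, 240), 60, "2024-01-01", dd)
  expect_equal(overall_activity(zero, 24), 0)
  # halving tau doubles cycles and halves the per-cycle value on uniform data
  expect_equal(overall_activity(rec, 12), 600)
})

test_that("day/night split respects the anchor and conserves activity", {
  # record starts at lights-on (anchor 8): first 12 h are day
  sched <- light_schedule("LD12_12", lights_on_clock = 8)
  dark_only <- activity_record(rep(c(rep(0, 12), rep(10, 12)), 10), 60,
                               "2024-01-01 08:00:00", sched)
  s <- split_day_night(dark_only)
  expect_equal(s$percent_day, 0)
  expect_equal(s$night_activity, 120)

  uniform <- activity_record(rep(4, 240), 60, "2024-01-01 08:00:00", sched)
  expect_equal(split_day_night(uniform)$percent_day, 50)

  set.seed(11)
  for (i in 1:20) {
    x <- rpois(240 * sample(1:3, 1), runif(1, 1, 20))
    r <- activity_record(x, 60, "2024-01-01 08:00:00", sched)
    s <- split_day_night(r)
    expect_equal(s$day_activity + s$night_activity, overall_activity(r, 24),
                 tolerance = 1e-12)
  }
})

test_that("subjective day under DD uses the acclimation anchor", {
  sched <- light_schedule("DD", acclimation_lights_on = 8)
  # record starts at CT0 (clock 8): day window = first 12 h of each cycle
  x <- rep(c(rep(10, 12), rep(0, 12)), 9)
  rec <- activity_record(x, 60, "2024-01-01 08:00:00", sched)
  expect_equal(split_day_night(rec)$percent_day, 100)
  # same counts but started at CT12 -> all activity in subjective night
  rec2 <- activity_record(x, 60, "2024-01-01 20:00:00", sched)
  expect_equal(split_day_night(rec2)$percent_day, 0)
})

test_that("activity/rest half-cycle split matches a brute-force window scan", {
  rec <- square_wave_record(n_days = 8, onset_h = 12, alpha_h = 12)
  ar <- activity_rest_split(rec, 24)
  expect_equal(ar$rest_phase_total, 0)          # all counts inside activity half
  expect_equal(ar$window_start_h, 12)

  uniform <- activity_record(rep(4, 240), 60, "2024-01-01", dd)
  aru <- activity_rest_split(uniform, 24)
  expect_equal(aru$activity_phase_total, aru$rest_phase_total)
  expect_equal(aru$window_start_h, 0)           # tie broken at phase 0

  # asymmetric planted waveform vs exhaustive scan over all bin starts
  set.seed(33)
  wave <- rpois(24, lambda = c(rep(2, 6), rep(30, 5), rep(8, 4), rep(1, 9)))
  x <- rep(wave, 10)
  r <- activity_record(x, 60, "2024-01-01", dd)
  ar2 <- activity_rest_split(r, 24)
  best <- -Inf; best_s <- NA
  for (s in 0:23) {
    v <- sum(x[((0:239) %% 24) %in% ((s + 0:11) %% 24)]) / 10
    if (v > best) { best <- v; best_s <- s }
  }
  expect_equal(ar2$window_start_h, best_s)
  expect_equal(ar2$activity_phase_total, best)
})

test_that("mid-activity breaks are detected with the duration threshold", {
  # active 12:00-24:00 at rate 10, with a 90-min gap starting at 17:00
  mins <- 0:(10 * 1440 - 1)
  tod <- (mins / 60) %% 24
  x <- ifelse(tod >= 12 & tod < 24, 10, 0)
  x[tod >= 17 & tod < 18.5] <- 0
  rec <- activity_record(x, 1, "2024-01-01", dd)
  on <- detect_onsets(rec, 24)
  br <- detect_breaks(rec, on, min_gap_minutes = 15)
  expect_equal(br$break_mean_h, 1.5)
  expect_true(all(vapply(br$per_cycle[!is.na(on$onsets_h)], length, 1L) == 1))

  # no sub-threshold run -> empty
  clean <- square_wave_record(n_days = 10)
  bc <- detect_breaks(clean, detect_onsets(clean, 24))
  expect_true(all(lengths(bc$per_cycle) == 0))
  expect_true(is.na(bc$break_mean_h))

  # gaps of 30 and 20 min with a 25-min minimum: only the 30-min gap reported
  x2 <- ifelse(tod >= 12 & tod < 24, 10, 0)
  x2[tod >= 14 & tod < 14.5] <- 0
  x2[tod >= 20 & tod < 20 + 20 / 60] <- 0
  rec2 <- activity_record(x2, 1, "2024-01-01", dd)
  br2 <- detect_breaks(rec2, detect_onsets(rec2, 24), min_gap_minutes = 25)
  expect_equal(unique(unlist(br2$per_cycle)), 0.5)
})

test_that("full analysis recovers planted parameters and keeps rho = tau - alpha", {
  p <- sim_activity_params(tau_h = 23.6, alpha_h = 12.7, rate_active = 9,
                           rate_rest = 0.6, break_offset_h = 5,
                           break_duration_h = 2.34, masking = FALSE, seed = 11)
  sim <- simulate_activity(p, dd, n_days = 12)
  rp <- analyze_rhythm(bin_activity(sim$record, 6))
  expect_true(rp$rhythmic)
  expect_lt(abs(rp$tau_h - 23.6), 0.1 + 1e-9)
  expect_lt(abs(rp$alpha_h - 12.7), 0.2 + 1e-9)
  expect_identical(rp$rho_h, rp$tau_h - rp$alpha_h)
  expect_lt(abs(rp$delta_h * 60 - sim$truth$delta_8_min), 12 + 1e-9)
  expect_lt(abs(rp$break_mean_h - 2.34), 0.3)
  df <- as.data.frame(rp)
  expect_named(df, c("animal_id", "tau_h", "delta_h", "alpha_h", "rho_h",
                     "overall_activity", "qp", "percent_qp", "rhythmic",
                     "day_activity", "night_activity", "percent_day",
                     "activity_phase_total", "rest_phase_total", "break_mean_h"))
})

test_that("actogram layout matches its definition", {
  rec <- activity_record(rpois(14400, 1), 1, "2024-01-01 08:00:00",
                         light_schedule("LD12_12"))
  a2 <- build_actogram(rec, 24, double_plot = TRUE)
  expect_equal(dim(a2), c(9, 2 * 1440))
  a1 <- build_actogram(rec, 24, double_plot = FALSE)
  expect_equal(dim(a1), c(10, 1440))
  # double plot: second half of row i equals first half of row i + 1
  expect_equal(a2[1, 1441:2880], a2[2, 1:1440])
  short <- activity_record(rpois(1440, 1), 1, "2024-01-01", dd)
  expect_error(build_actogram(short, 24), "two row periods")
})
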