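test_that("worked chi-square example matches the double-loop oracle", {
  rec <- toy_qp_record()
  pg <- chi_square_periodogram(rec, period_min_h = 18, period_max_h = 36)
  qp_at <- function(P) pg$statistic[pg$period_bins == P]
  expect_equal(qp_at(4), 12, tolerance = 1e-12)
  expect_equal(qp_at(3), 0, tolerance = 1e-12)
  expect_equal(qp_at(4), qp_oracle(rec$counts, 4), tolerance = 1e-9)
  expect_equal(qp_at(3), qp_oracle(rec$counts, 3), tolerance = 1e-9)
  expect_equal(pg$peak_period_h, 24)  # 4 bins of 6 h
  expect_equal(percent_qp(pg), 100)
  expect_true(classify_rhythmicity(pg))
})

test_that("chi-square Qp equals the naive oracle on random series", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(60:200, 1)
    x <- rpois(n, runif(1, 1, 30)) + ifelse(runif(n) < 0.3, rpois(n, 20), 0)
    rec <- activity_record(x, 60, "2024-01-01", light_schedule("DD"))
    pg <- chi_square_periodogram(rec, 2, n / 4)
    oracle <- vapply(pg$period_bins, function(P) qp_oracle(x, P), 0)
    expect_equal(pg$statistic, oracle, tolerance = 1e-9)
  }
})

test_that("Qp is bounded by the number of bins used at every period", {
  set.seed(202)
  for (i in 1:1000) {
    n <- sample(40:120, 1)
    x <- switch(sample(3, 1),
                rpois(n, runif(1, 0.5, 20)),
                runif(n, 0, 100),
                rep(rpois(ceiling(n / 7), 10), length.out = n) + rpois(n, 2))
    rec <- activity_record(x, 60, "2024-01-01", light_schedule("DD"))
    pg <- chi_square_periodogram(rec, 2, n / 2.5)
    expect_true(all(pg$statistic >= -1e-12))
    expect_true(all(pg$statistic <= pg$n_bins_used + 1e-9))
  }
})

test_that("constant series has zero Qp everywhere and classifies arrhythmic", {
  rec <- activity_record(rep(5, 120), 60, "2024-01-01", light_schedule("DD"))
  pg <- chi_square_periodogram(rec, 3, 40)
  expect_true(all(pg$statistic == 0))
  expect_equal(percent_qp(pg), 0)
  expect_false(classify_rhythmicity(pg))
})

test_that("peak ties are broken toward 24 h", {
  # period-4 square wave (6-h bins): Qp ties exactly at 4 bins (24 h) and its
  # 8-bin harmonic (48 h); the tie rule picks 24 h
  x <- rep(c(10, 0, 0, 0), 6)
  rec <- activity_record(x, 360, "2024-01-01", light_schedule("DD"))
  pg <- chi_square_periodogram(rec, 18, 54)
  q4 <- pg$statistic[pg$period_bins == 4]
  q8 <- pg$statistic[pg$period_bins == 8]
  expect_equal(q4, q8)
  expect_equal(estimate_tau(pg), 24)
})

test_that("%Qp stays in [0, 100] and rejects the Fourier method", {
  set.seed(7)
  for (i in 1:20) {
    x <- rpois(240, 5) + rep(c(20, 0), each = 120)[sample(240)]
    rec <- activity_record(x, 60, "2024-01-01", light_schedule("DD"))
    v <- percent_qp(chi_square_periodogram(rec, 3, 60))
    expect_true(v >= 0 && v <= 100)
  }
  rec <- toy_qp_record()
  fp <- fourier_periodogram(rec, 18, 36)
  expect_error(percent_qp(fp), "chi-square")
  expect_error(classify_rhythmicity(fp), "chi-square")
})

test_that("fourier periodogram finds the driving period", {
  t_h <- (0:2399) / 10  # 10 days, 6-min bins
  x <- 10 + 8 * sin(2 * pi * t_h / 24)
  rec <- activity_record(pmax(x, 0), 6, "2024-01-01", light_schedule("DD"))
  pg <- fourier_periodogram(rec, 20, 28)
  expect_lt(abs(pg$peak_period_h - 24), 24 / 9 - 24 / 10 + 1e-9)  # one grid step
  expect_equal(sum(pg$statistic), 1)

  flat <- activity_record(rep(3, 2400), 6, "2024-01-01", light_schedule("DD"))
  expect_true(all(fourier_periodogram(flat, 20, 28)$statistic == 0))

  x2 <- 10 + 8 * sin(2 * pi * t_h / 24) + 2 * sin(2 * pi * t_h / 12)
  pg2 <- fourier_periodogram(activity_record(pmax(x2, 0), 6, "2024-01-01",
                                             light_schedule("DD")), 20, 28)
  expect_lt(abs(pg2$peak_period_h - 24), 24 / 9 - 24 / 10 + 1e-9)
})

test_that("records shorter than two cycles of the longest period are rejected", {
  rec <- activity_record(rpois(300, 3), 6, "2024-01-01", light_schedule("DD"))
  expect_error(chi_square_periodogram(rec, 20, 28), "two cycles")
  expect_error(fourier_periodogram(rec, 20, 28), "two cycles")
})
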