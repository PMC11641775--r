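test_that("preprocessing removes uniform background and impulse noise", {
  flat <- matrix(7, 64, 64)
  expect_true(all(preprocess_channel(flat) == 0))

  impulse <- matrix(0, 64, 64)
  impulse[30, 30] <- 5
  expect_true(all(preprocess_channel(impulse, median_size_px = 3) < 1e-6))

  expect_error(preprocess_channel(matrix(1, 10, 10), background_radius_px = 20),
               "larger than the image")
  expect_error(preprocess_channel(flat, median_size_px = 4), "odd")
})

test_that("a spot on a linear ramp survives preprocessing while the ramp goes", {
  w <- 128
  ramp <- matrix(rep(seq(0, 0.6, length.out = w), each = w), w, w)
  spot <- matrix(0, w, w)
  cx <- 64; cy <- 64; sigma <- 2; amp <- 1
  for (i in (cy - 8):(cy + 8)) for (j in (cx - 8):(cx + 8))
    spot[i, j] <- amp * exp(-((i - cy)^2 + (j - cx)^2) / (2 * sigma^2))
  out <- preprocess_channel(ramp + spot, background_radius_px = 8)
  expect_gt(out[cy, cx], 0.5 * amp)              # peak retained above 50%
  far <- out[10:20, 100:120]                     # pure-ramp region
  expect_lt(max(far), 0.05 * 0.6)                # ramp removed to < 5%
})

test_that("segmentation counts well-separated spots and measures area", {
  img <- matrix(0, 120, 120)
  centers <- cbind(c(20, 60, 100, 30, 90), c(20, 60, 100, 95, 25))
  for (k in 1:5)
    for (i in -6:6) for (j in -6:6)
      img[centers[k, 1] + i, centers[k, 2] + j] <-
        img[centers[k, 1] + i, centers[k, 2] + j] + exp(-(i^2 + j^2) / 8)
  s <- segment_puncta(img, threshold = "fixed", threshold_value = 0.3)
  expect_equal(s$count, 5)

  sq <- matrix(0, 100, 100); sq[41:50, 61:70] <- 1
  s2 <- segment_puncta(sq, threshold = "fixed", threshold_value = 0.5)
  expect_equal(s2$count, 1)
  expect_equal(s2$area_fraction, 1.0)

  expect_equal(segment_puncta(matrix(0, 50, 50))$count, 0)
  expect_true(segment_puncta(matrix(3, 50, 50), threshold = "fixed",
                             threshold_value = 1)$saturated)
})

test_that("watershed separates two spots merged at threshold", {
  img <- matrix(0, 80, 80)
  sigma <- 2.5
  fwhm <- 2 * sqrt(2 * log(2)) * sigma
  cx <- c(40 - 0.75 * fwhm, 40 + 0.75 * fwhm)  # 1.5 x FWHM apart
  for (k in 1:2)
    for (i in 1:80) for (j in 1:80)
      img[i, j] <- img[i, j] + exp(-((i - 40)^2 + (j - cx[k])^2) / (2 * sigma^2))
  merged <- segment_puncta(img, threshold = "fixed", threshold_value = 0.25,
                           split_touching = FALSE)
  expect_equal(merged$count, 1)  # genuinely merged at this threshold
  split <- segment_puncta(img, threshold = "fixed", threshold_value = 0.25,
                          split_touching = TRUE)
  expect_equal(split$count, 2)
  expect_equal(sort(split$puncta$x), sort(cx - 1), tolerance = 0.15)
})

test_that("size filtering removes specks and over-large components", {
  img <- matrix(0, 60, 60)
  img[10, 10] <- 1                         # 1-px speck
  img[30:33, 30:33] <- 1                   # 16-px punctum
  s <- segment_puncta(img, threshold = "fixed", threshold_value = 0.5,
                      min_area_px = 4)
  expect_equal(s$count, 1)
  s2 <- segment_puncta(img, threshold = "fixed", threshold_value = 0.5,
                       min_area_px = 1, max_area_px = 8)
  expect_equal(s2$count, 1)
  expect_equal(s2$puncta$area, 1L)
})

test_that("AND colocalization matches the exhaustive pixel-overlap oracle", {
  expect_equal(colocalize(mask_set(random_disk_mask(7, 64) * 0 + TRUE),
                          mask_set(matrix(TRUE, 64, 64)))$co_labeled_count, 1)
  set.seed(77)
  for (i in 1:50) {
    a <- mask_set(random_disk_mask(sample(3:9, 1)))
    b <- mask_set(random_disk_mask(sample(3:9, 1)))
    got <- colocalize(a, b)$co_labeled_count
    expect_identical(got, coloc_oracle(a$labels, b$labels))
    # symmetry
    expect_identical(got, colocalize(b, a)$co_labeled_count)
  }
})

test_that("identical and disjoint masks give the expected counts", {
  m <- matrix(FALSE, 60, 60)
  for (k in 0:6) m[(5 + 8 * k):(7 + 8 * k), 10:14] <- TRUE
  s <- mask_set(m)
  expect_equal(colocalize(s, s)$co_labeled_count, 7)
  m2 <- matrix(FALSE, 60, 60); m2[1:5, 40:55] <- TRUE
  expect_equal(colocalize(s, mask_set(m2))$co_labeled_count, 0)
  expect_error(colocalize(s, mask_set(matrix(FALSE, 30, 30))), "dimensions")
})

test_that("every AND component lies inside one pre and one post punctum", {
  set.seed(88)
  for (i in 1:10) {
    p <- sim_image_params(n_puncta_a = 60, n_puncta_b = 60, coloc_fraction = 0.5,
                          seed = 1000 + i)
    f <- simulate_puncta_field(p)
    # plain connected-component puncta: the containment invariant is exact
    # (watershed sub-splits of one blob share a border and would be merged
    # again in the AND mask)
    sa <- segment_puncta(preprocess_channel(f$channels$pre), split_touching = FALSE)
    sb <- segment_puncta(preprocess_channel(f$channels$post), split_touching = FALSE)
    cl <- colocalize(sa, sb)
    comps <- flood_components(cl$and_mask)
    for (px in comps) {
      expect_equal(length(unique(sa$labels[px])), 1)
      expect_equal(length(unique(sb$labels[px])), 1)
      expect_true(all(sa$labels[px] > 0) && all(sb$labels[px] > 0))
    }
  }
})

test_that("recovery on noisy synthetic fields is within five percent", {
  set.seed(99)
  for (i in 1:10) {
    p <- sim_image_params(n_puncta_a = 100, n_puncta_b = 100,
                          coloc_fraction = 0.6, seed = 2000 + i)
    f <- simulate_puncta_field(p)
    q <- quantify_field(f)
    expect_lte(abs(q$count_pre - 100), 5)
    expect_lte(abs(q$count_post - 100), 5)
    expect_lte(abs(q$co_labeled_count - 60), 3)
  }
})

test_that("one rendered disk matches the analytic area fraction", {
  w <- 200; r <- 15
  img <- matrix(0, w, w)
  for (i in 1:w) for (j in 1:w)
    if ((i - 100)^2 + (j - 100)^2 <= r^2) img[i, j] <- 1
  s <- segment_puncta(img, threshold = "fixed", threshold_value = 0.5,
                      split_touching = FALSE)
  analytic <- 100 * pi * r^2 / w^2
  expect_lt(abs(s$area_fraction - analytic) / analytic, 0.02)
})

test_that("density and participation formulas are exact", {
  expect_equal(synapse_density(5, c(500, 500), 0.1, 0.46), 5 / 1150,
               tolerance = 1e-15)
  expect_equal(synapse_density(0, c(500, 500), 0.1, 0.46), 0)
  expect_equal(synapse_density(5, c(500, 500), 0.1, 0.92),
               synapse_density(5, c(500, 500), 0.1, 0.46) / 2)
  # density times volume reproduces the integer count
  vol <- 500 * 500 * 0.1^2 * 0.46
  expect_equal(synapse_density(5, c(500, 500), 0.1, 0.46) * vol, 5,
               tolerance = 1e-12)
  expect_error(synapse_density(5, c(500, 500)), "required")

  expect_equal(percent_participation(35, 50), 70)
  expect_equal(percent_participation(0, 50), 0)
  expect_equal(percent_participation(50, 50), 100)
  expect_warning(v <- percent_participation(0, 0), "undefined")
  expect_true(is.na(v))
  expect_error(percent_participation(10, 5), "exceeds")
})
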