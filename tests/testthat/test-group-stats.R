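test_that("identical groups give a null ANOVA with all pairs ns", {
  cmp <- compare_groups(list(A = c(1, 2, 3), B = c(1, 2, 3)))
  expect_equal(cmp$test_used, "anova_tukey")
  expect_equal(cmp$statistic, 0)
  expect_true(all(cmp$pairwise$verdict == "ns"))
})

test_that("well-separated normal groups take the ANOVA branch with correct verdicts", {
  set.seed(5)
  x <- c(rnorm(8, 0, 0.1), rnorm(8, 0, 0.1), rnorm(8, 10, 0.1))
  g <- rep(c("g1", "g2", "g3"), each = 8)
  cmp <- compare_groups(x, g)
  expect_equal(cmp$test_used, "anova_tukey")
  expect_equal(pair_verdict(cmp, "g1", "g3"), "up")
  expect_equal(pair_verdict(cmp, "g3", "g1"), "down")
  expect_equal(pair_verdict(cmp, "g1", "g2"), "ns")
})

test_that("ANOVA F and Tukey p match a from-scratch formula evaluation", {
  # fixed, balanced 4-group dataset
  dat <- list(a = c(5.1, 4.8, 5.6, 5.0, 5.3, 4.7),
              b = c(6.0, 6.4, 5.8, 6.1, 6.6, 5.9),
              c = c(5.2, 5.5, 4.9, 5.4, 5.1, 5.6),
              d = c(7.0, 6.8, 7.3, 6.9, 7.2, 6.7))
  cmp <- compare_groups(dat)
  expect_equal(cmp$test_used, "anova_tukey")

  # oracle: between/within mean squares and studentized-range quantiles
  k <- length(dat); n <- lengths(dat); N <- sum(n)
  means <- vapply(dat, mean, 0); grand <- mean(unlist(dat))
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum(vapply(dat, function(v) sum((v - mean(v))^2), 0))
  ms_between <- ss_between / (k - 1)
  ms_within <- ss_within / (N - k)
  expect_equal(cmp$statistic, ms_between / ms_within, tolerance = 1e-9)
  expect_equal(cmp$p_omnibus,
               pf(ms_between / ms_within, k - 1, N - k, lower.tail = FALSE),
               tolerance = 1e-9)
  for (j in seq_len(nrow(cmp$pairwise))) {
    g1 <- cmp$pairwise$group1[j]; g2 <- cmp$pairwise$group2[j]
    q <- abs(means[[g2]] - means[[g1]]) / sqrt(ms_within / n[[g1]])
    expect_equal(cmp$pairwise$p_adj[j],
                 ptukey(q, k, N - k, lower.tail = FALSE), tolerance = 1e-9)
  }
})

test_that("Tukey adjusted p is at least the unadjusted pairwise p", {
  set.seed(17)
  for (i in 1:10) {
    g <- rep(c("A", "B", "C", "D"), each = 8)
    x <- rnorm(32, mean = rep(runif(4, 0, 1), each = 8))
    cmp <- compare_groups(x, g)
    if (cmp$test_used != "anova_tukey") next
    fit <- aov(x ~ factor(g))
    msw <- summary(fit)[[1]][["Mean Sq"]][2]
    for (j in seq_len(nrow(cmp$pairwise))) {
      m1 <- mean(x[g == cmp$pairwise$group1[j]])
      m2 <- mean(x[g == cmp$pairwise$group2[j]])
      t_stat <- (m2 - m1) / sqrt(msw * (1 / 8 + 1 / 8))
      p_unadj <- 2 * pt(-abs(t_stat), 28)
      expect_gte(cmp$pairwise$p_adj[j] + 1e-12, p_unadj)
    }
  }
})

test_that("non-normal data selects Kruskal-Wallis with Holm-adjusted Dunn contrasts", {
  set.seed(23)
  x <- c(rexp(10, 1), rexp(10, 1), rexp(10, 0.2))
  g <- rep(c("A", "B", "C"), each = 10)
  cmp <- compare_groups(x, g)
  expect_equal(cmp$test_used, "kruskal_dunn")
  kw <- kruskal.test(x, factor(g))
  expect_equal(cmp$statistic, unname(kw$statistic))
  expect_equal(cmp$p_omnibus, kw$p.value)
  expect_true(all(cmp$pairwise$p_adj >= 0 & cmp$pairwise$p_adj <= 1))
  expect_equal(pair_verdict(cmp, "A", "C"), "up")
  # Holm adjustment never lowers a p-value
  raw <- compare_groups(x, g, p_adjust = "none")$pairwise$p_adj
  expect_true(all(cmp$pairwise$p_adj + 1e-12 >= raw))
})

test_that("branch choice and p-values are deterministic", {
  set.seed(31)
  x <- rnorm(24); g <- rep(letters[1:3], each = 8)
  c1 <- compare_groups(x, g)
  c2 <- compare_groups(x, g)
  expect_identical(c1[setdiff(names(c1), "call")], c2[setdiff(names(c2), "call")])
})

test_that("group size and count requirements are enforced", {
  expect_error(compare_groups(c(1, 2, 3, 4), rep(c("a", "b"), 2)), "at least 3")
  expect_error(compare_groups(1:6, rep("a", 6)), "two groups")
})

test_that("null exchangeable data rejects near the nominal rate", {
  set.seed(47)
  rej <- 0
  n_sim <- 200
  for (i in 1:n_sim) {
    x <- rnorm(32)
    cmp <- compare_groups(x, rep(1:4, each = 8))
    if (cmp$p_omnibus < 0.05) rej <- rej + 1
  }
  expect_gte(rej / n_sim, 0.02)
  expect_lte(rej / n_sim, 0.09)
})

test_that("correlation method follows normality and handles exact relations", {
  set.seed(53)
  x <- rnorm(30)
  r1 <- correlate(x, 2 * x + 1)
  expect_equal(r1$estimate, 1)
  r2 <- correlate(x, -x)
  expect_equal(r2$estimate, -1)
  # heavily tied ordinal data forces the Spearman branch
  xo <- rep(1:3, each = 10)
  yo <- rep(c(1, 2, 2), 10)
  expect_equal(correlate(xo, yo)$method, "spearman")
  expect_error(correlate(rep(1, 10), rnorm(10)), "zero-variance")
  expect_error(correlate(1:5, 1:4), "equal length")
})
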