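# Distribution-gated group comparisons and correlations.

shapiro_p <- function(x) {
  if (length(unique(x)) < 3) return(0)           # degenerate -> treat as non-normal
  tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
}

# Dunn's post-hoc rank test after Kruskal-Wallis, with tie correction.
# Returns one row per unordered group pair (g1, g2) in combn order; the z
# statistic and estimate are oriented as g2 - g1 (mean-rank difference).
dunn_test <- function(values, group) {
  group <- droplevels(as.factor(group))
  r <- rank(values)
  N <- length(values)
  rbar <- tapply(r, group, mean)
  n <- tapply(r, group, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(levels(group), 2)
  est <- z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[g1]] + 1 / n[[g2]]))
    est[j] <- rbar[[g2]] - rbar[[g1]]
    z[j] <- est[j] / se
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             estimate = est, statistic = z, p = p, stringsAsFactors = FALSE)
}

#' Compare groups with automatic test selection
#'
#' Reproduces the distribution-gated testing scheme used throughout the
#' analysis: Shapiro-Wilk normality per group and median-centered Levene
#' homogeneity across groups, both at 0.05, select the branch. If every group
#' is compatible with normality and variances are homogeneous, a one-way
#' ANOVA with Tukey's HSD post-hoc test is used; otherwise the Kruskal-Wallis
#' test with Dunn's post-hoc test (Holm-adjusted by default). Each unordered
#' pair receives a direction verdict at `alpha`: `"up"` if the second group
#' is significantly higher than the first, `"down"` if lower, `"ns"`
#' otherwise.
#'
#' @param values Numeric measurements, or a named list of per-group numeric
#'   vectors (then `group` is ignored).
#' @param group Group labels parallel to `values`.
#' @param alpha Verdict level (default 0.05).
#' @param p_adjust Adjustment for Dunn p-values: `"holm"` (default),
#'   `"bonferroni"` or `"none"`. Tukey HSD p-values carry their own
#'   family-wise adjustment.
#' @return An object of class `group_comparison`: `test_used`
#'   (`"anova_tukey"` or `"kruskal_dunn"`), omnibus `statistic`, `df`,
#'   `p_omnibus`, gate p-values, and a `pairwise` data frame (`group1`,
#'   `group2`, `estimate` oriented group2 - group1, `p_adj`, `verdict`).
#' @examples
#' set.seed(1)
#' g <- rep(c("A", "B", "C"), each = 8)
#' x <- rnorm(24, mean = c(0, 0, 2)[as.integer(factor(g))])
#' compare_groups(x, g)
#' @export
compare_groups <- function(values, group = NULL, alpha = 0.05,
                           p_adjust = c("holm", "bonferroni", "none")) {
  p_adjust <- match.arg(p_adjust)
  if (is.list(values) && is.null(group)) {
    group <- rep(names(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) stop("at least two groups required")
  n <- tapply(values, group, length)
  if (any(n < 3)) stop("every group needs at least 3 observations")

  shapiro <- vapply(split(values, group), shapiro_p, 0)
  lev <- car::leveneTest(values ~ group, center = stats::median)
  levene_p <- lev[["Pr(>F)"]][1]
  use_anova <- all(shapiro > 0.05) && levene_p > 0.05

  if (use_anova) {
    fit <- stats::aov(values ~ group)
    s <- summary(fit)[[1]]
    tuk <- stats::TukeyHSD(fit)$group
    pairs <- utils::combn(levels(group), 2)
    rown <- paste(pairs[2, ], pairs[1, ], sep = "-")
    if (!all(rown %in% rownames(tuk))) stop("unexpected Tukey contrast names")
    pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                     estimate = tuk[rown, "diff"],
                     p_adj = tuk[rown, "p adj"],
                     stringsAsFactors = FALSE, row.names = NULL)
    test_used <- "anova_tukey"
    statistic <- s[["F value"]][1]
    df <- s[["Df"]]
    p_omnibus <- s[["Pr(>F)"]][1]
  } else {
    kw <- stats::kruskal.test(values, group)
    dt <- dunn_test(values, group)
    pw <- data.frame(group1 = dt$group1, group2 = dt$group2,
                     estimate = dt$estimate,
                     p_adj = stats::p.adjust(dt$p, method = p_adjust),
                     stringsAsFactors = FALSE)
    test_used <- "kruskal_dunn"
    statistic <- unname(kw$statistic)
    df <- unname(kw$parameter)
    p_omnibus <- kw$p.value
  }
  pw$verdict <- ifelse(pw$p_adj < alpha,
                       ifelse(pw$estimate > 0, "up", "down"), "ns")
  structure(
    list(test_used = test_used, statistic = statistic, df = df,
         p_omnibus = p_omnibus, shapiro_p = shapiro, levene_p = levene_p,
         alpha = alpha, pairwise = pw),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: omnibus statistic %.3f, p = %.4g\n",
              x$test_used, x$statistic, x$p_omnibus))
  print(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Pairwise verdict between two specific groups
#'
#' Convenience accessor: the direction verdict of `group2` relative to
#' `group1` from a [compare_groups()] result.
#'
#' @param comparison A `group_comparison`.
#' @param group1,group2 Group labels.
#' @return `"up"`, `"down"` or `"ns"` (orientation group2 vs group1).
#' @export
pair_verdict <- function(comparison, group1, group2) {
  pw <- comparison$pairwise
  i <- which(pw$group1 == group1 & pw$group2 == group2)
  if (length(i) == 1) return(pw$verdict[i])
  i <- which(pw$group1 == group2 & pw$group2 == group1)
  if (length(i) != 1) stop("pair not found in comparison")
  switch(pw$verdict[i], up = "down", down = "up", "ns")
}

#' Correlation with automatic method selection
#'
#' Pearson correlation when both variables are compatible with normality
#' (Shapiro-Wilk at 0.05), Spearman rank correlation otherwise.
#'
#' @param x,y Numeric vectors of equal length (>= 3), non-constant.
#' @return An object of class `correlation_result`: `method`, `estimate`,
#'   `p_value`, `n`.
#' @examples
#' correlate(1:10, 2 * (1:10) + 1)$estimate  # 1
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3) stop("at least 3 paired observations required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero-variance variable")
  method <- if (shapiro_p(x) > 0.05 && shapiro_p(y) > 0.05) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  structure(list(method = method, estimate = unname(ct$estimate),
                 p_value = ct$p.value, n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.3f, p = %.4g (n = %d)\n",
              x$method, x$estimate, x$p_value, x$n))
  invisible(x)
}
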