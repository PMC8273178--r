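test_that("a 13 x 4 design yields the (3, 12, 36) degrees-of-freedom rows", {
  tab <- expand.grid(subject = 1:13, condition = chroma_levels())
  set.seed(5)
  tab$value <- rnorm(52)
  a <- rm_anova_oneway(tab)
  expect_equal(a$df, c(3L, 12L, 36L))
  expect_equal(a$source, c("Condition", "Subject", "Residuals"))
})

test_that("per-subject constant values give zero condition effect", {
  tab <- expand.grid(subject = 1:6, condition = c("A", "B", "C"))
  tab$value <- as.numeric(tab$subject) * 2
  a <- rm_anova_oneway(tab)
  expect_equal(a$sum_sq[1], 0, tolerance = 1e-12)
  expect_equal(a$F[1], 0)
})

test_that("a 3 x 2 toy table matches the hand-computed decomposition", {
  # subjects 1-3, conditions A/B: A = (2, 4, 6), B = (3, 7, 8)
  # grand mean 5; SS_cond = 6, SS_subj = 21, SS_resid = 1; F = 12
  tab <- data.frame(
    subject = rep(1:3, 2), condition = rep(c("A", "B"), each = 3),
    value = c(2, 4, 6, 3, 7, 8)
  )
  a <- rm_anova_oneway(tab)
  expect_equal(a$sum_sq, c(6, 21, 1), tolerance = 1e-10)
  expect_equal(a$mean_sq, c(6, 10.5, 0.5), tolerance = 1e-10)
  expect_equal(a$F[1], 12, tolerance = 1e-10)
  expect_equal(a$df, c(1L, 2L, 2L))
  expect_equal(a$p[1], pf(12, 1, 2, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("the decomposition agrees with aov() on random tables", {
  set.seed(31)
  for (i in 1:5) {
    n <- sample(4:12, 1)
    k <- sample(3:5, 1)
    tab <- expand.grid(subject = factor(1:n), condition = factor(1:k))
    tab$value <- rnorm(n * k, 1, 0.7)
    mine <- rm_anova_oneway(tab)
    ref <- summary(aov(value ~ condition + subject, data = tab))[[1]]
    expect_equal(mine$sum_sq[1], ref["condition", "Sum Sq"], tolerance = 1e-9)
    expect_equal(mine$sum_sq[2], ref["subject", "Sum Sq"], tolerance = 1e-9)
    expect_equal(mine$sum_sq[3], ref["Residuals", "Sum Sq"], tolerance = 1e-9)
    expect_equal(mine$F[1], ref["condition", "F value"], tolerance = 1e-9)
    expect_equal(mine$p[1], ref["condition", "Pr(>F)"], tolerance = 1e-9)
    # exact conservation of the total sum of squares
    expect_equal(
      sum(mine$sum_sq), sum((tab$value - mean(tab$value))^2),
      tolerance = 1e-9
    )
  }
})

test_that("incomplete crossings and degenerate designs are rejected", {
  tab <- expand.grid(subject = 1:4, condition = c("A", "B"))
  tab$value <- rnorm(8)
  expect_error(rm_anova_oneway(tab[-1, ]), "incomplete crossing")
  one <- data.frame(subject = 1, condition = c("A", "B"), value = 1:2)
  expect_error(rm_anova_oneway(one), ">= 2 subjects")
})

test_that("tukey hsd produces all pairs with correct q and reference p", {
  tab <- expand.grid(subject = 1:8, condition = c("/0", "/2", "/4", "/6"))
  set.seed(8)
  tab$value <- rnorm(32, rep(c(1, 0.6, 0.8, 0.9), each = 8), 0.3)
  a <- rm_anova_oneway(tab)
  tk <- tukey_hsd(tab, a)
  expect_equal(nrow(tk), 6L)
  ms_resid <- a$mean_sq[3]
  means <- tapply(tab$value, tab$condition, mean)
  expect_equal(
    tk$q[tk$pair == "/0 - /2"],
    abs(means[["/2"]] - means[["/0"]]) / sqrt(ms_resid / 8),
    tolerance = 1e-12
  )
  # adjusted p agree with direct numerical integration of the
  # studentized-range distribution
  for (i in c(1, 4, 6)) {
    expect_equal(
      tk$p_adj[i],
      quad_ptukey_upper(tk$q[i], k = 4, df = a$df[3]),
      tolerance = 1e-6
    )
  }
})

test_that("identical condition means give adjusted p of one", {
  tab <- expand.grid(subject = 1:6, condition = c("A", "B", "C"))
  set.seed(17)
  tab$value <- as.numeric(tab$subject) + rnorm(18, 0, 0.4)
  # center each condition on a common mean: residual variance stays, the
  # pairwise differences vanish
  tab$value <- tab$value - stats::ave(tab$value, tab$condition) + mean(tab$value)
  tk <- tukey_hsd(tab)
  expect_true(all(abs(tk$diff) < 1e-12))
  expect_true(all(tk$p_adj > 1 - 1e-9))
})

test_that("tukey adjusted p are conservative against pairwise t", {
  set.seed(12)
  for (i in 1:10) {
    tab <- expand.grid(subject = 1:9, condition = c("/0", "/2", "/4", "/6"))
    tab$value <- rnorm(36)
    a <- rm_anova_oneway(tab)
    tk <- tukey_hsd(tab, a)
    p_t <- 2 * pt(-tk$q / sqrt(2), df = a$df[3])
    expect_true(all(tk$p_adj >= p_t - 1e-12))
  }
})

test_that("mean comparisons match their closed forms", {
  a <- c(1.2, 1.5, 1.1, 1.9)
  expect_equal(compare_means(a, a, mode = "paired")$t, 0)
  expect_equal(compare_means(a, a, mode = "paired")$p, 1)

  b <- c(0.7, 2.3, 0.9, 1.4, 2.2)
  w <- compare_means(a, b, mode = "welch")
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  expect_equal(w$t, (mean(a) - mean(b)) / sqrt(va + vb), tolerance = 1e-10)
  expect_equal(
    w$df,
    (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1)),
    tolerance = 1e-10
  )
  # paired equals a one-sample t on the differences
  b4 <- b[1:4]
  pp <- compare_means(a, b4, mode = "paired")
  ref <- t.test(a - b4)
  expect_equal(pp$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(pp$p, ref$p.value, tolerance = 1e-12)

  expect_error(compare_means(rep(1, 3), rep(2, 3)), "zero variance")
  expect_error(compare_means(1, 1:3), "at least 2")
  expect_error(compare_means(1:3, 1:4, mode = "paired"), "equal-length")
})

test_that("the inside/on ratio is the plain quotient of mean magnitudes", {
  expect_equal(inside_on_ratio(c(2, 4), c(4, 4)), 0.75)
  expect_equal(inside_on_ratio(8.42, 10), 0.842)
})
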