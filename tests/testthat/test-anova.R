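test_that("one-way ANOVA reduces to the pooled t-test with two groups", {
  set.seed(41)
  for (i in 1:10) {
    y <- rnorm(14)
    g <- rep(c("a", "b"), c(6, 8))
    fit <- one_way_anova(y, g)
    tt <- t.test(y[g == "a"], y[g == "b"], var.equal = TRUE)
    expect_equal(fit$terms$F[1], unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(fit$terms$p[1], tt$p.value, tolerance = 1e-10)
  }
})

test_that("one-way ANOVA edge cases behave", {
  y <- c(1, 3, 1, 3, 1, 3)
  g <- rep(c("a", "b", "c"), each = 2)
  fit <- one_way_anova(y, g)  # identical means, nonzero spread
  expect_equal(fit$terms$F[1], 0)
  expect_error(one_way_anova(1:3, c("a", "a", "b")), "at least 2 observations")
  expect_warning(one_way_anova(c(1, 1, 2, 2), c("a", "a", "b", "b")),
                 "zero within-group variance")
})

test_that("one-way SS/F match a brute-force oracle and stats::aov", {
  set.seed(43)
  for (i in 1:10) {
    g <- factor(rep(letters[1:4], each = 6))
    y <- rnorm(24, mean = rep(runif(4, 0, 3), each = 6))
    fit <- one_way_anova(y, g)
    # brute-force mean-deviation sums
    grand <- mean(y)
    ssb <- sum(sapply(levels(g), function(l) 6 * (mean(y[g == l]) - grand)^2))
    ssw <- sum(sapply(levels(g), function(l) sum((y[g == l] - mean(y[g == l]))^2)))
    expect_equal(fit$terms$ss, c(ssb, ssw), tolerance = 1e-10)
    ref <- anova(aov(y ~ g))
    expect_equal(fit$terms$F[1], ref$`F value`[1], tolerance = 1e-10)
    expect_equal(fit$terms$p[1], ref$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("two-way SS/F match the brute-force decomposition and stats::aov", {
  set.seed(47)
  for (i in 1:50) {
    d <- expand.grid(a = letters[1:3], b = LETTERS[1:5], r = 1:6)
    d$y <- rnorm(nrow(d), mean = 0.4 * as.integer(d$a) + 0.2 * as.integer(d$b))
    fit <- two_way_anova(d$y, d$a, d$b)
    orc <- oracle_two_way(d$y, d$a, d$b)
    expect_equal(fit$terms$ss, orc$ss, tolerance = 1e-10)
    expect_equal(fit$terms$df, orc$df)
    expect_equal(fit$terms$F[1:3], orc$f, tolerance = 1e-10)
    if (i <= 5) {
      ref <- anova(aov(y ~ a * b, d))
      expect_equal(fit$terms$ss, ref$`Sum Sq`, tolerance = 1e-8)
      expect_equal(pmax(fit$terms$p[1:3], 1e-12),
                   pmax(ref$`Pr(>F)`[1:3], 1e-12), tolerance = 1e-8)
    }
    # balanced decomposition is exact
    ss_total <- sum((d$y - mean(d$y))^2)
    expect_equal(sum(fit$terms$ss), ss_total, tolerance = 1e-8 * ss_total)
  }
})

test_that("two-way ANOVA degenerate structures give zero sums of squares", {
  d <- expand.grid(a = 1:3, b = 1:4, r = 1:2)
  fit <- two_way_anova(rep(5, nrow(d)), d$a, d$b)
  expect_equal(fit$terms$ss, rep(0, 4))
  # additive construction: no interaction
  d$y <- 2 * as.integer(d$a) + 7 * as.integer(d$b)
  fit2 <- two_way_anova(d$y, d$a, d$b)
  expect_equal(fit2$terms$ss[3], 0, tolerance = 1e-20)
  expect_equal(fit2$terms$ss[4], 0, tolerance = 1e-20)
})

test_that("unbalanced or incomplete layouts are rejected", {
  d <- expand.grid(a = 1:2, b = 1:3, r = 1:3)
  expect_error(two_way_anova(rnorm(nrow(d) - 1), d$a[-1], d$b[-1]),
               "unbalanced")
  d2 <- d[!(d$a == 1 & d$b == 2), ]
  expect_error(two_way_anova(rnorm(nrow(d2)), d2$a, d2$b), "empty cells|unbalanced")
  d3 <- expand.grid(a = 1:2, b = 1:3)
  expect_error(two_way_anova(rnorm(nrow(d3)), d3$a, d3$b), ">= 2 replicates")
})

test_that("Bonferroni post-tests multiply by the family size", {
  set.seed(53)
  y <- rnorm(12); g <- rep(c("a", "b"), each = 6)
  fit <- one_way_anova(y, g)
  post <- bonferroni_posttest(fit, pairs = "all")
  expect_equal(nrow(post), 1)
  expect_equal(post$p_adjusted, post$p_raw)  # m = 1
  # identical cell means: every adjusted p = 1
  d <- expand.grid(a = 1:3, b = 1:4, r = 1:3)
  d$y <- as.integer(d$b) + 0.1 * d$r  # same replicate pattern in every cell
  fit2 <- two_way_anova(d$y, d$a, d$b)
  post2 <- bonferroni_posttest(fit2)
  expect_equal(attr(post2, "m"), 3 * 4)
  expect_equal(post2$t, rep(0, 12))
  expect_equal(post2$p_adjusted, rep(1, 12))
  # t formula: |diff| / sqrt(MS_error * 2/n) with error df
  d$y2 <- rnorm(nrow(d), mean = as.integer(d$a))
  fit3 <- two_way_anova(d$y2, d$a, d$b)
  post3 <- bonferroni_posttest(fit3)
  err <- fit3$terms[fit3$terms$term == "error", ]
  sub <- d[d$b == 1, ]
  m1 <- mean(sub$y2[sub$a == 1]); m2 <- mean(sub$y2[sub$a == 2])
  t_exp <- abs(m1 - m2) / sqrt(err$ms * 2 / 3)
  row <- post3[post3$stratum == "1" & post3$level_1 == "1" &
                 post3$level_2 == "2", ]
  expect_equal(row$t, t_exp, tolerance = 1e-12)
  expect_equal(row$df, err$df)
  expect_equal(row$p_adjusted, min(1, 12 * row$p_raw), tolerance = 1e-12)
})

test_that("F values are invariant under level relabeling", {
  set.seed(59)
  d <- expand.grid(a = letters[1:3], b = LETTERS[1:4], r = 1:3)
  d$y <- rnorm(nrow(d), as.integer(d$a))
  fit <- two_way_anova(d$y, d$a, d$b)
  relab <- c(a = "zz", b = "mm", c = "aa")
  fit2 <- two_way_anova(d$y, relab[as.character(d$a)], d$b)
  expect_equal(fit2$terms$F, fit$terms$F, tolerance = 1e-12)
  expect_equal(fit2$terms$ss, fit$terms$ss, tolerance = 1e-12)
  p1 <- bonferroni_posttest(fit)
  p2 <- bonferroni_posttest(fit2)
  expect_setequal(round(p1$t, 10), round(p2$t, 10))
})

test_that("p-values are floored, never zero", {
  y <- c(rnorm(20, 0, 0.01), rnorm(20, 100, 0.01))
  fit <- one_way_anova(y, rep(c("a", "b"), each = 20))
  expect_gt(fit$terms$p[1], 0)
  expect_match(ubdvmr:::format_p(fit$terms$p[1]), "< 1e-15")
})
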