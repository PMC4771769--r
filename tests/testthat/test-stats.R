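test_that("two-way ANOVA matches the balanced-design closed forms", {
  set.seed(13)
  cells <- expand.grid(loc = c("AIS", "NON_AIS"), area = c("X", "Y"))
  mu <- c(10, 10, 10, 20)
  df <- do.call(rbind, lapply(1:4, function(i)
    data.frame(y = rnorm(50, mu[i], 1), location_class = cells$loc[i],
               brain_area = cells$area[i])))
  got <- two_way_anova(df, "y")
  want <- oracle_balanced_twoway(df$y, df$location_class, df$brain_area)
  g <- function(e) got[got$effect == e, ]
  expect_equal(g("location")$ss, want$ss_a, tolerance = 1e-8)
  expect_equal(g("brain_area")$ss, want$ss_b, tolerance = 1e-8)
  expect_equal(g("interaction")$ss, want$ss_ab, tolerance = 1e-8)
  expect_equal(g("residual")$ss, want$ss_res, tolerance = 1e-8)
  f_want <- (want$ss_ab / want$df_ab) / (want$ss_res / want$df_res)
  expect_equal(g("interaction")$f, f_want, tolerance = 1e-8)
  expect_equal(g("interaction")$p,
               pf(f_want, want$df_ab, want$df_res, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("two-way ANOVA contract cases", {
  df <- expand.grid(location_class = c("AIS", "NON_AIS"),
                    brain_area = c("X", "Y", "Z"), rep = 1:4)
  df$y <- 5  # zero within-cell variance, equal means
  expect_warning(a <- two_way_anova(df, "y"), "residual")
  expect_true(all(is.na(a$f[a$effect != "residual"])))

  df2 <- df[!(df$location_class == "AIS" & df$brain_area == "X"), ]
  df2$y <- rnorm(nrow(df2))
  expect_error(two_way_anova(df2, "y"), "cell")
})

test_that("one-way ANOVA equals the brute-force decomposition", {
  # textbook 3-group data
  df <- data.frame(
    y = c(6, 8, 4, 5, 3, 4, 8, 12, 9, 11, 8, 7, 13, 9, 11, 8, 12, 13),
    g = rep(c("a", "b", "c"), each = 6))
  a <- one_way_anova(df, "y", "g")
  gm <- mean(df$y); mg <- tapply(df$y, df$g, mean)
  ss_b <- sum(6 * (mg - gm)^2)
  ss_w <- sum((df$y - mg[df$g])^2)
  expect_equal(a$ss[1], ss_b, tolerance = 1e-10)
  expect_equal(a$ss[2], ss_w, tolerance = 1e-10)
  expect_equal(a$f[1], (ss_b / 2) / (ss_w / 15), tolerance = 1e-10)

  # degenerate: identical groups
  dfe <- data.frame(y = rep(1, 8), g = rep(c("a", "b"), 4))
  expect_warning(ae <- one_way_anova(dfe, "y", "g"), "residual")
  expect_true(is.na(ae$f[1]))
})

test_that("two-group F equals the squared pooled t statistic", {
  set.seed(29)
  df <- data.frame(y = c(rnorm(12, 0), rnorm(15, 1)),
                   g = rep(c("a", "b"), c(12, 15)))
  a <- one_way_anova(df, "y", "g")
  tt <- t.test(y ~ g, data = df, var.equal = TRUE)
  expect_equal(a$f[1], unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("Bonferroni planned adjustment is min(1, p * n) and monotone", {
  expect_equal(bonferroni_planned(0.01, 6), 0.06)
  expect_equal(bonferroni_planned(0.5, 6), 1.0)
  expect_error(bonferroni_planned(c(0.1, 0.2), 1), "n_comparisons")
  p <- sort(runif(20))
  adj <- bonferroni_planned(p, 25)
  expect_true(all(diff(adj) >= 0))
  expect_true(all(adj >= p & adj <= 1))
})

test_that("Bonferroni controls the family-wise error under the null", {
  set.seed(41)
  reps <- 2000
  fwer <- mean(replicate(reps, {
    p <- vapply(1:6, function(i)
      t.test(rnorm(8), rnorm(8), var.equal = TRUE)$p.value, 0)
    any(bonferroni_planned(p, 6) < 0.05)
  }))
  expect_lte(fwer, 0.05 + 2 * sqrt(0.05 * 0.95 / reps) + 0.01)
})

test_that("Tukey-Kramer q statistics match hand arithmetic and the
           studentized range distribution", {
  # equal n, known means and MSE
  df <- data.frame(
    y = c(1, 2, 3, 11, 12, 13, 24, 25, 26),
    g = rep(c("a", "b", "c"), each = 3))
  res <- tukey_kramer(df, "y", "g")
  mse <- 1  # within-group variance of each group is 1 (n-1 denominators pool)
  se <- sqrt(mse / 2 * (1 / 3 + 1 / 3))
  expect_equal(res$q[res$group_a == "a" & res$group_b == "b"],
               10 / se, tolerance = 1e-12)
  expect_equal(res$q[res$group_a == "a" & res$group_b == "c"],
               23 / se, tolerance = 1e-12)
  # p-values from ptukey agree with independent quadrature of the CDF
  for (i in seq_len(nrow(res))) {
    p_or <- 1 - oracle_ptukey(res$q[i], k = 3, df = 6)
    expect_equal(res$p_adjusted[i], p_or, tolerance = 1e-4)
  }
})

test_that("identical groups give a null Tukey comparison", {
  df <- data.frame(y = rep(c(4, 5, 6, 7), 2),
                   g = rep(c("a", "b"), each = 4))
  res <- tukey_kramer(df, "y", "g")
  expect_equal(res$estimate, 0)
  expect_gt(res$p_adjusted, 0.999)
})

test_that("Type III sums of squares agree with car on unbalanced data", {
  set.seed(61)
  df <- data.frame(
    location_class = sample(c("AIS", "NON_AIS"), 90, replace = TRUE),
    brain_area = sample(c("CA1", "CA3", "BLA"), 90, replace = TRUE))
  df$y <- rnorm(90) + (df$location_class == "AIS") * 0.8 +
    (df$brain_area == "BLA") * 0.5
  got <- two_way_anova(df, "y")
  fit <- lm(y ~ loc * area,
            data = data.frame(y = df$y, loc = factor(df$location_class),
                              area = factor(df$brain_area)),
            contrasts = list(loc = "contr.sum", area = "contr.sum"))
  a3 <- car::Anova(fit, type = 3)
  expect_equal(got$ss[got$effect == "location"], a3["loc", "Sum Sq"],
               tolerance = 1e-10)
  expect_equal(got$ss[got$effect == "brain_area"], a3["area", "Sum Sq"],
               tolerance = 1e-10)
  expect_equal(got$ss[got$effect == "interaction"], a3["loc:area", "Sum Sq"],
               tolerance = 1e-10)
  expect_equal(got$p[got$effect == "location"],
               a3["loc", "Pr(>F)"], tolerance = 1e-10)
})

test_that("Tukey-Kramer handles unequal group sizes (Kramer form)", {
  set.seed(55)
  df <- data.frame(y = c(rnorm(5, 0), rnorm(9, 0), rnorm(14, 2)),
                   g = rep(c("a", "b", "c"), c(5, 9, 14)))
  res <- tukey_kramer(df, "y", "g")
  # cross-check against stats::TukeyHSD on the same data
  hsd <- TukeyHSD(aov(y ~ g, data = df))$g
  for (i in seq_len(nrow(res))) {
    key <- paste0(res$group_b[i], "-", res$group_a[i])
    expect_equal(res$p_adjusted[i], hsd[key, "p adj"], tolerance = 1e-8)
    expect_equal(-res$estimate[i], hsd[key, "diff"], tolerance = 1e-10)
  }
})

test_that("Bonferroni t-tests recover planted shifts and the F identity", {
  set.seed(17)
  d <- data.frame(value = c(rnorm(40, 0), rnorm(40, 2)),
                  location_class = rep(c("AIS", "NON_AIS"), each = 40),
                  metric = "m1")
  res <- bonferroni_t_tests(d, "value", "location_class", "metric")
  expect_lt(res$p_adjusted, 0.001)

  # identical samples -> t = 0, p_adj = 1
  d2 <- d; d2$value <- rep(d$value[1:40], 2)
  res2 <- bonferroni_t_tests(d2, "value", "location_class", "metric")
  expect_equal(res2$t, 0)
  expect_equal(res2$p_adjusted, 1)

  # t^2 equals the one-way F on the same two groups
  f <- one_way_anova(d, "value", "location_class")$f[1]
  expect_equal(res$t^2, f, tolerance = 1e-10)
})
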