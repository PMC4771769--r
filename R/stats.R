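#' Two-way factorial ANOVA (location x brain area)
#'
#' Full factorial ANOVA with interaction. Unbalanced designs (ROI counts
#' per cell are rarely equal) are handled with Type III sums of squares
#' under sum-to-zero contrasts, the factorial default of the classical
#' commercial statistics packages used in this field; for balanced data
#' Type III reduces to the textbook decomposition. Missing responses (e.g.
#' the missing mean size of an ROI with no retained clusters) are dropped
#' listwise.
#'
#' @param data data frame.
#' @param response name of the response column.
#' @param location name of the two-level location factor column
#'   (default `"location_class"`).
#' @param area name of the brain-area factor column (default `"brain_area"`).
#' @return data frame of class `anova_table` with one row per effect
#'   (`location`, `brain_area`, `interaction`, `residual`) and columns
#'   `df`, `ss`, `ms`, `f`, `p`. With zero residual variance all F and p
#'   are `NA` with a warning.
#' @export
two_way_anova <- function(data, response, location = "location_class",
                          area = "brain_area") {
  df <- data.frame(y = data[[response]],
                   loc = factor(data[[location]]),
                   area = factor(data[[area]]))
  df <- df[complete.cases(df), ]
  if (nlevels(droplevels(df$loc)) < 2L || nlevels(droplevels(df$area)) < 2L)
    stop("each factor needs at least 2 observed levels")
  df$loc <- droplevels(df$loc); df$area <- droplevels(df$area)
  cells <- table(df$loc, df$area)
  if (any(cells == 0L))
    stop("empty design cell(s); interaction is inestimable")
  # Type III sums of squares under sum-to-zero contrasts: for each term,
  # the increase in residual SS when that term's columns are dropped from
  # the full model matrix
  X <- stats::model.matrix(
    ~ loc * area, data = df,
    contrasts.arg = list(loc = "contr.sum", area = "contr.sum"))
  asn <- attr(X, "assign")
  y <- df$y
  rss <- function(M) {
    f <- stats::lm.fit(M, y)
    sum(f$residuals^2)
  }
  rss_full <- rss(X)
  df_res <- nrow(X) - qr(X)$rank
  if (df_res < 1L) stop("residual df < 1")
  ms_res <- rss_full / df_res
  scale <- mean(y^2) + 1
  degenerate <- ms_res <= 1e-12 * scale
  eff <- c(location = 1L, brain_area = 2L, interaction = 3L)
  rows <- lapply(names(eff), function(e) {
    term <- eff[[e]]
    ss <- rss(X[, asn != term, drop = FALSE]) - rss_full
    dfe <- sum(asn == term)
    ms <- ss / dfe
    if (degenerate) {
      f <- NA_real_; p <- NA_real_
    } else {
      f <- ms / ms_res
      p <- pf(f, dfe, df_res, lower.tail = FALSE)
    }
    data.frame(effect = e, df = dfe, ss = ss, ms = ms, f = f, p = p,
               stringsAsFactors = FALSE)
  })
  if (degenerate)
    warning("zero residual mean square; F statistics undefined")
  out <- rbind(do.call(rbind, rows),
               data.frame(effect = "residual", df = df_res,
                          ss = rss_full, ms = ms_res,
                          f = NA_real_, p = NA_real_,
                          stringsAsFactors = FALSE))
  class(out) <- c("anova_table", "data.frame")
  out
}

#' One-way ANOVA
#'
#' Standard between/within decomposition, used e.g. to compare enrichment
#' ratios across brain areas. Missing responses are dropped.
#'
#' @param data data frame.
#' @param response response column name.
#' @param group grouping column name.
#' @return data frame of class `anova_table` with rows `group` and
#'   `residual`. Zero residual variance yields `NA` F and p with a warning.
#' @export
one_way_anova <- function(data, response, group) {
  df <- data.frame(y = data[[response]], g = factor(data[[group]]))
  df <- df[complete.cases(df), ]
  df$g <- droplevels(df$g)
  if (nlevels(df$g) < 2L) stop("need at least 2 groups")
  if (nrow(df) - nlevels(df$g) < 1L) stop("residual df < 1")
  fit <- lm(y ~ g, data = df)
  a <- suppressWarnings(anova(fit))
  ss_b <- a[1, "Sum Sq"]; df_b <- a[1, "Df"]
  ss_w <- a[2, "Sum Sq"]; df_w <- a[2, "Df"]
  ms_w <- ss_w / df_w
  if (ms_w <= 1e-12 * (mean(df$y^2) + 1) || !is.finite(ms_w)) {
    warning("zero residual mean square; F undefined")
    f <- NA_real_; p <- NA_real_
  } else {
    f <- (ss_b / df_b) / ms_w
    p <- pf(f, df_b, df_w, lower.tail = FALSE)
  }
  out <- data.frame(
    effect = c("group", "residual"),
    df = c(df_b, df_w), ss = c(ss_b, ss_w),
    ms = c(ss_b / df_b, ms_w), f = c(f, NA_real_), p = c(p, NA_real_),
    stringsAsFactors = FALSE)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Bonferroni adjustment for planned comparisons
#'
#' `p_adj = min(1, p * n_comparisons)`. The number of comparisons may
#' exceed the number of p-values supplied (a planned family can include
#' comparisons not carried out).
#'
#' @param p_values numeric vector of raw p-values.
#' @param n_comparisons size of the planned family
#'   (default `length(p_values)`).
#' @return vector of adjusted p-values.
#' @export
bonferroni_planned <- function(p_values, n_comparisons = length(p_values)) {
  if (n_comparisons < length(p_values))
    stop("n_comparisons must be >= number of p-values")
  pmin(1, p_values * n_comparisons)
}

#' Tukey-Kramer pairwise comparisons
#'
#' All pairwise group comparisons using the studentized range distribution
#' with the Kramer adjustment for unequal group sizes:
#' `q = |mean_i - mean_j| / sqrt(MSE/2 * (1/n_i + 1/n_j))`, with p-values
#' from the studentized range distribution with `k` groups and the pooled
#' residual df.
#'
#' @param data data frame.
#' @param response response column name.
#' @param group grouping column name.
#' @return data frame of class `comparison_table` with columns `group_a`,
#'   `group_b`, `estimate` (mean difference a - b), `q`, `p_adjusted`,
#'   `method`.
#' @export
tukey_kramer <- function(data, response, group) {
  y <- data[[response]]; g <- factor(data[[group]])
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- droplevels(g[keep])
  k <- nlevels(g)
  if (k < 2L) stop("need at least 2 groups")
  ns <- tabulate(g)
  means <- tapply(y, g, mean)
  df_res <- length(y) - k
  if (df_res < 1L) stop("pooled residual df < 1")
  mse <- sum((y - means[g])^2) / df_res
  if (mse <= 0) stop("zero residual mean square")
  combs <- utils::combn(k, 2)
  rows <- apply(combs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- abs(means[i] - means[j]) / se
    data.frame(group_a = levels(g)[i], group_b = levels(g)[j],
               estimate = unname(means[i] - means[j]), q = unname(q),
               p_adjusted = ptukey(q, nmeans = k, df = df_res,
                                   lower.tail = FALSE),
               method = "TUKEY_KRAMER", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Bonferroni-corrected two-sample t-tests over a metric family
#'
#' For each metric (e.g. Pearson r, M1, M2) compares the two locations with
#' a pooled-variance two-sample t-test and Bonferroni-corrects across the
#' metric family.
#'
#' @param data data frame with one row per ROI.
#' @param value name of the value column.
#' @param location name of the two-level grouping column.
#' @param metric name of the metric-family column (default `NULL`: a single
#'   test, family size 1).
#' @return data frame of class `comparison_table` with columns `metric`,
#'   `group_a`, `group_b`, `estimate`, `t`, `df`, `p_raw`, `p_adjusted`,
#'   `method`.
#' @export
bonferroni_t_tests <- function(data, value, location, metric = NULL) {
  metrics <- if (is.null(metric)) list(all = data) else
    split(data, data[[metric]])
  rows <- lapply(names(metrics), function(mn) {
    d <- metrics[[mn]]
    y <- d[[value]]; g <- factor(d[[location]])
    keep <- !is.na(y) & !is.na(g)
    y <- y[keep]; g <- droplevels(g[keep])
    if (nlevels(g) != 2L) stop("location must have exactly 2 levels")
    if (min(tabulate(g)) < 2L) stop("need >= 2 observations per location")
    y1 <- y[g == levels(g)[1]]; y2 <- y[g == levels(g)[2]]
    tt <- tryCatch(t.test(y1, y2, var.equal = TRUE), error = function(e) NULL)
    if (is.null(tt)) {
      # essentially constant data: a zero-difference family member scores
      # t = 0, p = 1; a real difference with no variance is an error
      if (!isTRUE(all.equal(mean(y1), mean(y2))))
        stop("zero pooled variance with unequal means for metric '", mn, "'")
      tt <- list(statistic = 0, parameter = length(y) - 2, p.value = 1)
    }
    data.frame(metric = mn, group_a = levels(g)[1], group_b = levels(g)[2],
               estimate = mean(y1) - mean(y2),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value, p_adjusted = NA_real_,
               method = "BONFERRONI", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni_planned(out$p_raw, nrow(out))
  rownames(out) <- NULL
  class(out) <- c("comparison_table", "data.frame")
  out
}
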