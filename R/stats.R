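#' Two-sample or paired Student t-test
#'
#' Student's t with pooled variance for unpaired comparisons (Welch
#' available behind `var_equal = FALSE`), two-sided p.  Zero-variance
#' degeneracies are flagged rather than erroring: when the statistic is
#' undefined (no variance, equal means) p is reported as 1 with
#' `degenerate = TRUE`.
#'
#' @param x,y numeric samples (equal length when paired).
#' @param paired logical.
#' @param var_equal pooled variance (default TRUE, Student); FALSE gives
#'   Welch.
#' @return list of class `stat_result`: `test`, `statistic`, `df`,
#'   `p_value`, `groups` (n, mean, sd per group), `degenerate`.
#' @export
t_test <- function(x, y, paired = FALSE, var_equal = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (paired && length(x) != length(y)) {
    stop("paired test requires equal-length samples")
  }
  if (length(x) < 2L || length(y) < 2L) stop("need n >= 2 per sample")
  groups <- data.frame(group = c("x", "y"), n = c(length(x), length(y)),
                       mean = c(mean(x), mean(y)), sd = c(sd(x), sd(y)))
  degenerate <- if (paired) stats::var(x - y) == 0 else
    stats::var(x) == 0 && stats::var(y) == 0
  if (degenerate) {
    return(stat_result("t-test", NA_real_, NA_real_, 1, groups,
                       degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, paired = paired, var.equal = var_equal)
  stat_result(if (paired) "paired t-test" else "t-test",
              unname(ht$statistic), unname(ht$parameter), ht$p.value,
              groups)
}

#' One-way ANOVA
#'
#' F statistic with (k - 1, N - k) degrees of freedom.  On two groups
#' F equals the squared pooled-variance t statistic.
#'
#' @param groups list of numeric samples (>= 2 groups, each n >= 2), or a
#'   numeric vector together with `g`.
#' @param g optional factor when `groups` is a vector.
#' @return a `stat_result` with the F statistic, `df` of length 2.
#' @export
one_way_anova <- function(groups, g = NULL) {
  if (!is.null(g)) groups <- split(as.numeric(groups), g)
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("need n >= 2 in every group")
  }
  labs <- if (is.null(names(groups))) as.character(seq_along(groups))
          else names(groups)
  gs <- data.frame(group = labs,
                   n = vapply(groups, length, integer(1)),
                   mean = vapply(groups, mean, numeric(1)),
                   sd = vapply(groups, sd, numeric(1)))
  y <- unlist(groups, use.names = FALSE)
  if (stats::var(y) == 0) {
    return(stat_result("one-way ANOVA", NA_real_, c(NA_real_, NA_real_), 1,
                       gs, degenerate = TRUE))
  }
  f <- factor(rep(labs, times = gs$n), levels = labs)
  ht <- stats::oneway.test(y ~ f, var.equal = TRUE)
  stat_result("one-way ANOVA", unname(ht$statistic),
              unname(ht$parameter), ht$p.value, gs)
}

#' Pearson correlation with two-sided p
#'
#' @param x,y equal-length numeric samples, n >= 3, non-zero variance.
#' @return a `stat_result` with `statistic` = r and `t_value`.
#' @export
pearson_r <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need n >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  res <- stat_result("Pearson correlation", unname(ht$estimate),
                     unname(ht$parameter), ht$p.value,
                     data.frame(group = "xy", n = length(x),
                                mean = NA_real_, sd = NA_real_))
  res$t_value <- unname(ht$statistic)
  res
}

stat_result <- function(test, statistic, df, p, groups,
                        degenerate = FALSE) {
  structure(list(test = test, statistic = statistic, df = df,
                 p_value = p, groups = groups, degenerate = degenerate),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(x$test, ": ")
  if (x$degenerate) {
    cat("degenerate (zero variance); p reported as 1\n")
  } else {
    cat(sprintf("statistic = %.4g, df = %s, p = %.4g\n", x$statistic,
                paste(signif(x$df, 6), collapse = ", "), x$p_value))
  }
  for (i in seq_len(nrow(x$groups))) {
    g <- x$groups[i, ]
    cat(sprintf("  %s: n = %d, %.3f +/- %.3f\n", g$group, g$n, g$mean,
                g$sd))
  }
  invisible(x)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement --
#' the standard reproducibility index for intra- and interobserver
#' variability of manual measurements.  Computed from the mean squares of
#' the two-way subjects x raters decomposition; the confidence interval
#' follows McGraw & Wong's F-based formulation.
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns;
#'   no missing cells.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return list of class `icc_result`: `icc`, `model`, `ci` (lower,
#'   upper), `n_subjects`, `n_raters`, plus the mean squares.
#' @export
icc <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("missing cells are not supported")
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 5L) stop("need at least 5 subjects")
  if (k < 2L) stop("need at least 2 raters")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  msr <- k * sum((row_m - grand)^2) / (n - 1)              # subjects
  msc <- n * sum((col_m - grand)^2) / (k - 1)              # raters
  sse <- sum((ratings - outer(row_m, rep(1, k)) -
              outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))                          # residual
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  val <- if (denom == 0) 1 else (msr - mse) / denom

  # McGraw & Wong (1996) CI for ICC(A,1)
  alpha <- 1 - conf_level
  ci <- c(NA_real_, NA_real_)
  if (mse > 0) {
    a <- k * val / (n * (1 - val))
    b <- 1 + k * val * (n - 1) / (n * (1 - val))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lower, upper)
  } else if (val == 1) ci <- c(1, 1)
  structure(list(icc = val,
                 model = "two-way random, absolute agreement, single rater (ICC(2,1))",
                 ci = ci, conf_level = conf_level,
                 n_subjects = n, n_raters = k,
                 ms = c(msr = msr, msc = msc, mse = mse)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.4f (%d%% CI %.4f-%.4f), %d subjects x %d raters\n",
              x$icc, round(100 * x$conf_level), x$ci[1], x$ci[2],
              x$n_subjects, x$n_raters))
  invisible(x)
}

#' Group summary with omnibus test, in clinical-table layout
#'
#' Per-group n, mean and SD of a metric, with the omnibus p-value from a
#' pooled two-sample t-test (2 groups) or one-way ANOVA (> 2 groups) and
#' the significance stars used in the cohort tables ('*' at 0.05, '**' at
#' 0.005, '***' below 0.005).
#'
#' @param table a cohort data.frame (see [simulate_cohort()]).
#' @param metric metric column name.
#' @param group_by grouping column name (e.g. `"stent_type"`,
#'   `"vessel_type"`).
#' @return data.frame of per-group rows plus attributes `p_value`,
#'   `stars`, `test`.
#' @export
summarize_groups <- function(table, metric, group_by) {
  if (!metric %in% names(table)) stop("no such metric column: ", metric)
  if (!group_by %in% names(table)) stop("no such grouping column: ", group_by)
  vals <- table[[metric]]
  g <- factor(table[[group_by]])
  keep <- !is.na(vals)
  vals <- vals[keep]; g <- droplevels(g[keep])
  groups <- split(vals, g)
  if (length(groups) < 2L) stop("need >= 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("empty or singleton group in ", group_by)
  }
  res <- if (length(groups) == 2L) t_test(groups[[1]], groups[[2]])
         else one_way_anova(groups)
  out <- res$groups
  out$group <- names(groups)
  attr(out, "p_value") <- res$p_value
  attr(out, "stars") <- p_stars(res$p_value)
  attr(out, "test") <- res$test
  attr(out, "metric") <- metric
  attr(out, "degenerate") <- res$degenerate
  out
}

# Significance stars following the clinical-table legend.
p_stars <- function(p) {
  if (is.na(p)) "" else if (p < 0.005) "***" else if (p <= 0.005) "**"
  else if (p <= 0.05) "*" else ""
}
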