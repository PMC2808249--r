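#' Ordinary-least-squares fit of deep on shallow size, tested against slope 1
#'
#' Regresses the deep-sea log sizes `y` on the shallow-water log sizes `x`
#' by least squares and tests the null that the slope equals 1 — the value
#' expected when deep-sea colonization leaves body size evolution unchanged
#' on average — with the standard t-test, `t = (b - 1) / SE(b)` on `n - 2`
#' degrees of freedom, two-sided. A slope below 1 is the island-rule
#' signature (convergence of deep-sea sizes), but note that this test is
#' anti-conservative whenever the shallow lineages carry their own drift
#' variance: the resulting attenuation pushes the OLS slope below 1 under
#' the null. See [ols_randomization_study()].
#'
#' @param pairs a `genus_pairs` data frame from [build_genus_pairs()], or any
#'   data frame with numeric `x` and `y`.
#' @return A `size_regression` object: list with `method = "ols"`, `slope`,
#'   `intercept`, `statistic` (t), `p_value`, `n`.
#' @export
ols_fit <- function(pairs) {
  x <- pairs$x; y <- pairs$y
  n <- length(x)
  if (n < 3L) stop("need at least 3 genera for a fit")
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) stop("degenerate input: zero variance in x")
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(x)
  rss <- sum((y - a - b * x)^2)
  se <- sqrt(rss / (n - 2L) / sxx)
  # exact fits (rss = 0): t is 0 on the null line, +/-Inf off it
  t_stat <- if (se > 0) (b - 1) / se else if (b == 1) 0 else sign(b - 1) * Inf
  p <- 2 * stats::pt(-abs(t_stat), df = n - 2L)
  structure(list(method = "ols", slope = b, intercept = a,
                 statistic = t_stat, p_value = p, n = n),
            class = "size_regression")
}

#' Standardized-major-axis fit of deep on shallow size
#'
#' The SMA (reduced-major-axis) slope is `sign(r) * sd(y)/sd(x)`, the
#' symmetric line fit appropriate when both axes carry error — as both the
#' shallow and deep genus means do. Its natural test statistic for the null
#' slope of 1 is the Pearson correlation between `x + y` and `x - y`: since
#' `cov(x + y, x - y) = var(x) - var(y)`, the statistic has expectation zero
#' exactly when the two size distributions have equal spread, i.e. when the
#' SMA slope is 1. No analytic p-value is attached; significance is assessed
#' by the within-genus permutation test ([permutation_test()]), which is
#' distribution-free.
#'
#' @inheritParams ols_fit
#' @return A `size_regression` object with `method = "sma"`, `slope`,
#'   `intercept`, `statistic` (`r(x+y, x-y)`), `p_value = NA`, `n`.
#' @export
sma_fit <- function(pairs) {
  x <- pairs$x; y <- pairs$y
  n <- length(x)
  if (n < 3L) stop("need at least 3 genera for a fit")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx <= 0 || sy <= 0) stop("degenerate input: zero variance in x or y")
  r <- stats::cor(x, y)
  s <- if (r == 0) {
    warning("x and y uncorrelated; SMA slope sign set to +1")
    1
  } else sign(r)
  b <- s * sy / sx
  # the slope is defined whenever x and y vary; the test statistic also
  # needs variance on both derived axes (fails e.g. when y = c - x exactly)
  stat <- tryCatch(sma_statistic(x, y), error = function(e) {
    warning("SMA statistic undefined: ", conditionMessage(e))
    NA_real_
  })
  structure(list(method = "sma", slope = b,
                 intercept = mean(y) - b * mean(x),
                 statistic = stat, p_value = NA_real_, n = n),
            class = "size_regression")
}

# r(x + y, x - y); errors on zero variance of either derived axis
sma_statistic <- function(x, y) {
  u <- x + y; v <- x - y
  if (stats::sd(u) <= 0 || stats::sd(v) <= 0) {
    stop("degenerate input: zero variance in x + y or x - y")
  }
  stats::cor(u, v)
}

#' @export
print.size_regression <- function(x, ...) {
  cat(sprintf("%s regression (n = %d genera)\n", toupper(x$method), x$n))
  cat(sprintf("  slope = %.4f, intercept = %.4f\n", x$slope, x$intercept))
  if (x$method == "ols") {
    cat(sprintf("  t (H0: slope = 1) = %.4f, two-sided p = %.4g\n",
                x$statistic, x$p_value))
  } else {
    cat(sprintf("  statistic r(x+y, x-y) = %.4f (p via permutation_test)\n",
                x$statistic))
  }
  invisible(x)
}

# Within-group correlation between the SMA residual axis (y - b x) and
# fitted axis (y + b x); zero at the group's own SMA slope.
slope_axis_cor <- function(x, y, b) {
  stats::cor(y - b * x, y + b * x)
}

#' Likelihood-ratio test for a common SMA slope across groups
#'
#' Compares a one-slope model (a single SMA slope shared by all groups, each
#' keeping its own location) against a model with a separate SMA slope per
#' group. At a group's own SMA slope the residual axis `y - b x` and fitted
#' axis `y + b x` are exactly uncorrelated, so the separate-slope model
#' attains correlation zero in every group and the likelihood-ratio
#' statistic reduces to `-sum_i w_i log(1 - r_i(b)^2)` evaluated at the
#' common slope `b` that minimizes it, where `r_i(b)` is group *i*'s
#' residual/fitted-axis correlation and `w_i = n_i` (or `n_i - 5/2` with the
#' Bartlett-type small-sample correction). The statistic is referred to a
#' chi-square distribution with `(number of groups - 1)` degrees of freedom.
#' Used, e.g., to ask whether the island-rule slope differs between a focal
#' clade (Neogastropoda) and all other taxa.
#'
#' @param grouped_pairs named list of `genus_pairs` data frames (or any data
#'   frames with `x`, `y`), one per group; at least two groups, each with at
#'   least 3 pairs and positive variances.
#' @param bartlett apply the small-sample weight `n_i - 5/2` instead of
#'   `n_i`? Default `FALSE` (the plain likelihood ratio).
#' @return A `common_slope_test` object: `groups`, `group_slopes`,
#'   `common_slope`, `lr_statistic`, `df`, `p_value`.
#' @examples
#' set.seed(1)
#' g <- data.frame(x = rnorm(30), y = rnorm(30) * 0.3 + rnorm(30))
#' common_slope_test(list(a = g, b = g))  # identical groups: LR = 0, p = 1
#' @export
common_slope_test <- function(grouped_pairs, bartlett = FALSE) {
  if (length(grouped_pairs) < 2L) stop("need at least 2 groups")
  labs <- names(grouped_pairs) %||% as.character(seq_along(grouped_pairs))
  fits <- vector("list", length(grouped_pairs))
  for (i in seq_along(grouped_pairs)) {
    fits[[i]] <- tryCatch(sma_fit(grouped_pairs[[i]]),
                          error = function(e) {
                            stop("group '", labs[i], "': ",
                                 conditionMessage(e))
                          })
  }
  bs <- vapply(fits, `[[`, numeric(1), "slope")
  ns <- vapply(grouped_pairs, nrow, integer(1))
  w <- if (bartlett) ns - 2.5 else as.numeric(ns)
  if (length(unique(sign(bs))) > 1L) {
    warning("group SMA slopes differ in sign; common slope fitted on |b|",
            " with the majority sign")
  }
  sgn <- sign(sum(sign(bs)))
  if (sgn == 0) sgn <- 1
  negll <- function(logb) {
    b <- sgn * exp(logb)
    tot <- 0
    for (i in seq_along(grouped_pairs)) {
      r <- slope_axis_cor(grouped_pairs[[i]]$x, grouped_pairs[[i]]$y, b)
      tot <- tot + w[i] * -log(max(1 - r^2, .Machine$double.eps))
    }
    tot
  }
  interval <- log(range(abs(bs))) + c(-1, 1) * log(10)
  opt <- stats::optimize(negll, interval = interval, tol = 1e-10)
  lr <- max(opt$objective, 0)
  df <- length(grouped_pairs) - 1L
  structure(list(groups = labs, group_slopes = stats::setNames(bs, labs),
                 common_slope = sgn * exp(opt$minimum), lr_statistic = lr,
                 df = df,
                 p_value = stats::pchisq(lr, df = df, lower.tail = FALSE),
                 bartlett = bartlett),
            class = "common_slope_test")
}

#' @export
print.common_slope_test <- function(x, ...) {
  cat(sprintf("common SMA slope test (%d groups: %s)\n",
              length(x$groups), paste(x$groups, collapse = ", ")))
  cat(sprintf("  group slopes: %s\n",
              paste(sprintf("%.3f", x$group_slopes), collapse = ", ")))
  cat(sprintf("  common slope = %.4f; LR = %.4f on %d df; p = %.4g%s\n",
              x$common_slope, x$lr_statistic, x$df, x$p_value,
              if (x$bartlett) " (Bartlett-corrected)" else ""))
  invisible(x)
}
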