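#' Per-population regression of a gene-group signal on the cell-cycle
#' signal
#'
#' Ordinary least squares of the group signal (y) on the cell-cycle
#' signature signal (x) over the cells of one population, with the
#' transcriptome of each cell as a separate point.  Closed-form slope and
#' intercept, their standard errors, and r-squared as the
#' explained-variance fraction.
#'
#' @param signal `cell_signal` for the tested gene group.
#' @param cc_signal `cell_signal` for the cell-cycle signature (same
#'   cells, same order).
#' @param population Population label to restrict to; `NULL` uses all
#'   cells.
#' @param alpha Confidence level is `1 - alpha` (default 0.05).
#' @return `regression_fit` list: `population`, `slope`, `slope_se`,
#'   `slope_ci`, `intercept`, `intercept_se`, `r_squared`, `n_cells`,
#'   `sigma2`, `df`.
#' @export
fit_group_regression <- function(signal, cc_signal, population = NULL,
                                 alpha = 0.05) {
  xy <- align_signals(signal, cc_signal, population)
  x <- xy$x; y <- xy$y; n <- length(x)
  if (n < 3) stop("need >= 3 cells, got ", n)
  sxx <- sum((x - mean(x))^2)
  if (sxx < .Machine$double.eps * n)
    stop("cell-cycle signal is constant; slope undefined")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  b <- sxy / sxx
  a <- mean(y) - b * mean(x)
  resid <- y - a - b * x
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  df <- n - 2L
  sigma2 <- rss / df
  slope_se <- sqrt(sigma2 / sxx)
  intercept_se <- sqrt(sigma2 * (1 / n + mean(x)^2 / sxx))
  tq <- stats::qt(1 - alpha / 2, df)
  structure(
    list(population = if (is.null(population)) "all" else population,
         slope = b, slope_se = slope_se,
         slope_ci = c(b - tq * slope_se, b + tq * slope_se),
         intercept = a, intercept_se = intercept_se,
         r_squared = r2, n_cells = n, sigma2 = sigma2, df = df),
    class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "regression_fit [%s]: slope %.4g (SE %.3g), intercept %.4g, r2 %.3f, n %d\n",
    x$population, x$slope, x$slope_se, x$intercept, x$r_squared,
    x$n_cells))
  invisible(x)
}

#' Intercept difference between two populations at a common slope
#'
#' The core contrast of the package.  Fits the equal-slope (no
#' interaction) ANCOVA model `y = a + delta * g + b * x` over the cells of
#' both populations, where `g` indicates the contrast population; `delta`
#' is the vertical distance between the two parallel regression lines.
#' By extrapolation it is interpreted as the expression difference between
#' the populations at zero cell-cycle activity, i.e. the differentiation
#' effect with proliferation controlled for.  The common slope is the
#' pooled within-population slope; standard error, two-sided p-value and
#' confidence interval come from the standard linear-model covariance with
#' `n_total - 3` residual degrees of freedom, using the t distribution.
#'
#' @param signal,cc_signal `cell_signal` objects over the same cells.
#' @param contrast_pop,reference_pop Population labels; `delta` is
#'   contrast minus reference.
#' @param alpha Two-sided CI level is `1 - alpha`.
#' @return `intercept_contrast` list: `group`, `contrast`, `reference`,
#'   `delta`, `se`, `ci`, `p_value`, `slope`, `n_contrast`,
#'   `n_reference`, `df`.
#' @export
intercept_contrast <- function(signal, cc_signal, contrast_pop,
                               reference_pop, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  con <- align_signals(signal, cc_signal, contrast_pop)
  ref <- align_signals(signal, cc_signal, reference_pop)
  nc <- length(con$x); nr <- length(ref$x)
  if (nc < 3 || nr < 3)
    stop("both populations need >= 3 cells (contrast ", nc,
         ", reference ", nr, ")")
  n <- nc + nr
  x <- c(ref$x, con$x)
  if (sum((x - mean(x))^2) < .Machine$double.eps * n)
    stop("pooled cell-cycle signal is constant; slope undefined")
  sxx_c <- sum((con$x - mean(con$x))^2)
  sxx_r <- sum((ref$x - mean(ref$x))^2)
  sxy_c <- sum((con$x - mean(con$x)) * (con$y - mean(con$y)))
  sxy_r <- sum((ref$x - mean(ref$x)) * (ref$y - mean(ref$y)))
  sxx <- sxx_c + sxx_r
  if (sxx < .Machine$double.eps * n)
    stop("within-population cell-cycle signal is constant; slope undefined")
  b <- (sxy_c + sxy_r) / sxx
  delta <- (mean(con$y) - mean(ref$y)) - b * (mean(con$x) - mean(ref$x))
  a_ref <- mean(ref$y) - b * mean(ref$x)
  rss <- sum((ref$y - a_ref - b * ref$x)^2) +
    sum((con$y - a_ref - delta - b * con$x)^2)
  df <- n - 3L
  sigma2 <- rss / df
  dx <- mean(con$x) - mean(ref$x)
  se <- sqrt(sigma2 * (1 / nc + 1 / nr + dx^2 / sxx))
  p <- if (se > 0) 2 * stats::pt(-abs(delta / se), df)
       else if (abs(delta) > 0) 0 else 1   # zero-residual edge cases
  tq <- stats::qt(1 - alpha / 2, df)
  structure(
    list(group = attr(signal, "group") %||% "group",
         contrast = contrast_pop, reference = reference_pop,
         delta = delta, se = se, ci = c(delta - tq * se, delta + tq * se),
         p_value = p, slope = b, n_contrast = nc, n_reference = nr,
         df = df),
    class = "intercept_contrast")
}

#' @export
print.intercept_contrast <- function(x, ...) {
  cat(sprintf(
    "intercept_contrast [%s]: %s - %s = %.4g (SE %.3g, 95%% CI %.4g..%.4g, p %.3g)\n",
    x$group, x$contrast, x$reference, x$delta, x$se, x$ci[1], x$ci[2],
    x$p_value))
  invisible(x)
}

#' Linear-model adequacy against a quadratic alternative
#'
#' The intercept contrast is only meaningful for straight regression
#' lines (intercepts of curved fits are not comparable), so this check
#' quantifies how much of the variance captured by an order-2 polynomial
#' the straight line already captures, and whether the quadratic
#' coefficient is significant at all.
#'
#' @inheritParams fit_group_regression
#' @return `adequacy_report` list: `r_squared_linear`,
#'   `r_squared_quadratic`, `p_quadratic`, `linear_fraction`,
#'   `degenerate` (TRUE when the quadratic model explains essentially
#'   nothing and the fraction is reported as 0).
#' @export
adequacy_check <- function(signal, cc_signal, population = NULL) {
  xy <- align_signals(signal, cc_signal, population)
  x <- xy$x; y <- xy$y
  if (length(x) < 4) stop("need >= 4 cells for the quadratic fit")
  lin <- stats::lm(y ~ x)
  quad <- stats::lm(y ~ x + I(x^2))
  # explicit explained-variance fractions: summary.lm's ratio is pure
  # rounding noise when the total variance is (near) zero
  tss <- sum((y - mean(y))^2)
  r2l <- if (tss > 0) max(0, 1 - sum(stats::residuals(lin)^2) / tss)
         else 0
  r2q <- if (tss > 0) max(0, 1 - sum(stats::residuals(quad)^2) / tss)
         else 0
  cf <- suppressWarnings(summary(quad)$coefficients)
  p_quad <- if ("I(x^2)" %in% rownames(cf)) cf["I(x^2)", 4] else NA_real_
  degenerate <- r2q < 1e-12
  frac <- if (degenerate) 0 else r2l / r2q
  structure(
    list(r_squared_linear = r2l, r_squared_quadratic = r2q,
         p_quadratic = p_quad, linear_fraction = frac,
         degenerate = degenerate),
    class = "adequacy_report")
}

#' @export
print.adequacy_report <- function(x, ...) {
  cat(sprintf(
    "adequacy_report: r2 linear %.3f, quadratic %.3f, linear fraction %.3f, quadratic p %.3g\n",
    x$r_squared_linear, x$r_squared_quadratic, x$linear_fraction,
    x$p_quadratic))
  invisible(x)
}

# align tested and covariate signals cell-by-cell, optionally restricted
# to one population
align_signals <- function(signal, cc_signal, population = NULL) {
  stopifnot(inherits(signal, "cell_signal"),
            inherits(cc_signal, "cell_signal"))
  if (!identical(signal$cell_id, cc_signal$cell_id))
    stop("signals cover different cells or cell orders")
  keep <- if (is.null(population)) rep(TRUE, nrow(signal))
          else signal$label == population
  if (!any(keep) && !is.null(population))
    stop("unknown population label: ", population)
  list(x = cc_signal$signal[keep], y = signal$signal[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
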