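#' Bland-Altman agreement statistics
#'
#' Delineates systematic (bias = mean difference) and random (SD of the
#' differences) disagreement between two time-aligned measures, with 95%
#' limits of agreement `bias +/- 1.96 * SD` (classical multiplier, not a
#' t-quantile). Differences are `a - b`.
#'
#' @param a,b Paired numeric series of equal length (>= 2). Pairs with a
#'   missing value in either series are dropped (and counted out of `n`).
#' @return Object of class `agreement_stats`: `bias`, `sd` (n-1
#'   denominator), `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("series must have equal length")
  ok <- !is.na(a) & !is.na(b)
  d <- a[ok] - b[ok]
  if (length(d) < 2L) stop("need at least 2 complete pairs")
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sd = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = length(d)),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("bias %.3f +/- %.3f (95%% LoA %.3f to %.3f, n = %d)\n",
              x$bias, x$sd, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Ordinary least-squares regression of one measure on another
#'
#' Regresses `a` on `b` and reports slope, intercept and the coefficient
#' of determination `R^2 = 1 - SS_res / SS_tot`, a sensitive summary of
#' waveform correspondence.
#'
#' @param a,b Paired numeric series of equal length (>= 3); `b` must have
#'   non-zero variance.
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
linear_regression_r2 <- function(a, b) {
  if (length(a) != length(b)) stop("series must have equal length")
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]
  b <- b[ok]
  if (length(a) < 3L) stop("need at least 3 complete pairs")
  if (stats::var(b) == 0) stop("predictor has zero variance")
  fit <- stats::lm(a ~ b)
  sstot <- sum((a - mean(a))^2)
  r2 <- if (sstot == 0) 1 else 1 - sum(stats::resid(fit)^2) / sstot
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2,
       n = length(a))
}

#' Combined agreement summary for one treatment/component pair
#'
#' @param a Markerless-derived series.
#' @param b Criterion series.
#' @return One-row data frame with `bias`, `sd`, `loa_low`, `loa_high`,
#'   `r_squared`, `n`.
#' @export
agreement_summary <- function(a, b) {
  ba <- bland_altman(a, b)
  lr <- linear_regression_r2(a, b)
  data.frame(bias = ba$bias, sd = ba$sd,
             loa_low = ba$loa_low, loa_high = ba$loa_high,
             r_squared = lr$r_squared, n = ba$n)
}

#' Agreement comparison table
#'
#' Assembles per-treatment, per-component agreement statistics into the
#' standard reporting layout: one row per (treatment, component) with
#' bias, SD, the 95% limits-of-agreement interval and R^2.
#'
#' @param results Named list: `results[[treatment]][[component]]` is a
#'   one-row data frame from [agreement_summary()] (or a list with the
#'   same fields).
#' @return Data frame of class `comparison_table` with columns
#'   `treatment`, `component`, `bias`, `sd`, `loa_low`, `loa_high`,
#'   `r_squared`, `n` (header-only when `results` is empty).
#' @export
comparison_table <- function(results) {
  rows <- list()
  for (tr in names(results)) {
    for (cmp in names(results[[tr]])) {
      st <- results[[tr]][[cmp]]
      rows[[length(rows) + 1L]] <-
        data.frame(treatment = tr, component = cmp,
                   bias = st$bias, sd = st$sd,
                   loa_low = st$loa_low, loa_high = st$loa_high,
                   r_squared = st$r_squared, n = st$n)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(treatment = character(), component = character(),
               bias = numeric(), sd = numeric(), loa_low = numeric(),
               loa_high = numeric(), r_squared = numeric(), n = integer())
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Write a comparison table to CSV
#'
#' Values are rounded to `digits` decimals (3 by default, the precision
#' conventional for agreement tables).
#'
#' @param table A [comparison_table()].
#' @param path Output CSV path.
#' @param digits Decimal places for numeric columns.
#' @export
write_comparison_table <- function(table, path, digits = 3L) {
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "n"
  df[num] <- lapply(df[num], round, digits = digits)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
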