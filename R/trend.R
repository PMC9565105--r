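#' Least-squares trend of an annual series
#'
#' Closed-form ordinary-least-squares slope of a series against the time
#' index i = 1..n:
#' \deqn{slope = \frac{n\sum i\,y_i - \sum i \sum y_i}{n\sum i^2 - (\sum i)^2}}
#' with intercept \eqn{\bar y - slope\,\bar i}. Steps are annual, so the
#' slope is in units of the variable per year.
#'
#' @param series Numeric vector, gap-free, length >= 3.
#' @return Named numeric vector `c(slope =, intercept =)`.
#' @export
ols_slope_intercept <- function(series) {
  n <- length(series)
  if (n < 3L) stop("need at least 3 points for a trend, got ", n)
  if (any(!is.finite(series))) stop("series contains non-finite values")
  i <- seq_len(n)
  si <- sum(i); sii <- sum(i^2)
  slope <- (n * sum(i * series) - si * sum(series)) / (n * sii - si^2)
  c(slope = slope, intercept = mean(series) - slope * mean(i))
}

#' Two-sided p-value of the trend slope
#'
#' Student t test of the OLS slope with n - 2 degrees of freedom. A
#' degenerate fit (zero residual variance) is flagged with attribute
#' `degenerate = TRUE` and reported as p = 0 when the perfect line has a
#' nonzero slope, p = 1 when it is flat (a constant series carries no
#' trend signal).
#'
#' @param series Numeric vector, length >= 4.
#' @return p-value in `[0, 1]`.
#' @export
slope_pvalue <- function(series) {
  n <- length(series)
  if (n < 4L) stop("need at least 4 points for a significance test, got ", n)
  if (any(!is.finite(series))) stop("series contains non-finite values")
  fit <- ols_slope_intercept(series)
  i <- seq_len(n)
  resid <- series - (fit["intercept"] + fit["slope"] * i)
  rss <- sum(resid^2)
  sxx <- sum((i - mean(i))^2)
  if (rss <= .Machine$double.eps * sum(series^2)) {
    return(structure(if (abs(fit[["slope"]]) > 1e-12) 0 else 1,
                     degenerate = TRUE))
  }
  se <- sqrt(rss / (n - 2) / sxx)
  unname(2 * stats::pt(-abs(fit[["slope"]] / se), df = n - 2))
}

trend5_levels <- c("notable_degradation", "slight_degradation", "stable",
                   "slight_improvement", "notable_improvement")

#' Five-class NDVI trend label
#'
#' Classes and boundaries (slope in NDVI/yr): notable degradation
#' (slope < -0.005), slight degradation (-0.005 <= slope < -0.001),
#' stable (-0.001 <= slope <= 0.001), slight improvement
#' (0.001 < slope <= 0.005), notable improvement (slope > 0.005).
#'
#' @param slope Numeric vector of finite slopes.
#' @return Character vector of class labels.
#' @export
classify_trend5 <- function(slope) {
  if (any(!is.finite(slope))) stop("non-finite slope")
  out <- character(length(slope))
  out[slope < -0.005] <- "notable_degradation"
  out[slope >= -0.005 & slope < -0.001] <- "slight_degradation"
  out[slope >= -0.001 & slope <= 0.001] <- "stable"
  out[slope > 0.001 & slope <= 0.005] <- "slight_improvement"
  out[slope > 0.005] <- "notable_improvement"
  out
}

#' Three-class NDVI trend label
#'
#' The coarser cut used when crossing past trend with future
#' persistence: degradation (slope < -0.001), stable
#' (-0.001 <= slope <= 0.001), improvement (slope > 0.001).
#'
#' @param slope Numeric vector of finite slopes.
#' @return Character vector: `degradation`, `stable`, `improvement`.
#' @export
classify_trend3 <- function(slope) {
  if (any(!is.finite(slope))) stop("non-finite slope")
  ifelse(slope < -0.001, "degradation",
         ifelse(slope > 0.001, "improvement", "stable"))
}

# vectorized OLS over pixel columns of an n x npix matrix; returns
# slope/intercept/p vectors (shared machinery for trend and attribution maps)
ols_columns <- function(Y) {
  n <- nrow(Y)
  i <- seq_len(n)
  si <- sum(i); sii <- sum(i^2)
  sxx <- sii - si^2 / n
  slope <- (n * colSums(Y * i) - si * colSums(Y)) / (n * sii - si^2)
  intercept <- colMeans(Y) - slope * mean(i)
  fitted <- outer(i, slope) + rep(intercept, each = n)
  rss <- colSums((Y - fitted)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  tt <- slope / se
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  degen <- rss <= .Machine$double.eps * colSums(Y^2)
  p[degen] <- ifelse(abs(slope[degen]) > 1e-12, 0, 1)
  list(slope = slope, intercept = intercept, p_value = p)
}

#' Per-pixel trend map with five-class labelling
#'
#' Fits the annual trend on every valid pixel of an NDVI cube, tests the
#' slope at `sig_level`, labels pixels with [classify_trend5()], and
#' tabulates area fractions over valid pixels.
#'
#' @param cube An [annual_cube()] of growing-season annual NDVI.
#' @param valid_mask Optional logical matrix from [build_valid_mask()];
#'   defaults to all non-nodata pixels.
#' @param sig_level Significance threshold for the slope test (default 0.1).
#' @return A list of class `trend_map`: matrices `slope`, `intercept`,
#'   `p_value`, `class5` (character, `NA` off-mask), and `summary` with
#'   `class_fractions` (all five classes, summing to 1), `frac_positive`
#'   (share of valid pixels with slope > 0), `frac_significant`, and
#'   `mean_slope`.
#' @export
trend_map <- function(cube, valid_mask = NULL, sig_level = 0.1) {
  stopifnot(inherits(cube, "annual_cube"))
  d <- dim(cube$values)
  if (is.null(valid_mask)) valid_mask <- !cube$nodata_mask
  idx <- which(valid_mask & !cube$nodata_mask)
  if (length(idx) == 0L) stop("no valid pixels to analyse")
  Y <- matrix(cube$values, nrow = d[1])[, idx, drop = FALSE]
  fit <- ols_columns(Y)

  as_grid <- function(v) {
    m <- matrix(NA_real_, d[2], d[3]); m[idx] <- v; m
  }
  class5 <- matrix(NA_character_, d[2], d[3])
  class5[idx] <- classify_trend5(fit$slope)

  fr <- vapply(trend5_levels,
               function(cl) mean(class5[idx] == cl), 0)
  summary <- list(
    n_valid = length(idx),
    mean_slope = mean(fit$slope),
    class_fractions = data.frame(class = trend5_levels,
                                 fraction = unname(fr)),
    frac_positive = mean(fit$slope > 0),
    frac_significant = mean(fit$p_value < sig_level)
  )
  structure(list(slope = as_grid(fit$slope),
                 intercept = as_grid(fit$intercept),
                 p_value = as_grid(fit$p_value),
                 class5 = class5,
                 sig_level = sig_level,
                 summary = summary),
            class = "trend_map")
}

#' @export
print.trend_map <- function(x, ...) {
  s <- x$summary
  cat("trend_map:", s$n_valid, "valid pixels; mean slope",
      signif(s$mean_slope, 4), "/yr;",
      sprintf("%.1f%% slope>0; %.1f%% significant (p<%g)\n",
              100 * s$frac_positive, 100 * s$frac_significant, x$sig_level))
  invisible(x)
}
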