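#' Rescaled-range (R/S) curve of a series
#'
#' For each window size r the series is split into g = floor(n/r)
#' non-overlapping consecutive groups (trailing remainder discarded).
#' Per group: mean, cumulative deviations from the mean, range
#' R = max - min of the cumulative deviations, and population standard
#' deviation S (divisor r). The rescaled range of the group is R/S, and
#' RS-bar(r) is the mean over groups. Groups with S = 0 are dropped; a
#' window size whose groups are all degenerate is omitted.
#'
#' @param series Numeric vector, length n >= 4.
#' @param window_sizes Integer vector of r values; default `2:(n %/% 2)`.
#' @return data.frame with columns `r`, `rs_bar`, `n_groups` (usable
#'   groups). Errors if no usable window size remains (e.g. a constant
#'   series); the log-log fit in [hurst_exponent()] additionally needs
#'   at least two points.
#' @export
rs_curve <- function(series, window_sizes = NULL) {
  n <- length(series)
  if (n < 4L) stop("need at least 4 points for R/S analysis, got ", n)
  if (any(!is.finite(series))) stop("series contains non-finite values")
  if (is.null(window_sizes)) window_sizes <- 2:(n %/% 2L)
  window_sizes <- sort(unique(as.integer(window_sizes)))
  if (any(window_sizes < 2L | window_sizes > n %/% 2L)) {
    stop("window sizes must lie in [2, floor(n/2)]")
  }
  rows <- lapply(window_sizes, function(r) {
    g <- n %/% r
    seg <- matrix(series[seq_len(g * r)], nrow = r)   # one group per column
    mu <- colMeans(seg)
    dev <- sweep(seg, 2L, mu)
    X <- apply(dev, 2L, cumsum)
    if (r == 1L) X <- matrix(X, nrow = 1L)
    R <- apply(X, 2L, max) - apply(X, 2L, min)
    S <- sqrt(colMeans(dev^2))
    ok <- S > 0
    if (!any(ok)) return(NULL)
    data.frame(r = r, rs_bar = mean(R[ok] / S[ok]), n_groups = sum(ok))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("no usable window sizes (all groups have zero variance)")
  }
  out
}

h7_levels <- c("strong_anti", "medium_anti", "weak_anti", "random",
               "weak_sust", "medium_sust", "strong_sust")

#' Seven-class persistence label from a Hurst exponent
#'
#' Classes: strong anti-sustainability (0 < H <= 0.2), medium
#' anti-sustainability (0.2 < H <= 0.35), weak anti-sustainability
#' (0.35 < H < 0.5), random sequence (H = 0.5 exactly), weak
#' sustainability (0.5 < H <= 0.65), medium sustainability
#' (0.65 < H <= 0.8), strong sustainability (0.8 < H < 1). H > 0.5 means
#' the past trend tends to continue; H < 0.5 means it tends to reverse.
#'
#' R/S estimates on short series may fall outside (0, 1); with
#' `clamp = TRUE` (default) they are clamped into (0, 1) for labelling
#' and flagged in the `clamped` attribute of the result.
#'
#' @param H Numeric vector of Hurst exponents.
#' @param clamp Clamp estimates outside (0, 1) instead of erroring.
#' @return Character vector of labels, with attribute `clamped`.
#' @export
classify_h7 <- function(H, clamp = TRUE) {
  if (any(!is.finite(H))) stop("non-finite Hurst exponent")
  clamped <- H <= 0 | H >= 1
  if (any(clamped)) {
    if (!clamp) stop("Hurst exponent outside (0, 1)")
    H <- pmin(pmax(H, 1e-9), 1 - 1e-9)
  }
  out <- character(length(H))
  out[H <= 0.2] <- "strong_anti"
  out[H > 0.2 & H <= 0.35] <- "medium_anti"
  out[H > 0.35 & H < 0.5] <- "weak_anti"
  out[H == 0.5] <- "random"
  out[H > 0.5 & H <= 0.65] <- "weak_sust"
  out[H > 0.65 & H <= 0.8] <- "medium_sust"
  out[H > 0.8] <- "strong_sust"
  attr(out, "clamped") <- clamped
  out
}

#' R/S Hurst exponent of a series
#'
#' Least-squares fit of ln RS-bar = ln c + H ln r over the usable window
#' sizes of [rs_curve()]. H = 0.5 indicates an uncorrelated series,
#' H > 0.5 a persistent one (future change continues the past trend),
#' H < 0.5 an anti-persistent one.
#'
#' @param series Numeric vector.
#' @param window_sizes Optional window sizes, see [rs_curve()]. For long
#'   validation series, powers of two well inside `[16, n/8]` tame the
#'   small-window bias; the short-series default is `2:(n %/% 2)`.
#' @return List of class `hurst_result`: `H`, `fit_intercept` (ln c),
#'   `rs_points` (the fitted curve), `h_class` (seven-class label),
#'   `clamped` flag.
#' @export
hurst_exponent <- function(series, window_sizes = NULL) {
  cv <- rs_curve(series, window_sizes)
  if (nrow(cv) < 2L) {
    stop("fewer than 2 usable window sizes; cannot fit the R/S line")
  }
  lr <- log(cv$r); ls <- log(cv$rs_bar)
  H <- stats::cov(lr, ls) / stats::var(lr)
  a <- mean(ls) - H * mean(lr)
  cls <- classify_h7(H)
  structure(list(H = H, fit_intercept = a, rs_points = cv,
                 h_class = as.vector(cls),
                 clamped = attr(cls, "clamped")),
            class = "hurst_result")
}

#' @export
print.hurst_result <- function(x, ...) {
  cat("hurst_result: H =", signif(x$H, 4), "(", x$h_class, "),",
      nrow(x$rs_points), "window sizes\n")
  invisible(x)
}

#' Combined past-trend x future-persistence label
#'
#' Crosses the three-class past trend (degradation / stable /
#' improvement at the +/-0.001 NDVI/yr cut) with the seven-class
#' persistence label, e.g. `improvement_medium_sust`. When every H lies
#' in (0.2, 1) and never exactly at 0.5 — as observed in practice —
#' five persistence classes occur and the label space has 15 cases.
#'
#' @param slope Numeric vector of NDVI trends (NDVI/yr).
#' @param h_class Character vector of [classify_h7()] labels (recycled
#'   rules not applied; lengths must match).
#' @return Character vector `"<trend3>_<h_class>"`.
#' @export
combine_trend_persistence <- function(slope, h_class) {
  if (length(slope) != length(h_class)) {
    stop("slope and h_class lengths differ")
  }
  if (!all(h_class %in% h7_levels)) {
    stop("unknown persistence class: ",
         paste(setdiff(h_class, h7_levels), collapse = ", "))
  }
  paste(classify_trend3(slope), h_class, sep = "_")
}

#' Per-pixel Hurst map with seven-class labelling
#'
#' @param cube An [annual_cube()] of growing-season annual NDVI.
#' @param valid_mask Optional logical matrix of pixels to analyse.
#' @param window_sizes Optional window sizes, see [rs_curve()].
#' @return List of class `hurst_map`: matrices `H` (unclamped estimate),
#'   `h_class`, `clamped`; and `summary` with mean/min/max H, share of
#'   valid pixels with H > 0.5, and class shares.
#' @export
hurst_map <- function(cube, valid_mask = NULL, window_sizes = NULL) {
  stopifnot(inherits(cube, "annual_cube"))
  d <- dim(cube$values)
  if (is.null(valid_mask)) valid_mask <- !cube$nodata_mask
  idx <- which(valid_mask & !cube$nodata_mask)
  if (length(idx) == 0L) stop("no valid pixels to analyse")
  Y <- matrix(cube$values, nrow = d[1])[, idx, drop = FALSE]
  H <- numeric(length(idx)); cl <- character(length(idx))
  clamped <- logical(length(idx))
  for (j in seq_along(idx)) {
    hr <- hurst_exponent(Y[, j], window_sizes)
    H[j] <- hr$H; cl[j] <- hr$h_class; clamped[j] <- hr$clamped
  }
  Hg <- matrix(NA_real_, d[2], d[3]); Hg[idx] <- H
  cg <- matrix(NA_character_, d[2], d[3]); cg[idx] <- cl
  fg <- matrix(NA, d[2], d[3]); fg[idx] <- clamped
  shares <- vapply(h7_levels, function(x) mean(cl == x), 0)
  structure(list(H = Hg, h_class = cg, clamped = fg,
                 summary = list(n_valid = length(idx),
                                mean_H = mean(H), min_H = min(H),
                                max_H = max(H),
                                frac_persistent = mean(H > 0.5),
                                class_shares = data.frame(
                                  class = h7_levels,
                                  fraction = unname(shares)))),
            class = "hurst_map")
}

#' Management hotspots from trend, significance and persistence
#'
#' Two disjoint priority masks: `degradation_sustained` — pixels with a
#' significant past degradation trend expected to continue
#' (slope < -0.001, p < sig_level, H > 0.5) — and
#' `improvement_unsustained` — pixels with a significant past
#' improvement expected to reverse (slope > 0.001, p < sig_level,
#' H < 0.5).
#'
#' @param slope,p_value,H Aligned numeric matrices (e.g. from
#'   [trend_map()] and [hurst_map()]).
#' @param slope_cut Trend cut in NDVI/yr (default 0.001).
#' @param sig_level Significance gate (default 0.1).
#' @return List with logical matrices `degradation_sustained` and
#'   `improvement_unsustained` (`FALSE` wherever any input is `NA`).
#' @export
extract_hotspots <- function(slope, p_value, H, slope_cut = 0.001,
                             sig_level = 0.1) {
  if (!all(dim(slope) == dim(p_value)) || !all(dim(slope) == dim(H))) {
    stop("slope, p_value and H grids are not aligned")
  }
  ok <- !is.na(slope) & !is.na(p_value) & !is.na(H)
  a <- ok & slope < -slope_cut & p_value < sig_level & H > 0.5
  b <- ok & slope > slope_cut & p_value < sig_level & H < 0.5
  a[is.na(a)] <- FALSE; b[is.na(b)] <- FALSE
  list(degradation_sustained = a, improvement_unsustained = b)
}
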