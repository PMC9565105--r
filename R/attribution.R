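#' Fit the per-pixel climate model NDVI ~ T + P
#'
#' Binary (two-predictor) regression of growing-season NDVI on annual
#' mean air temperature and annual precipitation. The fitted values
#' (`predicted`) carry the climate-driven part of the signal; the
#' residuals (`NDVI - predicted`) carry the part not explained by
#' climate, attributed to human activities.
#'
#' If T and P are collinear (rank-deficient design) the minimum-norm
#' least-squares solution is returned and `collinearity_flag` is set; if
#' both predictors are constant the fit degrades to intercept-only.
#'
#' @param ndvi,temp,precip Numeric vectors of equal length n >= 4.
#' @return List of class `climate_fit`: coefficients `a` (NDVI per degC),
#'   `b` (NDVI per mm), `c` (intercept), `predicted`, `residuals`,
#'   `collinearity_flag`.
#' @export
fit_climate_model <- function(ndvi, temp, precip) {
  n <- length(ndvi)
  if (n < 4L) stop("need at least 4 years to fit the climate model, got ", n)
  if (length(temp) != n || length(precip) != n) {
    stop("ndvi, temp and precip must have equal length")
  }
  if (any(!is.finite(c(ndvi, temp, precip)))) {
    stop("non-finite values in climate-model inputs")
  }
  if (stats::var(temp) == 0 && stats::var(precip) == 0) {
    # no climate signal at all: intercept-only fit
    pred <- rep(mean(ndvi), n)
    return(structure(list(a = 0, b = 0, c = mean(ndvi),
                          predicted = pred, residuals = ndvi - pred,
                          collinearity_flag = TRUE),
                     class = "climate_fit"))
  }
  X <- cbind(1, temp, precip)
  qrX <- qr(X)
  flag <- qrX$rank < 3L
  if (!flag) {
    beta <- qr.coef(qrX, ndvi)
  } else {
    # minimum-norm solution via the pseudoinverse
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], ndvi)) / sv$d[pos])
    beta <- as.vector(beta)
  }
  pred <- as.vector(X %*% beta)
  beta <- unname(beta)
  structure(list(a = beta[2], b = beta[3], c = beta[1],
                 predicted = pred, residuals = ndvi - pred,
                 collinearity_flag = flag),
            class = "climate_fit")
}

attribution_conditions <- c("proportional_greening", "climate_greening",
                            "human_greening", "proportional_browning",
                            "climate_browning", "human_browning",
                            "undefined_stable")

#' Relative contributions of climate change and human activities
#'
#' Converts the trends of the observed NDVI series, the climate-predicted
#' series, and the residual series into percentage contributions of
#' climate change (CC) and human activities (HA), by the six-condition
#' scheme: when observed, predicted and residual trends share one sign,
#' CC = 100 * slope_pre / slope_obs and HA = 100 * slope_res / slope_obs;
#' when the predicted and residual trends disagree in sign, 100% is
#' assigned to the component whose sign matches the observed trend.
#' Pixels with |slope_obs| <= `eps` are `undefined_stable` (the scheme
#' divides by the observed trend) and get `NA` contributions. The same
#' `eps` zeroes the sign of component slopes, so a residual trend that
#' is pure floating-point dust (e.g. in a noise-free climate-only
#' scenario) yields exactly (100, 0) rather than 100 - 1e-16.
#'
#' @param slope_obs,slope_pre Numeric vectors (NDVI/yr).
#' @param slope_res Residual-trend vector; defaults to
#'   `slope_obs - slope_pre` (the exact decomposition). If supplied it is
#'   checked against that identity.
#' @param eps Stability threshold on `|slope_obs|` (default 1e-8).
#' @param tol Tolerance for the decomposition check (default 1e-6).
#' @return data.frame with `cc_pct`, `ha_pct` (in `[0, 100]`, summing to
#'   100 where defined) and `condition`.
#' @export
contribution_rates <- function(slope_obs, slope_pre, slope_res = NULL,
                               eps = 1e-8, tol = 1e-6) {
  if (is.null(slope_res)) {
    slope_res <- slope_obs - slope_pre
  } else if (any(abs(slope_res - (slope_obs - slope_pre)) >
                 pmax(tol, tol * abs(slope_obs)))) {
    stop("inconsistent slope triple: slope_res must equal slope_obs - slope_pre")
  }
  m <- length(slope_obs)
  cc <- rep(NA_real_, m); ha <- rep(NA_real_, m)
  cond <- rep("undefined_stable", m)

  pos <- is.finite(slope_obs) & slope_obs > eps
  neg <- is.finite(slope_obs) & slope_obs < -eps
  spre <- ifelse(abs(slope_pre) <= eps, 0, slope_pre)
  sres <- ifelse(abs(slope_res) <= eps, 0, slope_res)

  # greening: both components strictly positive -> proportional shares;
  # otherwise all weight on the component matching the observed sign.
  prop <- pos & spre > 0 & sres > 0
  cc[prop] <- 100 * slope_pre[prop] / slope_obs[prop]
  cond[prop] <- "proportional_greening"
  cg <- pos & !prop & spre > 0
  cc[cg] <- 100; cond[cg] <- "climate_greening"
  hg <- pos & !prop & !cg
  cc[hg] <- 0; cond[hg] <- "human_greening"

  propn <- neg & spre < 0 & sres < 0
  cc[propn] <- 100 * slope_pre[propn] / slope_obs[propn]
  cond[propn] <- "proportional_browning"
  cb <- neg & !propn & spre < 0
  cc[cb] <- 100; cond[cb] <- "climate_browning"
  hb <- neg & !propn & !cb
  cc[hb] <- 0; cond[hb] <- "human_browning"

  ha[!is.na(cc)] <- 100 - cc[!is.na(cc)]
  data.frame(cc_pct = cc, ha_pct = ha, condition = cond)
}

#' Per-pixel climate/human attribution map
#'
#' Fits the climate model on every valid pixel, derives the trends of
#' the observed, predicted and residual series (the residual trend is
#' taken as `slope_obs - slope_pre`, the exact decomposition), and
#' assigns CC/HA contributions via [contribution_rates()].
#'
#' @param ndvi,temp,precip Aligned [annual_cube()]s.
#' @param valid_mask Optional logical matrix of pixels to analyse.
#' @param zones Optional [zone_mask()] for per-zone HA summaries.
#' @param eps Stability threshold passed to [contribution_rates()].
#' @return List of class `attribution_map`: matrices `slope_obs`,
#'   `slope_pre`, `slope_res`, `cc_pct`, `ha_pct`, `condition`,
#'   `collinearity`; and `summary` with overall means over defined
#'   pixels, means stratified by the sign of the observed trend, counts,
#'   and (when `zones` is given) per-zone mean HA and a 20-point-bin HA
#'   histogram.
#' @export
attribute_map <- function(ndvi, temp, precip, valid_mask = NULL,
                          zones = NULL, eps = 1e-8) {
  stopifnot(inherits(ndvi, "annual_cube"), inherits(temp, "annual_cube"),
            inherits(precip, "annual_cube"))
  d <- dim(ndvi$values)
  if (!all(dim(temp$values) == d) || !all(dim(precip$values) == d)) {
    stop("ndvi, temp and precip cubes are not aligned")
  }
  if (is.null(valid_mask)) valid_mask <- !ndvi$nodata_mask
  idx <- which(valid_mask & !ndvi$nodata_mask &
               !temp$nodata_mask & !precip$nodata_mask)
  if (length(idx) == 0L) stop("no valid pixels to attribute")
  n <- d[1]
  Y <- matrix(ndvi$values, nrow = n)[, idx, drop = FALSE]
  TT <- matrix(temp$values, nrow = n)[, idx, drop = FALSE]
  PP <- matrix(precip$values, nrow = n)[, idx, drop = FALSE]

  pred <- matrix(NA_real_, n, length(idx))
  coll <- logical(length(idx))
  for (j in seq_along(idx)) {
    f <- fit_climate_model(Y[, j], TT[, j], PP[, j])
    pred[, j] <- f$predicted
    coll[j] <- f$collinearity_flag
  }
  slope_obs <- ols_columns(Y)$slope
  slope_pre <- ols_columns(pred)$slope
  slope_res <- slope_obs - slope_pre
  contrib <- contribution_rates(slope_obs, slope_pre, slope_res, eps = eps)

  as_grid <- function(v, mode = NA_real_) {
    m <- matrix(mode, d[2], d[3]); m[idx] <- v; m
  }
  cc_grid <- as_grid(contrib$cc_pct)
  ha_grid <- as_grid(contrib$ha_pct)
  cond_grid <- as_grid(contrib$condition, NA_character_)

  defined <- !is.na(contrib$cc_pct)
  up <- defined & slope_obs > 0
  dn <- defined & slope_obs < 0
  summary <- list(
    n_valid = length(idx),
    n_defined = sum(defined),
    n_undefined = sum(!defined),
    mean_cc = mean(contrib$cc_pct[defined]),
    mean_ha = mean(contrib$ha_pct[defined]),
    mean_cc_greening = if (any(up)) mean(contrib$cc_pct[up]) else NA_real_,
    mean_ha_greening = if (any(up)) mean(contrib$ha_pct[up]) else NA_real_,
    mean_cc_browning = if (any(dn)) mean(contrib$cc_pct[dn]) else NA_real_,
    mean_ha_browning = if (any(dn)) mean(contrib$ha_pct[dn]) else NA_real_
  )
  if (!is.null(zones)) {
    vm <- matrix(FALSE, d[2], d[3]); vm[idx[defined]] <- TRUE
    summary$zonal_mean_ha <- zonal_summary(ha_grid, zones, "mean",
                                           valid_mask = vm)
    summary$zonal_ha_bins <- zonal_summary(ha_grid, zones, "histogram",
                                           breaks = seq(0, 100, by = 20),
                                           valid_mask = vm)
  }
  structure(list(slope_obs = as_grid(slope_obs),
                 slope_pre = as_grid(slope_pre),
                 slope_res = as_grid(slope_res),
                 cc_pct = cc_grid, ha_pct = ha_grid,
                 condition = cond_grid,
                 collinearity = as_grid(coll, NA),
                 summary = summary),
            class = "attribution_map")
}

#' @export
print.attribution_map <- function(x, ...) {
  s <- x$summary
  cat("attribution_map:", s$n_defined, "defined pixels (",
      s$n_undefined, "stable/undefined );",
      sprintf("mean CC %.2f%%, mean HA %.2f%%\n", s$mean_cc, s$mean_ha))
  invisible(x)
}
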