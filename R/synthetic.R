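#' Synthetic-scenario configuration
#'
#' Defines a synthetic study region whose NDVI is generated as
#' `NDVI_t = a*T_t + b*P_t + c + human_rate*t + noise`, with linear
#' climate trends plus interannual noise in T and P. Defaults emulate a
#' 21-year annual record over an alpine region: baseline temperature
#' 2 degC and precipitation 600 mm; a slowly cooling (-0.01 degC/yr) and
#' wetting (+2 mm/yr) climate dominated by interannual variability
#' (0.5 degC, 60 mm); NDVI sensitivities a = 0.02 per degC and
#' b = 7e-4 per mm; baseline c = 0.15 (mean NDVI ~0.6); and a human
#' "restoration" trend of 1.2e-3 NDVI/yr, so the mean observed NDVI
#' trend is 2.4e-3/yr split roughly half/half between climate and human
#' drivers. Keeping the climate trends small relative to the interannual
#' noise also keeps the time index nearly orthogonal to (T, P), which is
#' the regime in which residual attribution is well posed (see the
#' methods vignette).
#'
#' @param n_years Number of annual steps (>= 4, default 21).
#' @param nrow,ncol Grid shape (default 20 x 25 = 500 pixels).
#' @param a NDVI per degC (default 0.02).
#' @param b NDVI per mm (default 7e-4).
#' @param c Baseline NDVI (default 0.15).
#' @param temp_base,precip_base Year-1 climate means (2 degC, 600 mm).
#' @param temp_trend degC/yr (default -0.01).
#' @param precip_trend mm/yr (default 2).
#' @param temp_sd,precip_sd Interannual climate noise SDs
#'   (0.5 degC, 60 mm).
#' @param human_rate Deterministic human-driven NDVI trend, NDVI/yr;
#'   scalar or a `nrow x ncol` matrix for region blocks (default 1.2e-3).
#' @param noise_sd NDVI observation-noise SD (default 0.01).
#' @param seed Integer seed fixing the full output stream (default 42).
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(n_years = 21L, nrow = 20L, ncol = 25L,
                            a = 0.02, b = 7e-4, c = 0.15,
                            temp_base = 2, precip_base = 600,
                            temp_trend = -0.01, precip_trend = 2,
                            temp_sd = 0.5, precip_sd = 60,
                            human_rate = 1.2e-3, noise_sd = 0.01,
                            seed = 42L) {
  n_years <- as.integer(n_years)
  if (n_years < 4L) stop("n_years must be >= 4")
  if (temp_sd < 0 || precip_sd < 0 || noise_sd < 0) stop("sd must be >= 0")
  if (is.matrix(human_rate)) {
    if (!all(dim(human_rate) == c(nrow, ncol))) {
      stop("human_rate matrix must match the grid shape")
    }
  } else if (length(human_rate) != 1L) {
    stop("human_rate must be a scalar or a nrow x ncol matrix")
  }
  structure(list(n_years = n_years, nrow = as.integer(nrow),
                 ncol = as.integer(ncol), a = a, b = b, c = c,
                 temp_base = temp_base, precip_base = precip_base,
                 temp_trend = temp_trend, precip_trend = precip_trend,
                 temp_sd = temp_sd, precip_sd = precip_sd,
                 human_rate = human_rate, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# Per-pixel substream seed: depends only on (seed, variable, row, col) via
# the Cantor pairing of (row, col), so enlarging the grid never reshuffles
# the noise of existing pixels. Kept below 2^31.
pixel_seed <- function(seed, var_id, row, col) {
  k <- (row + col) * (row + col + 1L) %/% 2L + col
  ((seed %% 1000003L) * 2039L + 3L * k + var_id) %% 2147483647L
}

pixel_noise_field <- function(seed, var_id, n_years, nr, nc, sd) {
  out <- array(0, c(n_years, nr, nc))
  if (sd == 0) return(out)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      set.seed(pixel_seed(seed, var_id, r, cc))
      out[, r, cc] <- stats::rnorm(n_years, sd = sd)
    }
  }
  out
}

#' Generate a synthetic climate + NDVI scenario with ground truth
#'
#' Produces aligned temperature, precipitation and NDVI cubes following
#' the generative model in [scenario_config()], plus a `scenario_truth`
#' record of the noise-free components for recovery tests. The truth
#' decomposes the noise-free observed trend of each pixel into a climate
#' component (the trend of `a*T_t + b*P_t` over the realized climate
#' series) and a human component (`human_rate`), and converts them to
#' true CC/HA shares with the same six-condition scheme used by the
#' estimator, so recovery error measures estimation error only.
#'
#' NDVI is clipped to `[0, 1]`; a warning is raised if more than 10% of
#' values are clipped (clipping distorts the linear structure). Output
#' is deterministic given the seed.
#'
#' @param config A [scenario_config()].
#' @return List with elements `temp`, `precip`, `ndvi` (aligned
#'   [annual_cube()]s), `truth` (class `scenario_truth`: matrices
#'   `climate_slope`, `human_slope`, `obs_slope`, `cc_pct`, `ha_pct`,
#'   scalars `a`, `b`, `c`), and `config`.
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  n <- config$n_years; nr <- config$nrow; nc <- config$ncol
  t_idx <- seq_len(n)

  temp_det <- config$temp_base + config$temp_trend * t_idx
  precip_det <- config$precip_base + config$precip_trend * t_idx
  hr <- if (is.matrix(config$human_rate)) config$human_rate else
    matrix(config$human_rate, nr, nc)

  TT <- array(rep(temp_det, nr * nc), c(n, nr, nc)) +
    pixel_noise_field(config$seed, 1L, n, nr, nc, config$temp_sd)
  PP <- array(rep(precip_det, nr * nc), c(n, nr, nc)) +
    pixel_noise_field(config$seed, 2L, n, nr, nc, config$precip_sd)
  eta <- pixel_noise_field(config$seed, 3L, n, nr, nc, config$noise_sd)

  human <- array(0, c(n, nr, nc))
  for (t in t_idx) human[t, , ] <- hr * t
  clim <- config$a * TT + config$b * PP + config$c
  ndvi <- clim + human + eta
  n_clip <- sum(ndvi < 0 | ndvi > 1)
  if (n_clip > 0.10 * length(ndvi)) {
    warning(sprintf("%.1f%% of NDVI values clipped to [0, 1]; ",
                    100 * n_clip / length(ndvi)),
            "linearity of the scenario is distorted")
  }
  ndvi <- pmin(pmax(ndvi, 0), 1)

  # ground truth from the realized noise-free components
  clim_mat <- matrix(clim, nrow = n)
  climate_slope <- matrix(ols_columns(clim_mat)$slope, nr, nc)
  human_slope <- hr
  obs_slope <- climate_slope + human_slope
  tc <- contribution_rates(as.vector(obs_slope), as.vector(climate_slope))
  truth <- structure(list(climate_slope = climate_slope,
                          human_slope = human_slope,
                          obs_slope = obs_slope,
                          cc_pct = matrix(tc$cc_pct, nr, nc),
                          ha_pct = matrix(tc$ha_pct, nr, nc),
                          condition = matrix(tc$condition, nr, nc),
                          a = config$a, b = config$b, c = config$c),
                     class = "scenario_truth")
  years <- seq(2000L, length.out = n)
  list(temp = annual_cube(TT, years),
       precip = annual_cube(PP, years),
       ndvi = annual_cube(ndvi, years),
       truth = truth, config = config)
}

#' Theoretical autocovariance of fractional Gaussian noise
#'
#' `gamma(k) = 0.5 * (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})` for a
#' unit-variance process.
#'
#' @param k Integer lag(s).
#' @param H Hurst exponent in (0, 1).
#' @return Numeric vector of autocovariances.
#' @export
fgn_autocov <- function(k, H) {
  0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}

# O(n^2) sequential conditional sampler via the Levinson-Durbin
# recursion; exact, used when circulant embedding is infeasible.
fgn_levinson <- function(n, H) {
  g <- fgn_autocov(0:(n - 1), H)
  x <- numeric(n)
  phi <- numeric(0)
  v <- g[1]
  x[1] <- stats::rnorm(1) * sqrt(v)
  for (t in 1:(n - 1)) {
    if (t == 1L) {
      k <- g[2] / g[1]
      phi <- k
    } else {
      k <- (g[t + 1] - sum(phi * g[t:2])) / v
      phi <- c(phi - k * rev(phi), k)
    }
    v <- v * (1 - k^2)
    mu <- sum(phi * x[t:1])
    x[t + 1] <- mu + stats::rnorm(1) * sqrt(v)
  }
  x
}

#' Simulate fractional Gaussian noise with exact covariance
#'
#' Stationary zero-mean unit-variance Gaussian series with the fGn
#' autocovariance of [fgn_autocov()]. Uses Davies-Harte circulant
#' embedding (exact covariance, O(n log n)); if the circulant eigenvalues
#' are not all non-negative the sampler falls back to an exact
#' sequential conditional method (Levinson-Durbin, O(n^2)). H = 0.5
#' reduces to i.i.d. standard Gaussians.
#'
#' @param n Series length (>= 16).
#' @param H Hurst exponent, strictly inside (0, 1).
#' @param seed Integer seed; the same seed gives an identical series.
#' @return Numeric vector of length `n`.
#' @export
generate_fgn <- function(n, H, seed) {
  if (!is.finite(H) || H <= 0 || H >= 1) stop("H must lie strictly in (0, 1)")
  n <- as.integer(n)
  if (n < 16L) stop("n must be >= 16")
  set.seed(as.integer(seed))
  m <- 2L * n
  g <- fgn_autocov(0:n, H)
  row1 <- c(g[1:n], g[n + 1], rev(g[2:n]))
  lam <- Re(stats::fft(row1))
  if (any(lam < -1e-8 * max(lam))) {
    return(fgn_levinson(n, H))
  }
  lam <- pmax(lam, 0)
  V <- complex(length.out = m)
  V[1] <- sqrt(lam[1]) * stats::rnorm(1)
  V[n + 1] <- sqrt(lam[n + 1]) * stats::rnorm(1)
  k <- 2:n
  re <- stats::rnorm(n - 1); im <- stats::rnorm(n - 1)
  V[k] <- sqrt(lam[k] / 2) * complex(real = re, imaginary = im)
  V[m - k + 2] <- Conj(V[k])
  Re(stats::fft(V))[1:n] / sqrt(m)
}
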