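# Independent oracles and fixture builders shared across the test files.

# Literal loop implementation of the R/S recipe (group means, cumulative
# deviations, range, population SD, per-group R/S, mean over groups).
# Deliberately scalar/loop-based: an independent code path from rs_curve().
rs_oracle <- function(x, rs = 2:(length(x) %/% 2)) {
  n <- length(x)
  out <- data.frame(r = integer(0), rs_bar = numeric(0))
  for (r in rs) {
    g <- n %/% r
    vals <- c()
    for (i in seq_len(g)) {
      seg <- x[((i - 1) * r + 1):((i - 1) * r + r)]
      mu <- sum(seg) / r
      X <- numeric(r)
      acc <- 0
      for (j in seq_len(r)) {
        acc <- acc + (seg[j] - mu)
        X[j] <- acc
      }
      R <- max(X) - min(X)
      S <- sqrt(sum((seg - mu)^2) / r)
      if (S > 0) vals <- c(vals, R / S)
    }
    if (length(vals) > 0) {
      out <- rbind(out, data.frame(r = r, rs_bar = mean(vals)))
    }
  }
  out
}

# least-squares oracle on the 1..n time grid via stats::lm
lm_trend_oracle <- function(y) {
  i <- seq_along(y)
  fit <- stats::lm(y ~ i)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       p = summary(fit)$coefficients[2, 4])
}

# small cube with linearly trending pixels: value = base + rate * t
make_trend_cube <- function(rates, n_years = 21, base = 0.5) {
  nr <- nrow(rates); nc <- ncol(rates)
  v <- array(NA_real_, c(n_years, nr, nc))
  for (t in seq_len(n_years)) v[t, , ] <- base + rates * t
  annual_cube(v, seq(2000, length.out = n_years))
}

# 2x2-block zone mask over an even-sized grid
make_zones <- function(nr, nc) {
  lab <- matrix(1L, nr, nc)
  lab[, (nc %/% 2 + 1):nc] <- 2L
  zone_mask(lab, c(`1` = "GTGP", `2` = "GRP"))
}
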