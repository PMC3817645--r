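# Independent oracles used to cross-check the implementation.

# Closed-form two-parameter OLS via the normal equations (independent of lm).
ols_oracle <- function(x, y) {
  n <- length(x)
  X <- cbind(1, x)
  XtX_inv <- solve(t(X) %*% X)
  beta <- unname(drop(XtX_inv %*% t(X) %*% y))
  resid <- y - drop(X %*% beta)
  sigma2 <- sum(resid^2) / (n - 2)
  se <- sqrt(diag(XtX_inv) * sigma2)
  list(intercept = beta[1], slope = beta[2],
       intercept_se = unname(se[1]), slope_se = unname(se[2]),
       r_squared = 1 - sum(resid^2) / sum((y - mean(y))^2))
}

# Forward Beer's-law absorbances at 266/284 nm from known concentrations.
forward_absorbance <- function(c_hmf, c_la,
                               eps = matrix(c(12.38, 22.7, 0.023, 0.014), 2),
                               path = 1) {
  list(a266 = path * (eps[1, 1] * c_hmf + eps[1, 2] * c_la),
       a284 = path * (eps[2, 1] * c_hmf + eps[2, 2] * c_la))
}

# Brute-force least-squares oracle: minimise ||A - E C|| over a zooming grid.
grid_solve_oracle <- function(a266, a284,
                              eps = matrix(c(12.38, 22.7, 0.023, 0.014), 2),
                              lower = c(0, 0), upper = c(0.2, 70),
                              levels = 10, pts = 41) {
  obj <- function(c1, c2) {
    (a266 - eps[1, 1] * c1 - eps[1, 2] * c2)^2 +
      (a284 - eps[2, 1] * c1 - eps[2, 2] * c2)^2
  }
  lo <- lower; hi <- upper
  best <- c(NA_real_, NA_real_)
  for (lev in seq_len(levels)) {
    g1 <- seq(lo[1], hi[1], length.out = pts)
    g2 <- seq(lo[2], hi[2], length.out = pts)
    vals <- outer(g1, g2, obj)
    idx <- arrayInd(which.min(vals), dim(vals))
    best <- c(g1[idx[1]], g2[idx[2]])
    span <- (hi - lo) / (pts - 1) * 4   # keep a few cells around the minimum
    lo <- best - span
    hi <- best + span
  }
  best
}

# Small synthetic spectrum builders used across test files.
tiny_spectrum <- function(wl = c(266, 284), ab = c(0.5, 0.8), ...) {
  uv_spectrum(data.frame(wavelength_nm = wl, absorbance = ab), ...)
}
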