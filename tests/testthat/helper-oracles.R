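# Independent oracles: hand-written closed forms kept deliberately free
# of the package's code paths (no lm(), no shared helpers).

# Weighted simple linear regression by the normal equations.
ols_oracle <- function(x, y, w = rep(1, length(x))) {
  sw <- sum(w)
  xb <- sum(w * x) / sw
  yb <- sum(w * y) / sw
  slope <- sum(w * (x - xb) * (y - yb)) / sum(w * (x - xb)^2)
  intercept <- yb - slope * xb
  resid <- y - intercept - slope * x
  r2 <- 1 - sum(w * resid^2) / sum(w * (y - yb)^2)
  list(slope = slope, intercept = intercept, r2 = r2)
}

# Textbook two-pass mean/SD/CV.
msc_oracle <- function(v, population = TRUE) {
  n <- length(v)
  m <- sum(v) / n
  ss <- sum((v - m)^2)
  s <- sqrt(ss / (if (population) n else n - 1))
  c(mean = m, sd = s, cv = s / m * 100)
}

# Brute-force terminal-slope oracle: enumerate every contiguous subset
# ending at the last candidate point, >= 3 points, negative slope;
# maximize adjusted R^2 (ties -> more points, same 1e-10 tolerance the
# contract states). Candidates must be prepared by the caller.
lambda_z_oracle <- function(t, logc) {
  n <- length(t)
  best <- NULL
  for (s in seq_len(n - 2)) {
    f <- ols_oracle(t[s:n], logc[s:n])
    if (f$slope >= 0) next
    m <- n - s + 1
    adj <- 1 - (1 - f$r2) * (m - 1) / (m - 2)
    if (is.null(best) || adj > best$adj + 1e-10 ||
        (abs(adj - best$adj) <= 1e-10 && m > best$n)) {
      best <- list(lambda = -f$slope, n = m, adj = adj)
    }
  }
  best
}

# Plain trapezoid on explicit points.
trapz_oracle <- function(t, y) {
  n <- length(t)
  sum(diff(t) * (y[-n] + y[-1]) / 2)
}

# Dense-grid numeric integral (trapezoid at fine resolution) used as the
# oracle for peak areas.
dense_integral <- function(f, a, b, n = 200000) {
  x <- seq(a, b, length.out = n)
  y <- f(x)
  sum((y[-1] + y[-n]) / 2) * (b - a) / (n - 1)
}

# Quick fixture: flat-baseline trace with a triangular peak of exact
# height `h` at `center` and an alternating +/- d "noise" block over
# [0, noise_end]; everything else zero. Grid step 0.01 min.
triangle_trace <- function(h, d = 1, center = 5, halfwidth = 0.5,
                           noise_end = 1.99, run_length = 10) {
  t <- seq(0, run_length, by = 0.01)
  y <- pmax(0, h * (1 - abs(t - center) / halfwidth))
  nz <- t <= noise_end
  y[nz] <- y[nz] + d * rep_len(c(1, -1), sum(nz))
  chromatogram_trace(t, y, channel = c(425, 247))
}
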