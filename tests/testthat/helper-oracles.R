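# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths.

# Exhaustive optimal segmentation of y into k+1 constant plateaus by
# dynamic programming over all change-point placements.
dp_segment_oracle <- function(y, k) {
  n <- length(y)
  cs <- c(0, cumsum(y))
  css <- c(0, cumsum(y^2))
  sse <- function(a, b) css[b + 1] - css[a] - (cs[b + 1] - cs[a])^2 / (b - a + 1)
  D <- matrix(Inf, k + 1, n)
  B <- matrix(0L, k + 1, n)
  for (i in 1:n) D[1, i] <- sse(1, i)
  if (k > 0) {
    for (j in 2:(k + 1)) for (i in j:n) {
      prev <- (j - 1):(i - 1)
      v <- D[j - 1, prev] + vapply(prev + 1, function(a) sse(a, i), numeric(1))
      m <- which.min(v)
      D[j, i] <- v[m]
      B[j, i] <- prev[m]
    }
  }
  bounds <- integer(k)
  i <- n
  if (k > 0) for (j in (k + 1):2) {
    bounds[j - 1] <- B[j, i]
    i <- B[j, i]
  }
  list(bounds = bounds, sse = D[k + 1, n])
}

# Analytic inverse-CDF rupture time for a linear force ramp F(t) = f0 + r t
# under the Bell-Evans hazard k(F) = k0 exp(F xd / kbt).
ramp_rupture_oracle <- function(u, k0, xd, kbt, rate, f0 = 0) {
  a <- xd / kbt
  # cumulative hazard: k0/(r a) (exp(a (f0 + r t)) - exp(a f0)) = -log(u)
  log((-log(u)) * rate * a / k0 + exp(a * f0)) / (a * rate) - f0 / rate
}

# Partial correlation by regressing out the controls and correlating the
# residuals.
residual_pcor_oracle <- function(x, y, z) {
  zm <- as.matrix(as.data.frame(z))
  rx <- stats::resid(stats::lm(x ~ zm))
  ry <- stats::resid(stats::lm(y ~ zm))
  stats::cor(rx, ry)
}

# Brute-force inversion of the ssDNA WLC on a fine grid.
ss_inverse_grid_oracle <- function(force, params = ss_wlc_params(),
                                   step = 1e-5) {
  r <- seq(0, 1 - step, by = step)
  f <- params$kbt / params$persistence_length *
    (0.25 * (1 - r)^-2 + r - 0.25)
  r[which.min(abs(f - force))]
}

make_staircase <- function(levels, durations, noise_sd = 0) {
  y <- rep(levels, durations)
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  y
}
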