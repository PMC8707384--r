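# Independent oracles used across the suite. These deliberately avoid the
# package's own integration/grouping code paths.

# Dense-grid cumulative-sum critical wavelength: evaluate the absorbance
# function (or linearly interpolate a sampled spectrum) on a 0.01 nm grid
# and locate the 90% crossing by cumulative sum.
oracle_lambda_c <- function(afun, step = 0.01, fraction = 0.9) {
  grid <- seq(290, 400, by = step)
  a <- pmax(afun(grid), 0)
  seg <- step * (head(a, -1) + tail(a, -1)) / 2
  cum <- c(0, cumsum(seg))
  grid[which(cum >= fraction * cum[length(cum)])[1]]
}

# Closed-form Gaussian band integral over [lo, hi].
gauss_band_integral <- function(center, sigma, peak, lo, hi) {
  peak * sigma * sqrt(2 * pi) *
    (pnorm(hi, center, sigma) - pnorm(lo, center, sigma))
}

# Absorbance function for a band model data.frame.
band_fun <- function(bands, baseline = 0) {
  function(l) {
    a <- rep(baseline, length(l))
    for (k in seq_len(nrow(bands)))
      a <- a + bands$peak[k] * exp(-(l - bands$center[k])^2 / (2 * bands$width[k]^2))
    a
  }
}

# Random smooth band model (1-3 Gaussian bands in the UV window).
random_bands <- function() {
  n <- sample(1:3, 1)
  data.frame(center = runif(n, 295, 395),
             width = runif(n, 6, 25),
             peak = runif(n, 0.2, 1.5))
}

flat_spectrum <- function(a = 1, step = 1) {
  grid <- seq(290, 400, by = step)
  absorbance_spectrum(grid, rep(a, length(grid)))
}
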