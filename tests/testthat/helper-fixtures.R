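# Shared fixtures: the canonical 56-offset schedule and a few tissue-like
# parameter sets used across test files.

sched56 <- build_offset_table()

gm_params <- two_pool_params(0.64, 1000, 38)
wm_params <- two_pool_params(0.59, 760, 30)
csf_params <- two_pool_params(0.68, 2100, 95)

# Rician corruption of a zspectrum (magnitude of complex Gaussian noise)
add_rician <- function(zspec, sigma) {
  n <- length(zspec$z)
  zspec$z <- sqrt((zspec$z + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  zspec
}

# Mean of a Rician distribution with location nu and scale sigma
# (Laguerre half polynomial via Bessel functions); independent oracle for
# the noise model.
rician_mean <- function(nu, sigma) {
  x <- -nu^2 / (2 * sigma^2)
  # exponentially scaled Bessel terms keep the large-SNR limit finite
  l_half <- (1 - x) * besselI(-x / 2, 0, expon.scaled = TRUE) -
    x * besselI(-x / 2, 1, expon.scaled = TRUE)
  sigma * sqrt(pi / 2) * l_half
}
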