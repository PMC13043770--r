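# Independent oracles and shared fixtures for the test suite.

# Direct-summation phasor oracle: a literal loop over channels, kept
# independent of the vectorized implementation it checks.
phasor_oracle <- function(intensities, harmonic = 1L) {
  nc <- length(intensities)
  tot <- 0
  g <- 0
  s <- 0
  for (c0 in 0:(nc - 1L)) {
    I <- intensities[c0 + 1L]
    tot <- tot + I
    g <- g + I * cos(2 * pi * harmonic * c0 / nc)
    s <- s + I * sin(2 * pi * harmonic * c0 / nc)
  }
  c(G = g / tot, S = s / tot)
}

# Brute-force mode oracle on a 0.001 nm grid.
brute_mode <- function(mu, sigma, gamma, halfwidth = 4) {
  grid <- seq(mu - halfwidth * sigma, mu + halfwidth * sigma, by = 0.001)
  grid[which.max(skew_gaussian(grid, 1, mu, sigma, gamma))]
}

# Numeric force-balance oracle for the wetting tension triangle: tensions
# pull along the three interfaces meeting at the contact line; going around
# the line the directions are separated by the apparent angles. Solving the
# 2x2 linear balance for the two membrane tensions (condensate interfacial
# tension set to 1) gives cos(theta_in) = Sigma_ic - Sigma_ie.
force_balance_oracle <- function(theta_i, theta_e, theta_c) {
  te <- unname(theta_e) * pi / 180
  tc <- unname(theta_c) * pi / 180
  A <- rbind(c(cos(te), cos(tc)),
             c(sin(te), -sin(tc)))
  x <- solve(A, c(-1, 0))
  list(sigma_ie = x[1], sigma_ic = x[2], cos_theta_in = x[2] - x[1])
}

# Rejection-sample valid apparent-angle triples (closure + arccos domain).
random_valid_triples <- function(n, seed = 42L) {
  set.seed(seed)
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    ti <- runif(1, 15, 170)
    te <- runif(1, 15, 330)
    tc <- 360 - ti - te
    if (tc <= 5 || tc >= 355) next
    if (abs(sin(te * pi / 180) - sin(tc * pi / 180)) >
        sin(ti * pi / 180) * (1 - 1e-9)) next
    out <- rbind(out, c(ti, te, tc))
  }
  colnames(out) <- c("theta_i", "theta_e", "theta_c")
  out
}

# Shared fixtures (built once per test file load; cheap).
test_axis <- function() spectral_axis(416, 728, 32)
test_fm <- local({
  fm <- NULL
  function() {
    if (is.null(fm)) fm <<- forward_model()
    fm
  }
})
test_cal <- function() test_fm()$calibration

# Random nonnegative spectra on the standard axis.
random_spectra <- function(n, nc = 32L, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) stats::runif(nc, 0, 100))
}
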