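# Canonical two-taxon reference parameters used throughout the tests.
canonical_refs <- function() {
  list(ref_dist("C. obtusa", 408, 145),
       ref_dist("C. japonica", 662, 257))
}

# Closed-form mean and sd of a Gaussian truncated to [lo, hi]
# (oracle for the rejection sampler and moment fits).
truncated_moments <- function(mu, sigma, lo = 0, hi = 4500) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  Z <- pnorm(b) - pnorm(a)
  m <- mu + sigma * (dnorm(a) - dnorm(b)) / Z
  v <- sigma^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                    ((dnorm(a) - dnorm(b)) / Z)^2)
  list(mean = m, sd = sqrt(v))
}

# Brute-force quadrature oracle for truncated interval mass.
quadrature_mass <- function(mu, sigma, a, b, lo = 0, hi = 4500) {
  f <- function(x) exp(-(x - mu)^2 / (2 * sigma^2)) / sqrt(2 * pi * sigma^2)
  stats::integrate(f, a, b, rel.tol = 1e-12)$value /
    stats::integrate(f, lo, hi, rel.tol = 1e-12)$value
}

# A throwaway CSV fixture on disk; returns the path.
write_fixture_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
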