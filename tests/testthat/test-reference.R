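test_that("Gaussian density matches the closed form and its symmetries", {
  d <- ref_dist("C. obtusa", 408, 145)
  expect_equal(density(d, 408), 1 / sqrt(2 * pi * 145^2))
  expect_equal(density(d, 408), 2.7515e-3, tolerance = 1e-4)
  for (off in c(10, 50, 137.5)) # symmetry about mu
    expect_equal(density(d, 408 + off), density(d, 408 - off))
  expect_gt(density(d, 408), density(d, 600)) # unimodality
  expect_equal(stats::integrate(function(x) density(d, x), -Inf, Inf,
                                rel.tol = 1e-12)$value, 1, tolerance = 1e-9)
})

test_that("truncated interval masses agree with a quadrature oracle", {
  refs <- canonical_refs()
  cases <- expand.grid(k = 1:2, a = c(500, 600), w = c(50, 100))
  for (i in seq_len(nrow(cases))) {
    r <- refs[[cases$k[i]]]
    a <- cases$a[i]; b <- a + cases$w[i]
    expect_equal(truncated_mass(r, a, b),
                 quadrature_mass(r$mu, r$sigma, a, b), tolerance = 1e-10)
  }
  # the widest-interval coefficients of the default unmixing system
  expect_equal(truncated_mass(refs[[1]], 500, 600), 0.1706, tolerance = 2e-4)
  expect_equal(truncated_mass(refs[[1]], 0, 4500), 1)
  expect_equal(truncated_mass(refs[[2]], 0, 4500), 1)
})

test_that("truncated mass is additive over adjacent intervals and monotone", {
  d <- ref_dist("C. japonica", 662, 257)
  set.seed(11)
  for (i in 1:25) {
    pts <- sort(runif(3, 0, 4500))
    expect_equal(truncated_mass(d, pts[1], pts[2]) +
                   truncated_mass(d, pts[2], pts[3]),
                 truncated_mass(d, pts[1], pts[3]), tolerance = 1e-12)
  }
  bs <- seq(500, 4500, by = 250)
  expect_true(all(diff(truncated_mass(d, 400, bs)) >= 0)) # nondecreasing in b
  expect_true(all(diff(truncated_mass(d, 400, seq(500, 2000, 100))) > 0))
  expect_error(truncated_mass(d, 600, 600), "below")
  expect_error(truncated_mass(d, -10, 600), "support")
})

test_that("moment fits recover the truncated-Gaussian moments", {
  d <- ref_dist("C. japonica", 662, 257)
  tm <- truncated_moments(662, 257)
  hits <- 0L
  n <- 1000
  for (s in 1:40) {
    x <- sample_taxon_forward(d, n, seed = 1000 + s)
    fit <- fit_gaussian(x, "C. japonica")
    ok_mu <- abs(fit$mu - tm$mean) <= 3 * tm$sd / sqrt(n)
    ok_sd <- abs(fit$sigma - tm$sd) <= 3 * tm$sd / sqrt(2 * n)
    hits <- hits + (ok_mu && ok_sd)
  }
  expect_gte(hits, 38L) # >= 95% of seeds
})

test_that("histogram least-squares fits agree with moments on clean data", {
  d <- ref_dist("C. obtusa", 408, 145)
  x <- sample_taxon_forward(d, 50000, seed = 4)
  fit <- fit_gaussian(x, "C. obtusa", method = "histogram_ls", bin_width = 10)
  expect_equal(fit$mu, truncated_moments(408, 145)$mean, tolerance = 0.01)
  expect_equal(fit$sigma, 145, tolerance = 0.05)
  # mode of any fitted density is 1/sqrt(2*pi*sigma^2)
  expect_equal(density(fit, fit$mu), 1 / sqrt(2 * pi * fit$sigma^2))
})

test_that("degenerate fitting inputs raise informative errors", {
  expect_error(fit_gaussian(c(1, 2, 3), "x"), "at least 10")
  expect_error(fit_gaussian(rep(500, 20), "x"), "zero variance")
  expect_error(fit_gaussian(c(rep(100, 19), 9000), "x"), "\\[0, 4500\\]")
  expect_error(ref_dist("x", 500, -1), "positive")
  expect_error(ref_dist("x", 500, 100, 600, 400), "below")
})

test_that("F statistic is the larger-over-smaller variance ratio", {
  set.seed(21)
  x <- rnorm(200); x <- (x - mean(x)) / sd(x) * 145
  y <- rnorm(300); y <- (y - mean(y)) / sd(y) * 257
  ft <- f_test(x, y)
  expect_equal(ft$f_statistic, 257^2 / 145^2, tolerance = 1e-12)
  expect_equal(ft$df, c(299L, 199L)) # larger-variance sample first
  expect_gte(f_test(y, x)$f_statistic, 1) # order-independent convention
  expect_equal(f_test(x, x)$f_statistic, 1)
  # cross-check p-value against stats::var.test (one-sided, greater)
  vt <- stats::var.test(y, x, alternative = "greater")
  expect_equal(ft$f_p, vt$p.value, tolerance = 1e-12)
  expect_error(f_test(rep(1, 5), x), "zero variance")
})

test_that("F boundary value shrinks to 1 with equal sample sizes", {
  crit <- vapply(c(1e2, 1e4, 1e6), function(n)
    f_test(rnorm(n), rnorm(n))$f_critical, 0)
  expect_true(all(diff(crit) < 0))
  expect_equal(crit[3], 1, tolerance = 5e-3)
})

test_that("t statistic follows the pooled closed form and mean(x)-mean(y) sign", {
  set.seed(31)
  x <- rnorm(100); x <- (x - mean(x)) / sd(x)        # mean 0, sd 1
  y <- rnorm(100); y <- (y - mean(y)) / sd(y) + 1    # mean 1, sd 1
  tt <- t_test(x, y, variant = "pooled")
  expect_equal(tt$t_statistic, -1 / sqrt(2 / 100), tolerance = 1e-12)
  expect_equal(tt$df, 198)
  expect_equal(t_test(x, x)$t_statistic, 0)
  # cross-check against stats::t.test
  st <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(tt$t_statistic, unname(st$statistic), tolerance = 1e-12)
  expect_equal(tt$t_p_two_sided, st$p.value, tolerance = 1e-12)
  sw <- stats::t.test(x, y)
  tw <- t_test(x, y, variant = "welch")
  expect_equal(tw$t_statistic, unname(sw$statistic), tolerance = 1e-12)
  expect_equal(tw$df, unname(sw$parameter), tolerance = 1e-9)
})

test_that("the canonical taxa are distinguishable from sampled signals", {
  refs <- canonical_refs()
  x <- sample_taxon_forward(refs[[1]], 1500, seed = 5)
  y <- sample_taxon_forward(refs[[2]], 1500, seed = 6)
  rep <- distinguishability(x, y)
  expect_true(rep$distinguishable)
  expect_gt(rep$f$f_statistic, 1)
  expect_lt(rep$t$t_statistic, 0) # obtusa scatters lower than japonica
  expect_lt(rep$f$f_p, 0.05)
  expect_lt(rep$t$t_p_two_sided, 0.05)
})
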