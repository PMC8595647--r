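test_that("interval enumeration matches a brute-force pair count", {
  sch <- interval_scheme()
  expect_equal(nrow(sch$pairs_first), 55L)
  expect_equal(nrow(sch$pairs_second), 55L)
  expect_equal(sch$n_combinations, 3025L)
  expect_equal(interval_scheme(step = 20)$n_combinations, 225L) # C(6,2)^2
  one <- interval_scheme(c(500, 510), c(600, 610), 10)
  expect_equal(one$n_combinations, 1L)
  expect_equal(unname(one$pairs_first[1, ]), c(500, 510))

  # brute-force enumeration oracle on a small grid
  brute <- function(lo, hi, step) {
    pts <- seq(lo, hi, step); out <- NULL
    for (i in seq_along(pts)) for (j in seq_along(pts))
      if (pts[i] < pts[j]) out <- rbind(out, c(pts[i], pts[j]))
    out
  }
  sch2 <- interval_scheme(c(0, 40), c(100, 120), 10)
  expect_equal(unname(sch2$pairs_first), brute(0, 40, 10))
  expect_equal(unname(sch2$pairs_second), brute(100, 120, 10))
  expect_equal(sch2$n_combinations, choose(5, 2) * choose(3, 2))

  expect_error(interval_scheme(step = 7), "divide")
  expect_error(interval_scheme(c(600, 500)), "lo < hi")
})

test_that("interval counting is half-open on the right", {
  expect_equal(count_in_interval(c(505, 510, 599), 500, 510), 1L)
  expect_equal(count_in_interval(numeric(0), 500, 510), 0L)
  set.seed(8)
  v <- runif(1000, 500, 600) # all below 600
  expect_equal(count_in_interval(v, 500, 600), 1000L)
  expect_error(count_in_interval(v, 600, 500), "below")
})

test_that("solving an exactly synthesized system recovers the counts", {
  refs <- canonical_refs()
  truth <- c(1000, 500)
  fab <- c(truncated_mass(refs[[1]], 500, 600),
           truncated_mass(refs[[2]], 500, 600))
  fcd <- c(truncated_mass(refs[[1]], 600, 700),
           truncated_mass(refs[[2]], 600, 700))
  sol <- solve_pair(refs[[1]], refs[[2]], c(500, 600), c(600, 700),
                    n_ab = sum(fab * truth), n_cd = sum(fcd * truth))
  expect_equal(sol$status, "accepted")
  expect_equal(sol$n_alpha, 1000, tolerance = 1e-6)
  expect_equal(sol$n_beta, 500, tolerance = 1e-6)
})

test_that("construct-then-invert holds across random combinations and counts", {
  refs <- canonical_refs()
  sch <- interval_scheme()
  set.seed(13)
  for (i in 1:50) {
    p1 <- sch$pairs_first[sample(55, 1), ]
    p2 <- sch$pairs_second[sample(55, 1), ]
    truth <- runif(2, 0, 3000)
    nab <- truncated_mass(refs[[1]], p1[1], p1[2]) * truth[1] +
      truncated_mass(refs[[2]], p1[1], p1[2]) * truth[2]
    ncd <- truncated_mass(refs[[1]], p2[1], p2[2]) * truth[1] +
      truncated_mass(refs[[2]], p2[1], p2[2]) * truth[2]
    sol <- solve_pair(refs[[1]], refs[[2]], p1, p2, nab, ncd)
    expect_equal(sol$status, "accepted")
    expect_equal(c(sol$n_alpha, sol$n_beta), truth, tolerance = 1e-6)
  }
})

test_that("zero counts, negative solutions and singular systems are classified", {
  refs <- canonical_refs()
  z <- solve_pair(refs[[1]], refs[[2]], c(500, 600), c(600, 700), 0, 0)
  expect_equal(z$status, "accepted")
  expect_equal(c(z$n_alpha, z$n_beta), c(0, 0))
  # all signal in the high range forces a negative alpha component
  n <- solve_pair(refs[[1]], refs[[2]], c(500, 600), c(600, 700), 0, 500)
  expect_equal(n$status, "negative")
  expect_lt(n$n_alpha, 0)
  # identical distributions are structurally singular
  s <- solve_pair(refs[[1]], refs[[1]], c(500, 600), c(600, 700), 10, 10)
  expect_equal(s$status, "singular")
})

test_that("solutions scale linearly with the interval counts", {
  refs <- canonical_refs()
  base <- solve_pair(refs[[1]], refs[[2]], c(520, 580), c(620, 690), 120, 90)
  for (m in c(2L, 5L, 11L)) {
    sc <- solve_pair(refs[[1]], refs[[2]], c(520, 580), c(620, 690),
                     120L * m, 90L * m)
    expect_equal(sc$n_alpha, m * base$n_alpha, tolerance = 1e-12)
    expect_equal(sc$n_beta, m * base$n_beta, tolerance = 1e-12)
  }
})

test_that("an empty signal set yields a unanimous zero estimate", {
  refs <- canonical_refs()
  fit <- ame(numeric(0), refs)
  expect_equal(unname(coef(fit)), c(0, 0))
  expect_equal(fit$n_outputs, 3025L)
  expect_equal(unname(fit$mode_support), c(3025L, 3025L))
  expect_equal(fit$n_total, 3025L)
})

test_that("the estimate is a pure function of the multiset of forward values", {
  refs <- canonical_refs()
  mx <- make_mixture(300, 400, refs, seed = 17)
  v <- mx$log$forward
  f1 <- ame(v, refs)
  f2 <- ame(rev(v), refs)
  set.seed(99); f3 <- ame(sample(v), refs)
  expect_identical(coef(f1), coef(f2))
  expect_identical(coef(f1), coef(f3))
  expect_identical(f1$candidates, f3$candidates)
  expect_identical(f1$mode_support, f3$mode_support)
})

test_that("candidate bookkeeping is consistent", {
  refs <- canonical_refs()
  mx <- make_mixture(562, 647, refs, seed = 1)
  fit <- ame(mx$log$forward, refs)
  expect_equal(fit$n_outputs + fit$n_negative + fit$n_singular, fit$n_total)
  expect_equal(sum(fit$candidates$status == "accepted"), fit$n_outputs)
  expect_true(all(fit$mode_support <= fit$n_outputs))
  expect_true(all(coef(fit) >= 0))
  acc <- fit$candidates[fit$candidates$status == "accepted", ]
  expect_true(all(acc$n_alpha >= 0 & acc$n_beta >= 0))
})

test_that("modal values break ties towards the smallest candidate", {
  m <- amepollen:::mode_smallest(c(5, 5, 9, 9, 2))
  expect_equal(m$value, 5)
  expect_true(m$tied)
  u <- amepollen:::mode_smallest(c(3, 3, 3, 7))
  expect_equal(u$value, 3)
  expect_false(u$tied)
})

test_that("confidence coefficients follow C*P/N", {
  expect_equal(confidence_coefficient(0, 100, 3025), 0)
  expect_equal(confidence_coefficient(2.0, 3025, 3025), 2.0)
  expect_equal(confidence_coefficient(23.7, 255, 3025), 23.7 * 255 / 3025)
  expect_equal(confidence_coefficient(23.7, 255, 3025), 1.9979,
               tolerance = 1e-4)
  expect_error(confidence_coefficient(1, 1, 0), "positive")
  expect_error(confidence_coefficient(-1, 1, 10), "non-negative")
})

test_that("a day is invalid only when both coefficients fall below threshold", {
  expect_false(validity(0.67, 0.89))
  expect_true(validity(2.07, 1.43))
  expect_false(validity(1.49, 1.22))
  expect_true(validity(1.0, 5.0))
  expect_true(validity(2.0, 0.0))   # at the threshold counts as confident
  expect_equal(validity(c(0.67, 2.07), c(0.89, 1.43)), c(FALSE, TRUE))
})
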