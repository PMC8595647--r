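#' Per-taxon Gaussian reference distribution
#'
#' A reference distribution describes the forward light-scattering intensity
#' of one pollen taxon as a Gaussian with location `mu` and scale `sigma`
#' (both in millivolts), restricted to the instrument's measurable voltage
#' range `[support_lo, support_hi]`. The truncated probability masses of
#' these distributions over voltage intervals form the coefficients of the
#' unmixing system solved by [ame()].
#'
#' @param taxon Character scalar naming the taxon.
#' @param mu Gaussian location, millivolts.
#' @param sigma Gaussian scale, millivolts; must be strictly positive.
#' @param support_lo,support_hi Instrument voltage range, millivolts.
#'   Defaults 0 and 4500 (the full output range of KH-3000 class counters).
#'
#' @return An object of class `ref_dist`.
#' @examples
#' hinoki <- ref_dist("C. obtusa", mu = 408, sigma = 145)
#' sugi   <- ref_dist("C. japonica", mu = 662, sigma = 257)
#' truncated_mass(hinoki, 500, 600)
#' @seealso [fit_gaussian()], [truncated_mass()], [ame()]
#' @export
ref_dist <- function(taxon, mu, sigma, support_lo = 0, support_hi = 4500) {
  stopifnot(is.character(taxon), length(taxon) == 1L, nzchar(taxon))
  mu <- as.numeric(mu); sigma <- as.numeric(sigma)
  support_lo <- as.numeric(support_lo); support_hi <- as.numeric(support_hi)
  if (!is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be strictly positive, got ", sigma)
  if (!is.finite(mu)) stop("'mu' must be finite")
  if (support_lo >= support_hi)
    stop("'support_lo' must be below 'support_hi'")
  mass <- stats::pnorm(support_hi, mu, sigma) - stats::pnorm(support_lo, mu, sigma)
  if (mass <= 0)
    stop("distribution has no mass on [", support_lo, ", ", support_hi, "]")
  structure(
    list(taxon = taxon, mu = mu, sigma = sigma,
         support_lo = support_lo, support_hi = support_hi),
    class = "ref_dist")
}

#' @export
print.ref_dist <- function(x, ...) {
  cat(sprintf("Reference distribution: %s\n", x$taxon))
  cat(sprintf("  Gaussian (mu, sigma) = (%g, %g) mV on [%g, %g] mV\n",
              x$mu, x$sigma, x$support_lo, x$support_hi))
  invisible(x)
}

#' Gaussian density of a reference distribution
#'
#' Evaluates the (untruncated) Gaussian probability density
#' \eqn{P(x) = (2\pi\sigma^2)^{-1/2} \exp\{-(x-\mu)^2 / 2\sigma^2\}}
#' of a reference distribution at the given voltages.
#'
#' @param x A [ref_dist()] object.
#' @param mv Voltages (millivolts) at which to evaluate the density.
#' @param ... Unused.
#' @return Densities (per millivolt) at `mv`.
#' @examples
#' density(ref_dist("C. obtusa", 408, 145), 408)  # 1 / sqrt(2*pi*145^2)
#' @export
density.ref_dist <- function(x, mv, ...) {
  stats::dnorm(as.numeric(mv), mean = x$mu, sd = x$sigma)
}

#' Truncated probability mass of a reference distribution on an interval
#'
#' Fraction of the reference distribution's mass (after renormalising to its
#' support) falling in the voltage interval `[a, b]`:
#' \deqn{\int_a^b P(x)\,dx \; / \; \int_{lo}^{hi} P(x)\,dx.}
#' These masses are the coefficients of the unmixing system. Computed from
#' the Gaussian cumulative distribution function, not numeric quadrature.
#'
#' @param dist A [ref_dist()] object.
#' @param a,b Interval endpoints, millivolts, with
#'   `support_lo <= a < b <= support_hi`. Vectorised over `a` and `b`.
#' @return Mass fractions in `[0, 1]`.
#' @examples
#' truncated_mass(ref_dist("C. obtusa", 408, 145), 500, 600)  # ~0.1706
#' truncated_mass(ref_dist("C. obtusa", 408, 145), 0, 4500)   # 1
#' @export
truncated_mass <- function(dist, a, b) {
  stopifnot(inherits(dist, "ref_dist"))
  a <- as.numeric(a); b <- as.numeric(b)
  if (any(a >= b)) stop("'a' must be strictly below 'b'")
  if (any(a < dist$support_lo) || any(b > dist$support_hi))
    stop("interval outside the distribution support [",
         dist$support_lo, ", ", dist$support_hi, "]")
  denom <- stats::pnorm(dist$support_hi, dist$mu, dist$sigma) -
    stats::pnorm(dist$support_lo, dist$mu, dist$sigma)
  (stats::pnorm(b, dist$mu, dist$sigma) -
     stats::pnorm(a, dist$mu, dist$sigma)) / denom
}

#' Fit a Gaussian reference distribution to forward-scattering samples
#'
#' Builds the per-taxon reference distribution from raw forward-scattering
#' intensities. `method = "moments"` takes the sample mean and standard
#' deviation. `method = "histogram_ls"` bins the sample into `bin_width`-mV
#' bins and least-squares fits a Gaussian with a free amplitude to the bin
#' counts (via [stats::nls()]), returning the fitted location and scale;
#' this mirrors curve-fitting a Gaussian to the observed signal histogram.
#'
#' @param intensities Numeric forward-scattering intensities, millivolts,
#'   all within `[support_lo, support_hi]`; at least 10 finite values.
#' @param taxon Taxon name for the resulting distribution.
#' @param method Fitting method, `"moments"` (default) or `"histogram_ls"`.
#' @param bin_width Histogram bin width in mV for `"histogram_ls"`;
#'   default 10 mV, the granularity of the unmixing interval grid.
#' @param support_lo,support_hi Support bounds passed to [ref_dist()].
#' @return A [ref_dist()] object.
#' @examples
#' x <- sample_taxon_forward(ref_dist("C. japonica", 662, 257), 5000, seed = 1)
#' fit_gaussian(x, "C. japonica")
#' @export
fit_gaussian <- function(intensities, taxon,
                         method = c("moments", "histogram_ls"),
                         bin_width = 10, support_lo = 0, support_hi = 4500) {
  method <- match.arg(method)
  x <- as.numeric(intensities)
  x <- x[is.finite(x)]
  if (length(x) < 10L)
    stop("need at least 10 finite intensity values, got ", length(x))
  if (any(x < support_lo) || any(x > support_hi))
    stop("intensities outside [", support_lo, ", ", support_hi, "] mV")
  if (stats::sd(x) == 0)
    stop("degenerate sample: zero variance")
  if (method == "moments") {
    return(ref_dist(taxon, mean(x), stats::sd(x), support_lo, support_hi))
  }
  breaks <- seq(floor(min(x) / bin_width) * bin_width,
                ceiling(max(x) / bin_width) * bin_width, by = bin_width)
  if (length(breaks) < 4L)
    stop("histogram has too few bins for a least-squares fit; ",
         "reduce 'bin_width' or use method = \"moments\"")
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  df <- data.frame(mid = h$mids, count = h$counts)
  start <- list(A = max(h$counts) * stats::sd(x) * sqrt(2 * pi),
                m = mean(x), s = stats::sd(x))
  fit <- tryCatch(
    stats::nls(count ~ A * exp(-(mid - m)^2 / (2 * s^2)) / sqrt(2 * pi * s^2),
               data = df, start = start, algorithm = "port",
               lower = c(A = 0, m = support_lo, s = 1e-6)),
    error = function(e)
      stop("histogram least-squares fit did not converge (",
           conditionMessage(e), "); try method = \"moments\"", call. = FALSE))
  est <- stats::coef(fit)
  ref_dist(taxon, unname(est["m"]), abs(unname(est["s"])),
           support_lo, support_hi)
}

#' Two-sample F test of equal scattering variance
#'
#' Tests whether the forward-scattering variances of two taxa differ. The
#' statistic is the larger sample variance over the smaller, with degrees of
#' freedom ordered to match, so `f_statistic >= 1`; the boundary (critical)
#' value is the upper one-sided F quantile at `alpha`.
#'
#' @param sample_x,sample_y Numeric samples, each of size >= 2 with
#'   positive variance.
#' @param alpha Significance level, default 0.05.
#' @return A list with `f_statistic`, `f_critical`, `f_p` (upper-tail),
#'   `df`, `alpha` and a `significant` flag.
#' @seealso [t_test()], [distinguishability()]
#' @export
f_test <- function(sample_x, sample_y, alpha = 0.05) {
  x <- as.numeric(sample_x); y <- as.numeric(sample_y)
  if (length(x) < 2L || length(y) < 2L) stop("both samples need size >= 2")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 || vy == 0) stop("degenerate sample: zero variance")
  if (vx >= vy) {
    f <- vx / vy; df <- c(length(x) - 1L, length(y) - 1L)
  } else {
    f <- vy / vx; df <- c(length(y) - 1L, length(x) - 1L)
  }
  list(f_statistic = f,
       f_critical = stats::qf(1 - alpha, df[1], df[2]),
       f_p = stats::pf(f, df[1], df[2], lower.tail = FALSE),
       df = df, alpha = alpha,
       significant = f > stats::qf(1 - alpha, df[1], df[2]))
}

#' Two-sample t test of equal mean scattering intensity
#'
#' Tests whether the mean forward-scattering intensities of two taxa differ.
#' The statistic follows the `mean(x) - mean(y)` sign convention. The
#' boundary (critical) value reported is the upper one-sided t quantile at
#' `alpha`; both one-sided and two-sided p values are returned.
#'
#' @param sample_x,sample_y Numeric samples, each of size >= 2.
#' @param alpha Significance level, default 0.05.
#' @param variant `"pooled"` (Student, equal variances; default) or
#'   `"welch"`.
#' @return A list with `t_statistic`, `t_critical`, `t_p_one_sided`,
#'   `t_p_two_sided`, `df`, `alpha`, `variant` and a `significant` flag
#'   (two-sided at `alpha`).
#' @seealso [f_test()], [distinguishability()]
#' @export
t_test <- function(sample_x, sample_y, alpha = 0.05,
                   variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  x <- as.numeric(sample_x); y <- as.numeric(sample_y)
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("both samples need size >= 2")
  vx <- stats::var(x); vy <- stats::var(y)
  if (variant == "pooled") {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    if (sp2 == 0) stop("degenerate samples: zero pooled variance")
    tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se2 <- vx / nx + vy / ny
    if (se2 == 0) stop("degenerate samples: zero variance")
    tt <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  p1 <- stats::pt(abs(tt), df, lower.tail = FALSE)
  list(t_statistic = tt,
       t_critical = stats::qt(1 - alpha, df),
       t_p_one_sided = p1, t_p_two_sided = 2 * p1,
       df = df, alpha = alpha, variant = variant,
       significant = 2 * p1 < alpha)
}

#' Are two taxa's scattering distributions statistically distinguishable?
#'
#' Runs [f_test()] and [t_test()] on the raw forward-scattering samples of
#' two taxa. The unmixing system is only meaningful when the two reference
#' distributions differ; two taxa are reported distinguishable when either
#' the variances or the means differ significantly.
#'
#' @inheritParams t_test
#' @return An object of class `distinguishability`: the two test results
#'   plus a `distinguishable` flag.
#' @export
distinguishability <- function(sample_x, sample_y, alpha = 0.05,
                               variant = c("pooled", "welch")) {
  ft <- f_test(sample_x, sample_y, alpha)
  tt <- t_test(sample_x, sample_y, alpha, variant)
  structure(list(f = ft, t = tt, alpha = alpha,
                 distinguishable = ft$significant || tt$significant),
            class = "distinguishability")
}

#' @export
print.distinguishability <- function(x, ...) {
  cat("Two-sample distinguishability of forward-scattering distributions\n")
  cat(sprintf("  F test : F = %.4g, boundary = %.4g (alpha = %g, df = %d, %d), p = %.3g\n",
              x$f$f_statistic, x$f$f_critical, x$alpha,
              x$f$df[1], x$f$df[2], x$f$f_p))
  cat(sprintf("  t test : t = %.4g, boundary = %.4g (%s, df = %.4g), two-sided p = %.3g\n",
              x$t$t_statistic, x$t$t_critical, x$t$variant, x$t$df,
              x$t$t_p_two_sided))
  cat(sprintf("  Distinguishable at alpha = %g: %s\n", x$alpha,
              if (x$distinguishable) "yes" else "no"))
  invisible(x)
}

#' Simulate forward-scattering intensities from a reference distribution
#'
#' @param object A [ref_dist()] object.
#' @param nsim Number of draws.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param ... Unused.
#' @return Integer millivolt values, see [sample_taxon_forward()].
#' @export
simulate.ref_dist <- function(object, nsim = 1, seed = NULL, ...) {
  sample_taxon_forward(object, nsim, seed = seed)
}
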