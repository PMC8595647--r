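#' Solve the two-taxon unmixing system for one interval combination
#'
#' For integration intervals `(a, b)` and `(c, d)` with observed signal
#' counts `n_ab` and `n_cd`, solves the 2x2 linear system
#' \deqn{f_\alpha(a,b) N_\alpha + f_\beta(a,b) N_\beta = n_{ab}}
#' \deqn{f_\alpha(c,d) N_\alpha + f_\beta(c,d) N_\beta = n_{cd}}
#' where \eqn{f} is [truncated_mass()]. The real-valued solution is accepted
#' only if both components are non-negative (exactly `>= 0`, no epsilon);
#' near-singular systems (|det| below `singular_tol` times the product of
#' the coefficient row norms) are rejected and flagged separately.
#'
#' @param dist_alpha,dist_beta [ref_dist()] objects for the two taxa.
#' @param pair_first,pair_second Length-2 numeric interval endpoints
#'   `(a, b)` and `(c, d)`, millivolts.
#' @param n_ab,n_cd Observed signal counts in the two intervals.
#' @param singular_tol Relative determinant tolerance, default `1e-12`.
#' @return A list with `status` (`"accepted"`, `"negative"` or
#'   `"singular"`) and, when accepted, `n_alpha`, `n_beta`.
#' @examples
#' a <- ref_dist("C. obtusa", 408, 145); b <- ref_dist("C. japonica", 662, 257)
#' solve_pair(a, b, c(500, 600), c(600, 700), n_ab = 100, n_cd = 80)
#' @export
solve_pair <- function(dist_alpha, dist_beta, pair_first, pair_second,
                       n_ab, n_cd, singular_tol = 1e-12) {
  a11 <- truncated_mass(dist_alpha, pair_first[1], pair_first[2])
  a12 <- truncated_mass(dist_beta, pair_first[1], pair_first[2])
  a21 <- truncated_mass(dist_alpha, pair_second[1], pair_second[2])
  a22 <- truncated_mass(dist_beta, pair_second[1], pair_second[2])
  det <- a11 * a22 - a12 * a21
  if (abs(det) < singular_tol * sqrt(a11^2 + a12^2) * sqrt(a21^2 + a22^2))
    return(list(status = "singular", n_alpha = NA_real_, n_beta = NA_real_))
  na <- (n_ab * a22 - a12 * n_cd) / det
  nb <- (a11 * n_cd - n_ab * a21) / det
  if (na < 0 || nb < 0)
    return(list(status = "negative", n_alpha = na, n_beta = nb))
  list(status = "accepted", n_alpha = na, n_beta = nb)
}

#' Estimate two-taxon pollen counts by interval-wise unmixing
#'
#' The core estimator. For every combination of integration intervals in
#' `scheme`, the observed forward-scattering signal counts are unmixed into
#' candidate per-taxon counts via [solve_pair()]; candidates with any
#' negative component (or a near-singular system) are discarded, the
#' surviving solutions are rounded to `mode_bin` grains, and the most
#' frequently output value per taxon is adopted as the estimate. The
#' multiplicity of the adopted value (`mode_support`) feeds the
#' [confidence_coefficient()].
#'
#' Ties for the modal value are broken towards the smallest value and
#' flagged in the result. If no combination yields a non-negative solution
#' the result carries `NA` estimates with `n_outputs = 0` rather than
#' raising an error.
#'
#' @param forward Forward-scattering intensities (mV) of all signals
#'   attributed to pollen, e.g. one day's dust-gated records.
#' @param refs List of exactly two [ref_dist()] objects (alpha = first).
#' @param scheme An [interval_scheme()]; default the 500-600 / 600-700 mV,
#'   10 mV-step scheme (3025 combinations).
#' @param mode_bin Rounding bin (grains) used to group the real-valued
#'   solutions before taking the mode; default 1.
#' @param mode_method `"per_taxon"` (default): each taxon's mode is taken
#'   independently over its rounded outputs. `"joint"`: the most frequent
#'   rounded (alpha, beta) pair is adopted.
#' @param singular_tol Passed to the per-combination solver.
#' @return An object of class `ame` with components `estimates` (named per
#'   taxon; `NA` when no solution), `mode_support`, `n_outputs` (accepted
#'   solutions, L), `n_total` (combinations, N), `n_negative`, `n_singular`,
#'   `ties`, `candidates` (one row per combination with endpoints, counts,
#'   solution and status), `taxa`, `n_signals`, `mode_bin` and the `scheme`.
#' @examples
#' refs <- list(ref_dist("C. obtusa", 408, 145),
#'              ref_dist("C. japonica", 662, 257))
#' x <- make_mixture(562, 647, refs, seed = 1)
#' fit <- ame(x$log$forward, refs)
#' coef(fit)
#' @seealso [run_daily()] for the daily field pipeline built on this.
#' @export
ame <- function(forward, refs, scheme = interval_scheme(), mode_bin = 1,
                mode_method = c("per_taxon", "joint"), singular_tol = 1e-12) {
  mode_method <- match.arg(mode_method)
  refs <- as_ref_list(refs, n = 2L)
  stopifnot(inherits(scheme, "interval_scheme"))
  if (mode_bin <= 0) stop("'mode_bin' must be positive")
  v <- as.numeric(forward)
  if (anyNA(v)) stop("'forward' contains missing values")

  p1 <- scheme$pairs_first; p2 <- scheme$pairs_second
  fa1 <- truncated_mass(refs[[1]], p1[, 1], p1[, 2])
  fb1 <- truncated_mass(refs[[2]], p1[, 1], p1[, 2])
  fa2 <- truncated_mass(refs[[1]], p2[, 1], p2[, 2])
  fb2 <- truncated_mass(refs[[2]], p2[, 1], p2[, 2])
  # signal counts per interval from cumulative counts at the grid points
  cnt_lt <- function(g) vapply(g, function(gi) sum(v < gi), 0)
  n1 <- cnt_lt(p1[, 2]) - cnt_lt(p1[, 1])
  n2 <- cnt_lt(p2[, 2]) - cnt_lt(p2[, 1])

  i <- rep(seq_len(nrow(p1)), each = nrow(p2))
  j <- rep(seq_len(nrow(p2)), times = nrow(p1))
  A11 <- fa1[i]; A12 <- fb1[i]; A21 <- fa2[j]; A22 <- fb2[j]
  nab <- n1[i]; ncd <- n2[j]
  det <- A11 * A22 - A12 * A21
  singular <- abs(det) <
    singular_tol * sqrt(A11^2 + A12^2) * sqrt(A21^2 + A22^2)
  na <- ifelse(singular, NA_real_, (nab * A22 - A12 * ncd) / det)
  nb <- ifelse(singular, NA_real_, (A11 * ncd - A21 * nab) / det)
  accepted <- !singular & na >= 0 & nb >= 0
  status <- ifelse(singular, "singular", ifelse(accepted, "accepted", "negative"))

  candidates <- data.frame(
    a = p1[i, 1], b = p1[i, 2], c = p2[j, 1], d = p2[j, 2],
    n_ab = nab, n_cd = ncd, n_alpha = na, n_beta = nb, status = status)

  taxa <- names(refs)
  L <- sum(accepted)
  est <- c(NA_real_, NA_real_); supp <- c(0L, 0L); ties <- c(FALSE, FALSE)
  if (L > 0) {
    ra <- round(na[accepted] / mode_bin) * mode_bin
    rb <- round(nb[accepted] / mode_bin) * mode_bin
    if (mode_method == "per_taxon") {
      ma <- mode_smallest(ra); mb <- mode_smallest(rb)
      est <- c(ma$value, mb$value)
      ties <- c(ma$tied, mb$tied)
    } else {
      key <- paste(format(ra, scientific = FALSE), format(rb, scientific = FALSE))
      tab <- table(key)
      top <- names(tab)[tab == max(tab)]
      pick <- top[order(ra[match(top, key)], rb[match(top, key)])][1]
      k <- match(pick, key)
      est <- c(ra[k], rb[k])
      ties <- rep(length(top) > 1L, 2L)
    }
    supp <- c(sum(ra == est[1]), sum(rb == est[2]))
  }
  names(est) <- names(supp) <- names(ties) <- taxa

  structure(list(estimates = est, mode_support = supp,
                 n_outputs = L, n_total = scheme$n_combinations,
                 n_negative = sum(status == "negative"),
                 n_singular = sum(singular),
                 ties = ties, candidates = candidates, taxa = taxa,
                 n_signals = length(v), mode_bin = mode_bin,
                 mode_method = mode_method, scheme = scheme, refs = refs),
            class = "ame")
}

# Mode with smallest-value tie-break; returns the value and a tie flag.
mode_smallest <- function(x) {
  ux <- sort(unique(x))
  cnt <- vapply(ux, function(u) sum(x == u), 0L)
  top <- which(cnt == max(cnt))
  list(value = ux[top[1]], tied = length(top) > 1L)
}

#' @export
print.ame <- function(x, ...) {
  cat("Two-taxon unmixing estimate (", x$n_signals, " signals)\n", sep = "")
  if (x$n_outputs == 0) {
    cat("  No non-negative solution over", x$n_total, "interval combinations\n")
  } else {
    for (k in 1:2)
      cat(sprintf("  %-14s %8.0f grains  (mode support %d / %d outputs%s)\n",
                  x$taxa[k], x$estimates[k], x$mode_support[k], x$n_outputs,
                  if (x$ties[k]) ", tied" else ""))
  }
  invisible(x)
}

#' @export
coef.ame <- function(object, ...) object$estimates

#' @export
summary.ame <- function(object, ...) {
  structure(list(fit = object), class = "summary.ame")
}

#' @export
print.summary.ame <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  combinations: %d total; %d accepted (L), %d negative, %d singular\n",
              f$n_total, f$n_outputs, f$n_negative, f$n_singular))
  cat(sprintf("  mode bin: %g grain(s), mode: %s\n", f$mode_bin, f$mode_method))
  acc <- f$candidates[f$candidates$status == "accepted", ]
  if (nrow(acc)) {
    cat("  accepted-solution spread:\n")
    print(rbind(
      stats::setNames(stats::quantile(acc$n_alpha, c(.05, .5, .95)),
                      c("5%", "50%", "95%")),
      stats::quantile(acc$n_beta, c(.05, .5, .95))),
      digits = 4)
  }
  invisible(x)
}

#' Plot the distribution of accepted unmixing outputs
#'
#' Histograms of the accepted per-taxon candidate counts over all interval
#' combinations, with the adopted (modal) estimate marked. A tight spike at
#' the adopted value means a unique, well-supported output; a flat spread
#' means low confidence.
#'
#' @param x An [ame()] fit.
#' @param ... Passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.ame <- function(x, ...) {
  acc <- x$candidates[x$candidates$status == "accepted", ]
  if (!nrow(acc)) {
    warning("no accepted solutions to plot")
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  for (k in 1:2) {
    vals <- if (k == 1) acc$n_alpha else acc$n_beta
    graphics::hist(vals, main = x$taxa[k], xlab = "estimated grains",
                   col = "grey85", border = "grey40", ...)
    graphics::abline(v = x$estimates[k], col = "red3", lwd = 2)
  }
  invisible(x)
}

#' Confidence coefficient of a daily unmixing estimate
#'
#' Scores how unique the adopted output is:
#' \deqn{\frac{L}{N} \times \frac{C}{L} \times P = \frac{C\,P}{N}}
#' where `C` is the day's total estimated airborne concentration (both taxa
#' summed, grains m^-3), `P` the number of outputs equal to the adopted
#' value for the taxon, and `N` the total number of interval combinations.
#' Days where the coefficient is below 2.0 for both taxa are treated as
#' invalid by [validity()].
#'
#' @param total_concentration Daily total concentration C, grains m^-3.
#' @param mode_support Mode multiplicity P for the taxon.
#' @param n_total_combinations Total combinations N (3025 with the default
#'   scheme).
#' @return The coefficient `C * P / N`. Vectorised.
#' @examples
#' confidence_coefficient(23.7, 255, 3025)  # 1.9977...
#' @export
confidence_coefficient <- function(total_concentration, mode_support,
                                   n_total_combinations) {
  if (any(n_total_combinations <= 0))
    stop("'n_total_combinations' must be positive")
  if (any(total_concentration < 0) || any(mode_support < 0))
    stop("inputs must be non-negative")
  total_concentration * mode_support / n_total_combinations
}

#' Validity of a day's estimate from its confidence coefficients
#'
#' A day's result is invalid if and only if the confidence coefficients of
#' *both* taxa fall below the threshold; one confident taxon is enough to
#' keep the day.
#'
#' @param cc_alpha,cc_beta Per-taxon confidence coefficients (vectorised).
#' @param threshold Validity threshold, default 2.0.
#' @return Logical: `TRUE` where the day is valid.
#' @examples
#' validity(0.67, 0.89)  # FALSE
#' validity(2.07, 1.43)  # TRUE
#' @export
validity <- function(cc_alpha, cc_beta, threshold = 2.0) {
  if (any(cc_alpha < 0, na.rm = TRUE) || any(cc_beta < 0, na.rm = TRUE))
    stop("confidence coefficients must be non-negative")
  !(cc_alpha < threshold & cc_beta < threshold)
}
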