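#' Enumerate the integration-interval combinations
#'
#' The unmixing system is solved once for every combination of one
#' integration interval `(a, b)` from a first voltage range and one interval
#' `(c, d)` from a second range. Intervals are all unordered pairs of grid
#' points spaced `step` mV apart, enumerated in lexicographic order. With
#' the defaults (500-600 mV and 600-700 mV, 10 mV step) each range has 11
#' grid points, hence `choose(11, 2) = 55` intervals and `55 * 55 = 3025`
#' combinations.
#'
#' @param first_range,second_range Length-2 numeric `(lo, hi)` voltage
#'   ranges in mV; defaults `c(500, 600)` and `c(600, 700)`.
#' @param step Grid spacing in mV (must divide both range widths);
#'   default 10.
#' @return An object of class `interval_scheme` with components
#'   `pairs_first`, `pairs_second` (two-column matrices of interval
#'   endpoints), `n_combinations`, and the generating parameters.
#' @examples
#' sch <- interval_scheme()
#' sch$n_combinations  # 3025
#' @export
interval_scheme <- function(first_range = c(500, 600),
                            second_range = c(600, 700), step = 10) {
  pairs_first <- grid_pairs(first_range, step)
  pairs_second <- grid_pairs(second_range, step)
  structure(list(first_range = as.numeric(first_range),
                 second_range = as.numeric(second_range),
                 step = as.numeric(step),
                 pairs_first = pairs_first, pairs_second = pairs_second,
                 n_combinations = nrow(pairs_first) * nrow(pairs_second)),
            class = "interval_scheme")
}

grid_pairs <- function(range, step) {
  range <- as.numeric(range)
  if (length(range) != 2L || range[1] >= range[2])
    stop("a range must be (lo, hi) with lo < hi")
  if (step <= 0) stop("'step' must be positive")
  width <- range[2] - range[1]
  if (abs(width / step - round(width / step)) > 1e-9)
    stop("'step' (", step, ") must divide the range width (", width, ")")
  pts <- seq(range[1], range[2], by = step)
  idx <- which(upper.tri(matrix(0, length(pts), length(pts))), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  cbind(lo = pts[idx[, "row"]], hi = pts[idx[, "col"]])
}

#' @export
print.interval_scheme <- function(x, ...) {
  cat("Integration-interval scheme\n")
  cat(sprintf("  first range : %g-%g mV, step %g -> %d intervals\n",
              x$first_range[1], x$first_range[2], x$step, nrow(x$pairs_first)))
  cat(sprintf("  second range: %g-%g mV, step %g -> %d intervals\n",
              x$second_range[1], x$second_range[2], x$step,
              nrow(x$pairs_second)))
  cat(sprintf("  combinations: %d\n", x$n_combinations))
  invisible(x)
}

#' Count signals in a half-open voltage interval
#'
#' Number of forward-scattering values `v` with `a <= v < b`. The half-open
#' convention lets adjacent grid intervals tile the voltage axis without
#' double counting; a value at exactly the boundary between the two scheme
#' ranges belongs to the second range's intervals.
#'
#' @param forward_values Numeric forward-scattering intensities, mV.
#' @param a,b Interval endpoints, `a < b`.
#' @return Integer count.
#' @examples
#' count_in_interval(c(505, 510, 599), 500, 510)  # 1; 510 is excluded
#' @export
count_in_interval <- function(forward_values, a, b) {
  if (a >= b) stop("'a' must be strictly below 'b'")
  v <- as.numeric(forward_values)
  sum(v >= a & v < b)
}
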