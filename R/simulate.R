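# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Draw forward-scattering intensities for one taxon
#'
#' Samples from the taxon's Gaussian reference distribution truncated to
#' its support by rejection (out-of-range draws are resampled, never
#' clipped, so no probability mass piles up at the bounds), then rounds to
#' the instrument's integer millivolt grid.
#'
#' @param dist A [ref_dist()] object.
#' @param n Number of draws.
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return `n` integer millivolt values within the support.
#' @examples
#' x <- sample_taxon_forward(ref_dist("C. japonica", 662, 257), 1000, seed = 7)
#' range(x)
#' @export
sample_taxon_forward <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "ref_dist"), n >= 0)
  with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      draw <- stats::rnorm(max(n - length(out), 16L), dist$mu, dist$sigma)
      out <- c(out, draw[draw >= dist$support_lo & draw <= dist$support_hi])
    }
    as.integer(round(out[seq_len(n)]))
  })
}

#' Generate one mixed two-taxon signal log with known truth
#'
#' Emulates a laboratory mixing test: `n_alpha` and `n_beta` signals are
#' drawn from the two reference distributions, given side-scatter values
#' inside the pollen band and timestamps uniform within one day, and
#' interleaved in time order. The generating counts are returned alongside
#' as ground truth.
#'
#' @param n_alpha,n_beta True per-taxon signal counts.
#' @param refs List of exactly two [ref_dist()] objects (alpha = first).
#' @param date Calendar day for the timestamps.
#' @param side_range Pollen side-scatter band (mV); side values are drawn
#'   uniformly within it. Default `c(400, 1400)`, the dust-gate band.
#' @param seed Optional integer seed.
#' @return A list with `log` (a [signal_log()]) and `truth` (data frame of
#'   per-taxon true counts).
#' @examples
#' refs <- list(ref_dist("C. obtusa", 408, 145),
#'              ref_dist("C. japonica", 662, 257))
#' mx <- make_mixture(562, 647, refs, seed = 1)
#' nrow(mx$log)  # 1209
#' @export
make_mixture <- function(n_alpha, n_beta, refs, date = "2012-03-25",
                         side_range = c(400, 1400), seed = NULL) {
  refs <- as_ref_list(refs, n = 2L)
  stopifnot(n_alpha >= 0, n_beta >= 0)
  with_seed(seed, {
    fwd <- c(sample_taxon_forward(refs[[1]], n_alpha),
             sample_taxon_forward(refs[[2]], n_beta))
    n <- n_alpha + n_beta
    log <- signal_log(day_timestamps(date, n), fwd,
                      sample_side(n, side_range))
    truth <- data.frame(taxon = names(refs),
                        true_count = c(n_alpha, n_beta))
    list(log = log, truth = truth)
  })
}

day_timestamps <- function(date, n) {
  d0 <- as.POSIXct(paste0(as.character(date), " 00:00:00"), tz = "UTC")
  format(d0 + floor(stats::runif(n, 0, 86400)), "%Y-%m-%dT%H:%M:%S")
}

sample_side <- function(n, range) {
  as.integer(round(stats::runif(n, range[1], range[2])))
}

#' Define a multi-day simulation scenario
#'
#' Bundles everything [make_field_series()] needs: the two reference
#' distributions, the true per-day pollen counts, and the dust model. Dust
#' records get forward scatters uniform on `dust_forward_range` (so they
#' overlap the pollen signal band — only the side-scatter gate separates
#' them) and side scatters outside the pollen band `[400, 1400]` mV, except
#' for a fraction `dust_in_band` drawn inside it to emulate pollen-like
#' dust.
#'
#' @param refs List of exactly two [ref_dist()] objects.
#' @param daily_counts Data frame with columns `n_alpha`, `n_beta` (one row
#'   per day) and optionally `date`; without dates, consecutive days from
#'   `start_date` are used.
#' @param dust_rate Expected dust records per day (Poisson); default 0.
#' @param dust_in_band Fraction of dust whose side scatter falls inside the
#'   pollen band (survives the gate); default 0.
#' @param dust_forward_range Forward-scatter range for dust, mV.
#' @param start_date First day, used when `daily_counts` has no `date`.
#' @param seed Integer seed; fixed seed implies byte-identical output.
#' @return An object of class `sim_scenario`.
#' @seealso [make_field_series()]
#' @export
simulation_scenario <- function(refs, daily_counts, dust_rate = 0,
                                dust_in_band = 0,
                                dust_forward_range = c(100, 1500),
                                start_date = "2012-03-24", seed = 1) {
  refs <- as_ref_list(refs, n = 2L)
  stopifnot(is.data.frame(daily_counts),
            all(c("n_alpha", "n_beta") %in% names(daily_counts)),
            all(daily_counts$n_alpha >= 0), all(daily_counts$n_beta >= 0),
            dust_rate >= 0, dust_in_band >= 0, dust_in_band <= 1)
  if (!"date" %in% names(daily_counts))
    daily_counts$date <- seq(as.Date(start_date), by = "day",
                             length.out = nrow(daily_counts))
  daily_counts$date <- as.Date(daily_counts$date)
  structure(list(refs = refs, daily_counts = daily_counts,
                 dust_rate = dust_rate, dust_in_band = dust_in_band,
                 dust_forward_range = as.numeric(dust_forward_range),
                 seed = seed),
            class = "sim_scenario")
}

#' Generate a multi-day field signal stream with dust and known truth
#'
#' For each day of the scenario, draws the true numbers of pollen signals
#' from the two reference distributions (side scatters inside the 400-1400
#' mV pollen band) plus a Poisson number of dust records (side scatters
#' outside the band, except for the configured in-band fraction), all with
#' timestamps uniform within the day. The truth table carries per-day true
#' counts and the concentrations they correspond to at the default
#' 4.1 L min^-1 flow.
#'
#' @param scenario A [simulation_scenario()].
#' @return A list with `log` (one [signal_log()] covering all days) and
#'   `truth` (long data frame `date`, `taxon`, `true_count`,
#'   `true_concentration_m3`, plus per-day `n_dust` rows under taxon
#'   `".dust"`).
#' @examples
#' refs <- list(ref_dist("C. obtusa", 408, 145),
#'              ref_dist("C. japonica", 662, 257))
#' sc <- simulation_scenario(refs,
#'         data.frame(n_alpha = c(50, 100), n_beta = c(400, 200)),
#'         dust_rate = 30, seed = 42)
#' fs <- make_field_series(sc)
#' @export
make_field_series <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  refs <- scenario$refs
  with_seed(scenario$seed, {
    logs <- list(); truths <- list()
    for (k in seq_len(nrow(scenario$daily_counts))) {
      row <- scenario$daily_counts[k, ]
      na <- row$n_alpha; nb <- row$n_beta
      n_dust <- if (scenario$dust_rate > 0)
        stats::rpois(1, scenario$dust_rate) else 0L
      fwd <- c(sample_taxon_forward(refs[[1]], na),
               sample_taxon_forward(refs[[2]], nb),
               if (n_dust > 0)
                 as.integer(round(stats::runif(n_dust,
                                               scenario$dust_forward_range[1],
                                               scenario$dust_forward_range[2]))))
      side <- c(sample_side(na + nb, c(400, 1400)),
                if (n_dust > 0) dust_side(n_dust, scenario$dust_in_band))
      n <- na + nb + n_dust
      logs[[k]] <- data.frame(timestamp = day_timestamps(row$date, n),
                              forward = fwd, side = side)
      truths[[k]] <- data.frame(
        date = row$date, taxon = c(names(refs), ".dust"),
        true_count = c(na, nb, n_dust),
        true_concentration_m3 = c(to_concentration(c(na, nb)), NA))
    }
    all <- do.call(rbind, logs)
    list(log = signal_log(all$timestamp, all$forward, all$side),
         truth = do.call(rbind, truths))
  })
}

# Dust side scatter: outside the 400-1400 mV pollen band, except an
# in-band contaminating fraction.
dust_side <- function(n, in_band_frac) {
  inb <- stats::runif(n) < in_band_frac
  below <- stats::runif(n) < 0.5
  out <- ifelse(below, stats::runif(n, 0, 399), stats::runif(n, 1401, 4500))
  out[inb] <- stats::runif(sum(inb), 400, 1400)
  as.integer(round(out))
}
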