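#' Read per-taxon reference distributions from a config file
#'
#' The config is a plain-text file of blank-line-separated key: value blocks
#' (Debian control format, read with [base::read.dcf()]), one block per
#' taxon with fields `taxon`, `mu`, `sigma` and optionally `support_lo`,
#' `support_hi` (defaults 0 and 4500 mV):
#'
#' ```
#' taxon: C. obtusa
#' mu: 408
#' sigma: 145
#'
#' taxon: C. japonica
#' mu: 662
#' sigma: 257
#' ```
#'
#' @param path Path to the config file.
#' @return A named list of [ref_dist()] objects, one per taxon block.
#' @seealso [write_reference_config()]
#' @export
read_reference_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- read.dcf(path)
  need <- c("taxon", "mu", "sigma")
  miss <- setdiff(need, colnames(m))
  if (length(miss))
    stop("reference config missing field(s): ", paste(miss, collapse = ", "))
  get <- function(field, default) {
    if (field %in% colnames(m)) {
      v <- suppressWarnings(as.numeric(m[, field]))
      ifelse(is.na(v), default, v)
    } else rep(default, nrow(m))
  }
  taxa <- m[, "taxon"]
  if (anyNA(taxa) || any(!nzchar(taxa))) stop("every block needs a 'taxon' name")
  if (anyDuplicated(taxa)) stop("duplicate taxon names in reference config")
  mu <- get("mu", NA_real_); sigma <- get("sigma", NA_real_)
  if (anyNA(mu) || anyNA(sigma)) stop("non-numeric 'mu' or 'sigma'")
  lo <- get("support_lo", 0); hi <- get("support_hi", 4500)
  refs <- mapply(ref_dist, taxa, mu, sigma, lo, hi, SIMPLIFY = FALSE)
  names(refs) <- taxa
  refs
}

#' Write reference distributions to a config file
#'
#' @param refs A list of [ref_dist()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_reference_config()]
#' @export
write_reference_config <- function(refs, path) {
  refs <- as_ref_list(refs, n = length(refs))
  m <- do.call(rbind, lapply(refs, function(r)
    cbind(taxon = r$taxon, mu = format(r$mu), sigma = format(r$sigma),
          support_lo = format(r$support_lo), support_hi = format(r$support_hi))))
  write.dcf(m, path)
  invisible(path)
}

# Validate a list of ref_dist objects (exactly n when n is given).
as_ref_list <- function(refs, n = NULL) {
  if (inherits(refs, "ref_dist")) refs <- list(refs)
  if (!is.list(refs) || !all(vapply(refs, inherits, TRUE, "ref_dist")))
    stop("'refs' must be a list of ref_dist objects")
  if (!is.null(n) && length(refs) != n)
    stop("expected exactly ", n, " reference distribution(s), got ",
         length(refs))
  nm <- vapply(refs, `[[`, "", "taxon")
  if (anyDuplicated(nm)) stop("duplicate taxon names")
  names(refs) <- nm
  refs
}

#' Write daily two-taxon estimates to CSV
#'
#' Long format, one row per day and taxon, with header
#' `date,taxon,concentration_m3,confidence_coefficient,valid,n_outputs,mode_support`.
#'
#' @param daily A daily-estimate table from [run_daily()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_daily_estimates <- function(daily, path) {
  stopifnot(inherits(daily, "ame_daily"))
  taxa <- attr(daily, "taxa")
  long <- rbind(
    data.frame(date = daily$date, taxon = taxa[1],
               concentration_m3 = daily$concentration_alpha,
               confidence_coefficient = daily$cc_alpha,
               valid = daily$valid, n_outputs = daily$n_outputs,
               mode_support = daily$mode_support_alpha),
    data.frame(date = daily$date, taxon = taxa[2],
               concentration_m3 = daily$concentration_beta,
               confidence_coefficient = daily$cc_beta,
               valid = daily$valid, n_outputs = daily$n_outputs,
               mode_support = daily$mode_support_beta))
  long <- long[order(long$date, long$taxon), ]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a daily deposition reference table
#'
#' Reads gravimetric (Durham-sampler style) daily deposition counts used as
#' the manual reference in [compare_reference()]. Expected header:
#' `date,taxon,deposition_cm2`.
#'
#' @param path Path to the CSV file.
#' @return A data frame with columns `date` (Date), `taxon`,
#'   `deposition_cm2`.
#' @export
read_deposition <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("date", "taxon", "deposition_cm2")
  if (!all(need %in% names(df)))
    stop("deposition table needs columns ", paste(need, collapse = ","))
  data.frame(date = as.Date(df$date), taxon = df$taxon,
             deposition_cm2 = as.numeric(df$deposition_cm2))
}

#' Published two-week field summary (Funabashi, spring 2012)
#'
#' Daily summary of a two-week field campaign (24 March - 6 April 2012) at
#' the Funabashi monitoring site, where a KH-3000-01 laser-optics counter
#' ran alongside a Durham gravimetric sampler during the season in which
#' *Chamaecyparis obtusa* and *Cryptomeria japonica* pollen are both
#' airborne. Columns: per-taxon Durham deposition (grains cm^-2), per-taxon
#' unmixed volumetric concentration (grains m^-3), per-taxon confidence
#' coefficients, the published confident/not-confident call, and the number
#' of non-negative unmixing outputs (`valid_plots`).
#'
#' @return A data frame with one row per day.
#' @examples
#' fb <- funabashi_daily()
#' validity(fb$cc_obtusa, fb$cc_japonica)  # matches fb$confident
#' @export
funabashi_daily <- function() {
  path <- system.file("extdata", "funabashi_2012_daily.csv",
                      package = "amepollen", mustWork = TRUE)
  df <- utils::read.csv(path)
  df$date <- as.Date(df$date)
  df$confident <- as.logical(df$confident)
  df
}

#' Published laboratory evaluation tests of the unmixing estimator
#'
#' Five laboratory mixtures of *C. obtusa* and *C. japonica* scattering
#' signals with known per-taxon counts, alongside the counts the unmixing
#' estimator reported for them. The true counts serve as realistic inputs
#' for the synthetic-data generator.
#'
#' @return A data frame with columns `test`, `actual_obtusa`,
#'   `actual_japonica`, `estimated_obtusa`, `estimated_japonica`.
#' @export
evaluation_tests <- function() {
  path <- system.file("extdata", "evaluation_tests.csv",
                      package = "amepollen", mustWork = TRUE)
  utils::read.csv(path)
}
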