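#' Particle-counter signal log
#'
#' One row per detected particle: a timestamp plus the forward and side
#' light-scattering intensities in millivolts. Records are kept sorted by
#' timestamp; duplicate timestamps are allowed (distinct particles may be
#' detected within the same second).
#'
#' @param timestamp POSIXct (or ISO-8601 strings) detection times.
#' @param forward,side Scattering intensities, millivolts, each in
#'   `[0, 4500]`. Stored as integers.
#' @param site_label,device_label Free-text labels.
#' @return A data frame of class `signal_log` with columns `timestamp`,
#'   `forward`, `side`, sorted by timestamp, carrying `site_label` and
#'   `device_label` attributes.
#' @examples
#' signal_log(c("2012-03-25T09:14:02", "2012-03-25T09:13:50"),
#'            forward = c(612, 430), side = c(740, 800))
#' @export
signal_log <- function(timestamp = character(), forward = integer(),
                       side = integer(), site_label = "", device_label = "") {
  ts <- parse_timestamp(timestamp)
  forward <- as.numeric(forward); side <- as.numeric(side)
  n <- length(ts)
  if (length(forward) != n || length(side) != n)
    stop("'timestamp', 'forward' and 'side' must have equal length")
  if (anyNA(ts)) stop("unparseable or missing timestamps")
  check_mv(forward, "forward"); check_mv(side, "side")
  out <- data.frame(timestamp = ts,
                    forward = as.integer(round(forward)),
                    side = as.integer(round(side)))
  out <- out[order(out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, site_label = site_label, device_label = device_label,
            class = c("signal_log", "data.frame"))
}

parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(format(x, tz = "UTC"), tz = "UTC"))
  as.POSIXct(as.character(x), tz = "UTC",
             tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                            "%Y-%m-%d"))
}

check_mv <- function(v, what) {
  if (anyNA(v) || any(v < 0) || any(v > 4500))
    stop("'", what, "' intensities must lie in [0, 4500] mV")
  invisible(v)
}

#' @export
print.signal_log <- function(x, ...) {
  cat(sprintf("Signal log: %d record(s)", nrow(x)))
  lab <- attr(x, "site_label")
  if (nzchar(lab)) cat(", site ", lab, sep = "")
  cat("\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("  ... and", nrow(x) - 10L, "more row(s)\n")
  invisible(x)
}

#' Read a particle signal log from CSV
#'
#' Expects the dialect `timestamp,forward_mV,side_mV` with ISO-8601
#' timestamps and integer millivolts. Rows whose intensities fall outside
#' `[0, 4500]` mV (e.g. saturated readings) or whose timestamps do not parse
#' are, under the default `on_invalid = "skip"` policy, dropped with a
#' warning stating how many rows were rejected; with `on_invalid = "fail"`
#' any such row is an error.
#'
#' @param path Path to the CSV file.
#' @param on_invalid Row-level validation policy: `"skip"` (default) or
#'   `"fail"`.
#' @return A [signal_log()]; the number of rejected rows is available as
#'   `attr(x, "n_rejected")`.
#' @seealso [write_signal_log()]
#' @export
read_signal_log <- function(path, on_invalid = c("skip", "fail")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  expected <- c("timestamp", "forward_mV", "side_mV")
  if (!identical(names(df)[seq_along(expected)], expected)) {
    bad <- setdiff(expected, names(df))
    stop("malformed signal-log header: expected columns ",
         paste(expected, collapse = ","),
         if (length(bad)) paste0("; missing ", paste(bad, collapse = ",")))
  }
  ts <- suppressWarnings(parse_timestamp(df$timestamp))
  fwd <- suppressWarnings(as.numeric(df$forward_mV))
  sde <- suppressWarnings(as.numeric(df$side_mV))
  ok <- !is.na(ts) & !is.na(fwd) & !is.na(sde) &
    fwd >= 0 & fwd <= 4500 & sde >= 0 & sde <= 4500
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    if (on_invalid == "fail")
      stop(n_bad, " row(s) violate the signal-log invariants ",
           "(unparseable timestamp or intensity outside [0, 4500] mV)")
    warning("skipped ", n_bad, " invalid row(s) in ", path)
  }
  log <- signal_log(format(ts[ok], "%Y-%m-%dT%H:%M:%S"), fwd[ok], sde[ok])
  attr(log, "n_rejected") <- n_bad
  log
}

#' Write a particle signal log to CSV
#'
#' Writes the `timestamp,forward_mV,side_mV` dialect read by
#' [read_signal_log()]; a write/read round trip reproduces every record
#' field-for-field (millivolts are integers, timestamps second-resolution
#' ISO-8601).
#'
#' @param log A [signal_log()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_log <- function(log, path) {
  stopifnot(inherits(log, "signal_log"))
  out <- data.frame(timestamp = format(log$timestamp, "%Y-%m-%dT%H:%M:%S"),
                    forward_mV = log$forward, side_mV = log$side)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
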