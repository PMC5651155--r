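#' Multichannel MEG recording
#'
#' A recording holds one brain region's gradiometer channels as a
#' channels-by-samples numeric matrix together with its sampling rate.
#' Regions carry 26 channels, except the two occipital regions with 24.
#'
#' @param data numeric matrix, one row per channel, one column per sample.
#'   Amplitudes are in arbitrary (sensor) units; all values must be finite.
#' @param fs sampling rate in Hz (positive scalar).
#' @param region region name, one of [region_names()].
#' @return an object of class `meg_recording` with fields `data`, `fs`,
#'   `region` and `channel_count`.
#' @examples
#' rec <- recording(matrix(rnorm(26 * 1000), nrow = 26), fs = 1000)
#' rec$channel_count
#' @export
recording <- function(data, fs, region = "left_temporal") {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric channels-by-samples matrix", call. = FALSE)
  if (!all(is.finite(data)))
    stop("recording contains non-finite samples", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)", call. = FALSE)
  region <- match.arg(region, region_names())
  n_ch <- nrow(data)
  if (!n_ch %in% c(24L, 26L))
    stop("a regional recording has 26 channels (24 for occipital regions), got ",
         n_ch, call. = FALSE)
  structure(
    list(data = data, fs = fs, region = region, channel_count = n_ch),
    class = "meg_recording"
  )
}

#' The eight scalp region names
#'
#' Left/right crossed with frontal, temporal, parietal and occipital.
#' @return character vector of length 8.
#' @export
region_names <- function() {
  as.vector(outer(c("left", "right"),
                  c("frontal", "temporal", "parietal", "occipital"),
                  paste, sep = "_"))
}

#' @export
print.meg_recording <- function(x, ...) {
  cat(sprintf("<meg_recording> %d channels x %d samples, fs = %g Hz, region = %s\n",
              x$channel_count, ncol(x$data), x$fs, x$region))
  invisible(x)
}

#' Read / write a recording in the plain-text dialect
#'
#' The on-disk format is CSV with one row per channel, preceded by a single
#' header line `# fs=<Hz> region=<name>`.
#'
#' @param rec an `meg_recording`.
#' @param path file path.
#' @return `read_recording` returns an `meg_recording`; `write_recording`
#'   returns `path` invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "meg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%s region=%s", format(rec$fs), rec$region), con)
  utils::write.table(rec$data, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header,
                  regexec("^#\\s*fs=([0-9.eE+-]+)\\s+region=(\\S+)", header))[[1]]
  if (length(m) != 3L)
    stop("missing or malformed recording header line '# fs=<Hz> region=<name>'",
         call. = FALSE)
  dat <- as.matrix(utils::read.table(path, sep = ",", skip = 1L,
                                     colClasses = "numeric"))
  dimnames(dat) <- NULL
  recording(dat, fs = as.numeric(m[2]), region = m[3])
}

#' Read / write expert spike annotations
#'
#' Annotations are half-open `[start_sample, end_sample)` intervals in 0-based
#' sample coordinates, stored as TSV with columns `start_sample`, `end_sample`,
#' `region`.
#'
#' @param events data frame with integer columns `start_sample` and
#'   `end_sample` (and optionally `region`).
#' @param path file path.
#' @param region region name written when `events` lacks a `region` column.
#' @export
write_annotations <- function(events, path, region = "left_temporal") {
  events <- validate_events(events)
  if (is.null(events$region)) events$region <- rep(region, nrow(events))
  utils::write.table(events[, c("start_sample", "end_sample", "region")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  validate_events(ev)
}

validate_events <- function(events) {
  if (nrow(events) == 0L)
    return(data.frame(start_sample = integer(), end_sample = integer()))
  if (!all(c("start_sample", "end_sample") %in% names(events)))
    stop("annotations need columns start_sample and end_sample", call. = FALSE)
  if (any(events$end_sample <= events$start_sample))
    stop("malformed annotation interval: end_sample <= start_sample",
         call. = FALSE)
  if (any(events$start_sample < 0))
    stop("annotation start_sample must be >= 0", call. = FALSE)
  events
}
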