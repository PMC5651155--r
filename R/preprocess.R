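#' Segmentation configuration
#'
#' Windows are 100 ms with 50% overlap by default, the epoch length chosen
#' from the distribution of interictal spike durations (bulk below 150 ms).
#' The window length in samples is `round(window_ms * fs / 1000)`, so at
#' 1000 Hz the canonical window is exactly N = 100 samples.
#'
#' @param window_ms window duration in milliseconds.
#' @param overlap_fraction fraction of the window shared by consecutive
#'   windows, in `[0, 1)`.
#' @param median_filter_order odd positive integer; kernel length of the
#'   per-segment median smoother.
#' @return a `segmentation_config` list.
#' @export
segmentation_config <- function(window_ms = 100, overlap_fraction = 0.5,
                                median_filter_order = 5L) {
  if (window_ms <= 0) stop("window_ms must be positive", call. = FALSE)
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)", call. = FALSE)
  median_filter_order <- as.integer(median_filter_order)
  if (median_filter_order < 1L || median_filter_order %% 2L == 0L)
    stop("median_filter_order must be an odd integer >= 1", call. = FALSE)
  structure(list(window_ms = window_ms,
                 overlap_fraction = overlap_fraction,
                 median_filter_order = median_filter_order),
            class = "segmentation_config")
}

#' Window length and hop in samples
#' @param cfg a [segmentation_config()].
#' @param fs sampling rate in Hz.
#' @return integer window length (`window_samples`) or hop (`window_step`).
#' @export
window_samples <- function(cfg, fs) {
  n <- as.integer(round(cfg$window_ms * fs / 1000))
  if (n < 1L) stop("window shorter than one sample at this rate", call. = FALSE)
  n
}

#' @rdname window_samples
#' @export
window_step <- function(cfg, fs) {
  n <- window_samples(cfg, fs)
  max(1L, as.integer(round(n * (1 - cfg$overlap_fraction))))
}

#' 0-based start positions of the overlapping windows
#'
#' Starts run `0, step, 2*step, ...` while a full window fits; a trailing
#' partial window is discarded, giving `floor((L - N) / step) + 1` windows.
#'
#' @param n_samples signal length L.
#' @param n window length N in samples.
#' @param step hop in samples.
#' @return integer vector of 0-based start samples.
#' @export
segment_starts <- function(n_samples, n, step) {
  if (n_samples < n)
    stop("signal shorter than one window (", n_samples, " < ", n, ")",
         call. = FALSE)
  seq.int(0L, n_samples - n, by = step)
}

#' Cut one channel into overlapping segments
#'
#' @param signal numeric vector, one channel.
#' @param cfg a [segmentation_config()].
#' @param fs sampling rate in Hz.
#' @return list of segments; each is a list with `values` (raw, unsmoothed),
#'   `start_sample` (0-based) and `label` (`"unknown"`).
#' @examples
#' segs <- segment_channel(rnorm(1000), segmentation_config(), fs = 1000)
#' length(segs)  # 19
#' @export
segment_channel <- function(signal, cfg, fs) {
  n <- window_samples(cfg, fs)
  starts <- segment_starts(length(signal), n, window_step(cfg, fs))
  lapply(starts, function(s) {
    list(values = signal[(s + 1L):(s + n)], start_sample = s,
         label = "unknown")
  })
}

# All windows of one channel as an N x n_windows matrix (fast path used by
# feature tables and scoring; column j is the window starting at starts[j]).
window_matrix <- function(signal, n, step) {
  starts <- segment_starts(length(signal), n, step)
  idx <- outer(seq_len(n), starts, `+`)
  m <- matrix(signal[idx], nrow = n)
  attr(m, "starts") <- starts
  m
}

#' Median smoothing with edge replication
#'
#' Running median of odd order `k`; the signal is padded by replicating its
#' first and last values so the output has the input's length. `order = 1`
#' is the identity.
#'
#' @param x numeric vector (one segment's samples).
#' @param order odd integer kernel length, `order <= length(x)`.
#' @return numeric vector, same length as `x`.
#' @examples
#' median_smooth(c(1, 9, 1, 1, 1), 3)  # impulse removed
#' @export
median_smooth <- function(x, order = 5L) {
  order <- as.integer(order)
  if (order %% 2L == 0L || order < 1L)
    stop("median filter order must be an odd integer >= 1", call. = FALSE)
  if (order == 1L) return(x)
  if (order > length(x))
    stop("median filter order exceeds segment length", call. = FALSE)
  h <- (order - 1L) %/% 2L
  padded <- c(rep(x[1L], h), x, rep(x[length(x)], h))
  # interior of runmed over the padded signal == replicate-padded medians
  sm <- stats::runmed(padded, order, endrule = "keep")
  sm[(h + 1L):(h + length(x))]
}

# column-wise median smoothing of a window matrix
smooth_columns <- function(m, order) {
  if (order == 1L) return(m)
  apply(m, 2L, median_smooth, order = order)
}

#' The eight window statistics
#'
#' For a window of N samples the features are X1 = max, X2 = min,
#' X3 = mean, X4 = standard deviation (1/(N-1) normalisation), X5 = median,
#' X6 = interquartile range, X7 = kurtosis, X8 = skewness.
#'
#' Two definitions are deliberately nonstandard and kept throughout the
#' package:
#' * kurtosis and skewness use the 1/(N-1) normalisation,
#'   `sum((x - mu)^4) / ((N - 1) * sigma^4)` and
#'   `sum((x - mu)^3) / ((N - 1) * sigma^3)`, not the usual 1/N moment
#'   estimators (a Gaussian sample therefore has kurtosis near 3 * N/(N-1));
#' * quartiles are medians of the exclusive halves: the lower half is the
#'   data below the median and the upper half the data above it, the middle
#'   point being excluded from both when N is odd. No interpolation.
#'
#' A zero-variance window is degenerate: kurtosis and skewness are defined
#' as 0 (rather than NaN) and the result carries `attr(, "degenerate")`.
#'
#' @param x numeric vector of window samples (post-smoothing), length >= 4,
#'   or a segment list as produced by [segment_channel()].
#' @return named numeric vector `X1..X8`.
#' @examples
#' extract_features(c(1, 2, 3, 4))[["X6"]]  # IQR = 3.5 - 1.5 = 2
#' @export
extract_features <- function(x) {
  if (is.list(x)) x <- x$values
  n <- length(x)
  if (n < 2L) stop("segment too short for feature extraction (N < 2)",
                   call. = FALSE)
  s <- sort(x)
  mu <- mean(x)
  d <- x - mu
  ss <- sum(d * d)
  sigma <- sqrt(ss / (n - 1L))
  q <- exclusive_quartiles(s)
  if (sigma == 0) {
    kur <- 0
    ske <- 0
  } else {
    kur <- sum(d^4) / ((n - 1L) * sigma^4)
    ske <- sum(d^3) / ((n - 1L) * sigma^3)
  }
  out <- c(X1 = s[n], X2 = s[1L], X3 = mu, X4 = sigma,
           X5 = sorted_median(s, 1L, n), X6 = q[2L] - q[1L],
           X7 = kur, X8 = ske)
  if (sigma == 0) attr(out, "degenerate") <- TRUE
  out
}

# median of sorted[i:j]
sorted_median <- function(s, i, j) {
  l <- j - i + 1L
  if (l %% 2L == 1L) s[i + (l - 1L) %/% 2L]
  else (s[i + l %/% 2L - 1L] + s[i + l %/% 2L]) / 2
}

# Q1/Q3 as medians of the exclusive halves of a sorted vector
exclusive_quartiles <- function(s) {
  n <- length(s)
  if (n %% 2L == 0L) {
    c(sorted_median(s, 1L, n %/% 2L), sorted_median(s, n %/% 2L + 1L, n))
  } else {
    h <- (n - 1L) %/% 2L
    c(sorted_median(s, 1L, h), sorted_median(s, n - h + 1L, n))
  }
}

#' Feature matrix for many windows at once
#'
#' Vectorised equivalent of applying [extract_features()] to every column of
#' an N x m window matrix.
#'
#' @param m numeric matrix, one window per column.
#' @return m x 8 numeric matrix with columns `X1..X8`.
#' @export
extract_features_matrix <- function(m) {
  n <- nrow(m)
  if (n < 2L) stop("segment too short for feature extraction (N < 2)",
                   call. = FALSE)
  s <- apply(m, 2L, sort)
  mu <- colMeans(m)
  d <- m - rep(mu, each = n)
  ss <- colSums(d * d)
  sigma <- sqrt(ss / (n - 1L))
  ok <- sigma > 0
  kur <- ske <- numeric(ncol(m))
  kur[ok] <- colSums(d[, ok, drop = FALSE]^4) / ((n - 1L) * sigma[ok]^4)
  ske[ok] <- colSums(d[, ok, drop = FALSE]^3) / ((n - 1L) * sigma[ok]^3)
  med <- if (n %% 2L == 1L) s[(n + 1L) %/% 2L, ]
         else (s[n %/% 2L, ] + s[n %/% 2L + 1L, ]) / 2
  lo <- if (n %% 2L == 0L) c(1L, n %/% 2L) else c(1L, (n - 1L) %/% 2L)
  hi <- if (n %% 2L == 0L) c(n %/% 2L + 1L, n) else c(n - (n - 1L) %/% 2L + 1L, n)
  q1 <- half_median(s, lo)
  q3 <- half_median(s, hi)
  cbind(X1 = s[n, ], X2 = s[1L, ], X3 = mu, X4 = sigma, X5 = med,
        X6 = q3 - q1, X7 = kur, X8 = ske)
}

# row-indexed median of sorted-matrix rows range[1]:range[2]
half_median <- function(s, range) {
  l <- range[2L] - range[1L] + 1L
  if (l %% 2L == 1L) s[range[1L] + (l - 1L) %/% 2L, ]
  else (s[range[1L] + l %/% 2L - 1L, ] + s[range[1L] + l %/% 2L, ]) / 2
}

#' Ground-truth label of a window from expert spike intervals
#'
#' A window is labelled `"spike"` when it overlaps some annotated interval by
#' at least half the window length; otherwise `"nonspike"`. Both windows and
#' annotations are half-open `[start, end)` intervals in 0-based samples.
#' With 50% window overlap this rule guarantees that every spike of at least
#' half a window's duration labels at least one window positive.
#'
#' @param starts integer vector of 0-based window starts.
#' @param n window length in samples.
#' @param events data frame with columns `start_sample`, `end_sample`.
#' @return character vector of `"spike"` / `"nonspike"`, one per window.
#' @export
label_segments <- function(starts, n, events) {
  events <- validate_events(events)
  lab <- rep("nonspike", length(starts))
  if (nrow(events) == 0L) return(lab)
  need <- n / 2
  for (i in seq_len(nrow(events))) {
    ov <- pmin(starts + n, events$end_sample[i]) -
          pmax(starts, events$start_sample[i])
    lab[ov >= need] <- "spike"
  }
  lab
}

#' @rdname label_segments
#' @param segment a segment list with fields `start_sample` and `values`.
#' @export
label_segment <- function(segment, events) {
  label_segments(segment$start_sample, length(segment$values), events)
}

#' Labelled feature table for a whole recording
#'
#' Segments every channel, median-smooths each window, extracts the eight
#' statistics and attaches the ground-truth label derived from the regional
#' annotations (labels depend only on the window position, so all channels of
#' a window share one label).
#'
#' @param rec an [recording()].
#' @param events annotation data frame (may have zero rows).
#' @param cfg a [segmentation_config()].
#' @return data frame with columns `channel` (1-based), `start_sample`,
#'   `X1..X8`, `label`.
#' @export
compute_feature_table <- function(rec, events, cfg = segmentation_config()) {
  stopifnot(inherits(rec, "meg_recording"))
  n <- window_samples(cfg, rec$fs)
  step <- window_step(cfg, rec$fs)
  starts <- segment_starts(ncol(rec$data), n, step)
  labels <- label_segments(starts, n, events)
  per_ch <- lapply(seq_len(rec$channel_count), function(ch) {
    m <- window_matrix(rec$data[ch, ], n, step)
    m <- smooth_columns(m, cfg$median_filter_order)
    f <- extract_features_matrix(m)
    data.frame(channel = ch, start_sample = starts, f, label = labels)
  })
  do.call(rbind, per_ch)
}

#' Write a feature table as TSV
#' @param features data frame from [compute_feature_table()].
#' @param path file path.
#' @export
write_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
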