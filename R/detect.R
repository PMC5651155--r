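#' Score every window of every channel with the evolved formula
#'
#' For each channel and window position: cut the window, median-smooth it,
#' extract the eight statistics and evaluate the formula, yielding one
#' scalar per channel per window.
#'
#' @param rec an [recording()].
#' @param formula a `gp_tree`.
#' @param cfg a [segmentation_config()].
#' @return channels x n_windows numeric matrix of finite scores, with
#'   attributes `starts` (0-based window starts) and `window_samples`.
#' @export
score_segments <- function(rec, formula, cfg = segmentation_config()) {
  stopifnot(inherits(rec, "meg_recording"))
  n <- window_samples(cfg, rec$fs)
  step <- window_step(cfg, rec$fs)
  starts <- segment_starts(ncol(rec$data), n, step)
  scores <- matrix(NA_real_, rec$channel_count, length(starts))
  for (ch in seq_len(rec$channel_count)) {
    m <- window_matrix(rec$data[ch, ], n, step)
    m <- smooth_columns(m, cfg$median_filter_order)
    scores[ch, ] <- evaluate_formula(formula, extract_features_matrix(m))
  }
  attr(scores, "starts") <- starts
  attr(scores, "window_samples") <- n
  scores
}

#' Strict regional majority vote over per-channel decisions
#'
#' A 26-channel regional window is a spike when more than 13 channels vote
#' spike; for the 24-channel occipital regions the same strict-majority rule
#' gives a threshold of more than 12.
#'
#' @param channel_votes logical (or 0/1) vector of per-channel spike votes,
#'   length 24 or 26.
#' @return `"spike"` or `"nonspike"`.
#' @examples
#' vote_region(rep(c(TRUE, FALSE), c(14, 12)))  # spike (14 of 26 > 13)
#' @export
vote_region <- function(channel_votes) {
  len <- length(channel_votes)
  if (!len %in% c(24L, 26L))
    stop("regional vote expects 24 or 26 channels, got ", len, call. = FALSE)
  if (sum(channel_votes) > len %/% 2L) "spike" else "nonspike"
}

#' Regional spike detection
#'
#' Runs the full classification stage on one recording: formula scores per
#' channel and window, per-channel KNN decisions ("1" spike / "0"
#' spike-free), then the strict regional majority vote per window position.
#'
#' @param rec an [recording()].
#' @param formula a `gp_tree`.
#' @param model a [knn_model()] of reference points (shared across patients
#'   and channels: the detector is patient-independent).
#' @param cfg a [segmentation_config()].
#' @param annotations optional annotation data frame; when given, each
#'   window's ground truth is attached via [label_segments()], otherwise
#'   `truth` is `"unknown"`.
#' @return data frame, one row per window: `start_sample`, `end_sample`,
#'   `n_spike_votes`, `decision`, `truth`.
#' @export
detect_spikes <- function(rec, formula, model, cfg = segmentation_config(),
                          annotations = NULL) {
  scores <- score_segments(rec, formula, cfg)
  starts <- attr(scores, "starts")
  n <- attr(scores, "window_samples")
  votes <- matrix(knn_classify(model, as.vector(scores)) == "spike",
                  nrow = nrow(scores))
  counts <- colSums(votes)
  decision <- apply(votes, 2L, vote_region)
  truth <- if (is.null(annotations)) rep("unknown", length(starts))
           else label_segments(starts, n, annotations)
  data.frame(start_sample = starts, end_sample = starts + n,
             n_spike_votes = counts, decision = decision, truth = truth)
}

#' Sensitivity and specificity of regional decisions
#'
#' Sensitivity = 100 * TP / (TP + FN), specificity = 100 * TN / (TN + FP),
#' in percent. A zero denominator yields `NA` (reported as not applicable,
#' never silently 0).
#'
#' @param decisions data frame from [detect_spikes()] (rows may be pooled
#'   across recordings); every `truth` must be known.
#' @return list with `sensitivity`, `specificity` (percent, possibly `NA`)
#'   and `counts` (named integer vector TP, FP, TN, FN).
#' @export
evaluate_detections <- function(decisions) {
  if (any(decisions$truth == "unknown"))
    stop("cannot evaluate decisions with unknown ground truth", call. = FALSE)
  tp <- sum(decisions$decision == "spike" & decisions$truth == "spike")
  fn <- sum(decisions$decision == "nonspike" & decisions$truth == "spike")
  tn <- sum(decisions$decision == "nonspike" & decisions$truth == "nonspike")
  fp <- sum(decisions$decision == "spike" & decisions$truth == "nonspike")
  ratio <- function(num, den) if (den == 0L) NA_real_ else 100 * num / den
  list(sensitivity = ratio(tp, tp + fn),
       specificity = ratio(tn, tn + fp),
       counts = c(TP = tp, FP = fp, TN = tn, FN = fn))
}

#' Merge consecutive positive windows into spike events
#'
#' Optional human-readable post-processing: adjacent spike-positive windows
#' whose starts differ by at most one hop are merged into a single event
#' interval. Not used by [evaluate_detections()], which stays per-window.
#'
#' @param decisions data frame from [detect_spikes()].
#' @param step hop between window starts in samples.
#' @return data frame with columns `start_sample`, `end_sample`,
#'   `n_windows`.
#' @export
merge_detections <- function(decisions, step) {
  pos <- decisions[decisions$decision == "spike", , drop = FALSE]
  if (nrow(pos) == 0L)
    return(data.frame(start_sample = integer(), end_sample = integer(),
                      n_windows = integer()))
  pos <- pos[order(pos$start_sample), ]
  new_run <- c(TRUE, diff(pos$start_sample) > step)
  run <- cumsum(new_run)
  do.call(rbind, lapply(split(pos, run), function(g) {
    data.frame(start_sample = min(g$start_sample),
               end_sample = max(g$end_sample), n_windows = nrow(g))
  }))
}

#' Write per-window detections as TSV
#' @param decisions data frame from [detect_spikes()].
#' @param path file path.
#' @export
write_detections <- function(decisions, path) {
  utils::write.table(decisions, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
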