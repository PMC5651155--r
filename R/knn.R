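#' Scalar K-nearest-neighbour model
#'
#' The classifier operates on the evolved formula's scalar output, so its
#' feature space is one-dimensional and the distance is the absolute
#' difference (all p-norms coincide in 1-D). Reference points are the
#' formula values of preclassified segments, class-balanced by construction.
#'
#' @param values numeric vector of reference scalars.
#' @param labels character vector (`"spike"` / `"nonspike"`), same length;
#'   the model requires equal counts of both classes.
#' @param k neighbour count; the published classification stage uses
#'   k = 100. Clamped to the reference size with a warning so small fixtures
#'   run unchanged.
#' @return a `knn_model`.
#' @export
knn_model <- function(values, labels, k = 100L) {
  if (length(values) == 0L) stop("empty reference set", call. = FALSE)
  if (length(values) != length(labels))
    stop("values and labels differ in length", call. = FALSE)
  if (!all(labels %in% c("spike", "nonspike")))
    stop("labels must be 'spike' or 'nonspike'", call. = FALSE)
  if (sum(labels == "spike") != sum(labels == "nonspike"))
    stop("reference set must be class-balanced", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > length(values)) {
    warning("k = ", k, " exceeds reference size ", length(values),
            "; clamping", call. = FALSE)
    k <- length(values)
  }
  structure(list(values = as.numeric(values), labels = as.character(labels),
                 k = k),
            class = "knn_model")
}

#' Classify scalar queries by majority of the k nearest references
#'
#' Deterministic tie handling: reference points at equal distance are
#' ordered by their insertion order in the model, and an even split of the
#' k votes is resolved by the label of the single nearest reference
#' (data-driven rather than a fixed class bias).
#'
#' @param model a [knn_model()].
#' @param queries numeric vector of formula outputs; must be finite.
#' @return character vector of `"spike"` / `"nonspike"` decisions.
#' @examples
#' m <- knn_model(c(0, 2), c("spike", "nonspike"), k = 2)
#' knn_classify(m, 0.9)  # vote tie 1-1 -> nearest (0, spike)
#' @export
knn_classify <- function(model, queries) {
  stopifnot(inherits(model, "knn_model"))
  if (!all(is.finite(queries))) stop("queries must be finite", call. = FALSE)
  v <- model$values
  spike <- model$labels == "spike"
  k <- model$k
  vapply(queries, function(q) {
    o <- order(abs(q - v))          # stable: distance ties by insertion order
    votes <- spike[o[seq_len(k)]]
    ns <- sum(votes)
    if (2L * ns > k) "spike"
    else if (2L * ns < k) "nonspike"
    else if (spike[o[1L]]) "spike" else "nonspike"
  }, character(1))
}

#' Persist reference points as two-column TSV (value, label)
#' @param model a `knn_model`.
#' @param path file path.
#' @export
write_reference_points <- function(model, path) {
  utils::write.table(data.frame(value = model$values, label = model$labels),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_reference_points
#' @param k neighbour count for the loaded model.
#' @export
read_reference_points <- function(path, k = 100L) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  knn_model(df$value, df$label, k = k)
}
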