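# From attention weights to human-readable rules. Attention values above the
# uniform level 1/l mark "attended" timesteps; one tree explains which
# timesteps get attended, a second explains how attended segments determine
# the class.

#' Threshold an attention vector into attended / none labels
#'
#' Because attention is softmax-normalized over the l timesteps, the natural
#' threshold is the uniform level `1/l`: a timestep is "attended" iff its
#' weight strictly exceeds it. Exactly uniform attention therefore attends
#' nothing.
#'
#' @param a Numeric attention vector (nonnegative, sums to 1).
#' @return A factor of levels `c("none", "attended")`, one per timestep.
#' @export
label_attention <- function(a) {
  a <- as.numeric(a)
  if (any(a < 0) || abs(sum(a) - 1) > 1e-6)
    stop("not an attention vector: entries must be >= 0 and sum to 1",
         call. = FALSE)
  factor(ifelse(a > 1 / length(a), "attended", "none"),
         levels = c("none", "attended"))
}

#' Fit the attention-explanation tree
#'
#' Pools per-timestep feature rows across all series and fits a decision tree
#' separating attended from non-attended timesteps. The top one or two levels
#' are the interpretable product; read them with [tree_report()].
#'
#' @param features A matrix of per-timestep features (rows pooled over the
#'   training set), e.g. stacked [extract_window_features()] outputs.
#' @param labels Factor/character labels per row, `"attended"` or `"none"`
#'   (e.g. concatenated [label_attention()] outputs).
#' @param ... Passed to [fit_surrogate_tree()] (`max_depth`, `min_leaf`, ...).
#' @return A `surrogate_tree`.
#' @export
fit_attention_tree <- function(features, labels, ...) {
  labels <- factor(as.character(labels), levels = c("none", "attended"))
  if (anyNA(labels)) stop("labels must be 'attended' or 'none'", call. = FALSE)
  fit_surrogate_tree(features, labels, ...)
}

#' Attention-weighted average of per-timestep features
#'
#' Each row t is weighted by the attention a_t and the rows summed; since
#' attention sums to one this is a convex combination, so each averaged
#' feature stays within the range of its per-timestep values.
#'
#' @param features Per-timestep feature matrix (l x p).
#' @param a Attention vector of length l.
#' @return A named numeric vector of length p.
#' @export
attention_weighted_features <- function(features, a) {
  a <- as.numeric(a)
  if (length(a) != nrow(features))
    stop("attention length must match feature rows", call. = FALSE)
  v <- as.numeric(crossprod(features, a))
  names(v) <- colnames(features)
  v
}

#' Fit the classification-explanation tree
#'
#' One feature vector per series: the attention-weighted average of the
#' series' per-timestep features (so the tree's rule is dominated by what
#' happens inside attended segments). The tree is then fitted against the
#' series class labels.
#'
#' @param series List of normalized [speed_series()] carrying class labels.
#' @param attentions Matrix (l x n) or list of attention vectors, one per
#'   series.
#' @param windows Window lengths for [extract_window_features()].
#' @param ... Passed to [fit_surrogate_tree()].
#' @return A `surrogate_tree` with levels `c("class0", "class1")`.
#' @export
fit_classification_tree <- function(series, attentions,
                                    windows = c(5L, 11L, 21L), ...) {
  if (is.matrix(attentions))
    attentions <- lapply(seq_len(ncol(attentions)),
                         function(j) attentions[, j])
  stopifnot(length(series) == length(attentions))
  rows <- lapply(seq_along(series), function(i) {
    F <- extract_window_features(series[[i]], windows)
    attention_weighted_features(F, attentions[[i]])
  })
  X <- do.call(rbind, rows)
  y <- vapply(series, function(s) s$class_label, 0L)
  if (length(unique(y)) < 2L)
    stop("degenerate labels: both classes must be present", call. = FALSE)
  fit_surrogate_tree(X, factor(ifelse(y == 1L, "class1", "class0"),
                               levels = c("class0", "class1")), ...)
}

#' Export a per-series attention highlight table
#'
#' The data behind highlighted-speed plots: timestep, speed, attention weight
#' and the attended flag, as tab-separated text.
#'
#' @param s A [speed_series()].
#' @param a Attention vector for the series.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_highlights <- function(s, a, path) {
  stopifnot(inherits(s, "speed_series"), length(a) == length(s$values))
  lab <- label_attention(a)
  utils::write.table(
    data.frame(t = seq_along(s$values), speed = s$values, attention = a,
               attended = as.integer(lab == "attended")),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
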