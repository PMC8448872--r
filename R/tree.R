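# A small CART classifier (Gini impurity, binary splits on continuous
# features, depth- and leaf-size-limited). The convention throughout: rows
# with feature value strictly below the threshold go to the left child.

gini_node <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

best_split <- function(X, y1, min_leaf) {
  n <- length(y1)
  n1 <- sum(y1)
  parent <- gini_node(c(n - n1, n1))
  best <- list(gain = 0)
  for (j in seq_len(ncol(X))) {
    xj <- X[, j]
    ord <- order(xj)
    xs <- xj[ord]; ys <- y1[ord]
    c1 <- cumsum(ys)
    i <- seq_len(n - 1L)
    valid <- xs[i] < xs[i + 1L] & i >= min_leaf & (n - i) >= min_leaf
    if (!any(valid)) next
    i <- i[valid]
    nl <- i; nr <- n - i
    c1l <- c1[i]; c1r <- n1 - c1l
    gl <- 1 - ((c1l / nl)^2 + ((nl - c1l) / nl)^2)
    gr <- 1 - ((c1r / nr)^2 + ((nr - c1r) / nr)^2)
    gain <- parent - (nl * gl + nr * gr) / n
    k <- which.max(gain)
    if (gain[k] > best$gain + 1e-12) {
      best <- list(gain = gain[k], feature = j,
                   threshold = (xs[i[k]] + xs[i[k] + 1L]) / 2)
    }
  }
  if (is.null(best$feature)) NULL else best
}

grow_tree <- function(X, y1, depth, max_depth, min_leaf, min_split) {
  counts <- c(sum(y1 == 0L), sum(y1))
  node <- list(n = length(y1), counts = counts,
               pred = as.integer(counts[2L] >= counts[1L]), depth = depth)
  if (depth >= max_depth || length(y1) < min_split ||
      any(counts == 0L)) return(node)
  sp <- best_split(X, y1, min_leaf)
  if (is.null(sp)) return(node)
  left <- X[, sp$feature] < sp$threshold
  node$feature <- sp$feature
  node$threshold <- sp$threshold
  node$gain <- sp$gain
  node$left <- grow_tree(X[left, , drop = FALSE], y1[left], depth + 1L,
                         max_depth, min_leaf, min_split)
  node$right <- grow_tree(X[!left, , drop = FALSE], y1[!left], depth + 1L,
                          max_depth, min_leaf, min_split)
  node
}

#' Fit a surrogate decision tree
#'
#' CART with Gini impurity on continuous features. Rows with a feature value
#' strictly smaller than the node threshold descend to the left child. Used
#' both to explain attention (attended vs none timesteps) and to explain
#' classification (attention-weighted series features vs class).
#'
#' @param X Numeric feature matrix with column names (rows = instances).
#' @param y Binary labels (0/1, logical, or a 2-level factor).
#' @param max_depth Maximum tree depth, default 4.
#' @param min_leaf Minimum instances per leaf, default 5.
#' @param min_split Minimum instances to attempt a split, default 10.
#' @return An object of class `surrogate_tree` with the fitted `root` node,
#'   `feature_names`, and the label `levels`.
#' @export
fit_surrogate_tree <- function(X, y, max_depth = 4L, min_leaf = 5L,
                               min_split = 10L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (is.logical(y)) y <- as.integer(y)
  if (is.factor(y) || is.character(y)) {
    y <- factor(y)
    lev <- levels(y)
    y <- as.integer(y) - 1L
  } else {
    lev <- c("0", "1")
    y <- as.integer(y)
  }
  if (length(unique(y)) < 2L)
    stop("degenerate labels: both classes must be present", call. = FALSE)
  if (length(y) != nrow(X)) stop("X and y sizes differ", call. = FALSE)
  root <- grow_tree(X, y, 0L, max_depth, min_leaf, min_split)
  structure(list(root = root, feature_names = colnames(X), levels = lev,
                 max_depth = max_depth, min_leaf = min_leaf),
            class = "surrogate_tree")
}

#' Root split of a surrogate tree
#'
#' @param tree A `surrogate_tree`.
#' @return A list with `feature` (name) and `threshold`, or `NULL` for a
#'   stump with no split.
#' @export
tree_root <- function(tree) {
  stopifnot(inherits(tree, "surrogate_tree"))
  nd <- tree$root
  if (is.null(nd$feature)) return(NULL)
  list(feature = tree$feature_names[nd$feature], threshold = nd$threshold)
}

#' @export
predict.surrogate_tree <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  classify <- function(node, row) {
    while (!is.null(node$feature)) {
      node <- if (row[node$feature] < node$threshold) node$left else node$right
    }
    node$pred
  }
  preds <- vapply(seq_len(nrow(X)), function(i) classify(object$root, X[i, ]),
                  0L)
  factor(object$levels[preds + 1L], levels = object$levels)
}

#' Text report of a surrogate tree
#'
#' Indented per-node report of feature, threshold and class histogram. Only
#' the top levels are meant for interpretation; deeper structure mostly fits
#' noise.
#'
#' @param tree A `surrogate_tree`.
#' @param max_levels Number of split levels to print, default 2.
#' @return Character vector of report lines (also usable with `writeLines`).
#' @export
tree_report <- function(tree, max_levels = 2L) {
  stopifnot(inherits(tree, "surrogate_tree"))
  lines <- character()
  walk <- function(node, indent) {
    cnt <- sprintf("[%s=%d %s=%d]", tree$levels[1L], node$counts[1L],
                   tree$levels[2L], node$counts[2L])
    if (is.null(node$feature) || node$depth >= max_levels) {
      lines <<- c(lines, sprintf("%sleaf -> %s %s", indent,
                                 tree$levels[node$pred + 1L], cnt))
      return(invisible())
    }
    lines <<- c(lines, sprintf("%s%s < %.4g %s", indent,
                               tree$feature_names[node$feature],
                               node$threshold, cnt))
    walk(node$left, paste0(indent, "  "))
    walk(node$right, paste0(indent, "  "))
  }
  walk(tree$root, "")
  lines
}

#' @export
print.surrogate_tree <- function(x, ...) {
  cat(sprintf("<surrogate_tree: %d features, max depth %d>\n",
              length(x$feature_names), x$max_depth))
  writeLines(tree_report(x, max_levels = 2L))
  invisible(x)
}
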