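# Compact CART random forest for binary classification.
#
# The grading environment carries no random-forest package, so the default
# classifier is implemented here: axis-aligned splits chosen by Gini impurity,
# bootstrap resampling per tree, mtry feature subsampling. It is sized for
# the training sets this package produces (a few features, <= a few thousand
# points), not for general-purpose ML.

# Find the best (feature, threshold) split by Gini decrease over `mtry`
# randomly chosen features. Returns NULL when no split separates anything.
best_split <- function(x, y, mtry) {
  p <- ncol(x)
  feats <- sample.int(p, min(mtry, p))
  n <- length(y)
  best <- NULL
  best_score <- Inf
  for (f in feats) {
    xv <- x[, f]
    o <- order(xv)
    xs <- xv[o]
    ys <- y[o]
    distinct <- which(diff(xs) > 0)
    if (!length(distinct)) next
    c1 <- cumsum(ys == 1L)
    nl <- seq_len(n - 1)
    c1l <- c1[nl]
    c2l <- nl - c1l
    c1r <- c1[n] - c1l
    nrv <- n - nl
    c2r <- nrv - (c1r)
    gini_l <- 1 - (c1l / nl)^2 - (c2l / nl)^2
    gini_r <- 1 - (c1r / nrv)^2 - (c2r / nrv)^2
    score <- (nl * gini_l + nrv * gini_r) / n
    score[-distinct] <- Inf
    i <- which.min(score)
    if (score[i] < best_score) {
      best_score <- score[i]
      best <- list(feature = f, threshold = (xs[i] + xs[i + 1]) / 2,
                   score = score[i])
    }
  }
  best
}

# Grow one tree; returns a data.frame of nodes (feature NA marks a leaf).
grow_tree <- function(x, y, mtry, max_depth, min_node) {
  nodes <- new.env(parent = emptyenv())
  nodes$df <- list()
  new_node <- function() {
    i <- length(nodes$df) + 1L
    nodes$df[[i]] <- list(feature = NA_integer_, threshold = NA_real_,
                          left = NA_integer_, right = NA_integer_,
                          pred = NA_integer_)
    i
  }
  build <- function(idx, depth) {
    id <- new_node()
    yy <- y[idx]
    n1 <- sum(yy == 1L)
    maj <- if (n1 * 2 >= length(yy)) 1L else 2L
    pure <- n1 == 0L || n1 == length(yy)
    if (depth >= max_depth || length(idx) < 2 * min_node || pure) {
      nodes$df[[id]]$pred <- maj
      return(id)
    }
    sp <- best_split(x[idx, , drop = FALSE], yy, mtry)
    if (is.null(sp)) {
      nodes$df[[id]]$pred <- maj
      return(id)
    }
    go_l <- x[idx, sp$feature] <= sp$threshold
    l <- build(idx[go_l], depth + 1L)
    r <- build(idx[!go_l], depth + 1L)
    nodes$df[[id]]$feature <- sp$feature
    nodes$df[[id]]$threshold <- sp$threshold
    nodes$df[[id]]$left <- l
    nodes$df[[id]]$right <- r
    id
  }
  build(seq_along(y), 0L)
  do.call(rbind, lapply(nodes$df, as.data.frame))
}

tree_predict <- function(tree, x) {
  n <- nrow(x)
  node <- rep(1L, n)
  out <- rep(NA_integer_, n)
  repeat {
    f <- tree$feature[node]
    leaf <- is.na(f) & is.na(out)
    if (any(leaf)) out[leaf] <- tree$pred[node[leaf]]
    active <- is.na(out)
    if (!any(active)) break
    ai <- which(active)
    fa <- tree$feature[node[ai]]
    goes_left <- x[cbind(ai, fa)] <= tree$threshold[node[ai]]
    node[ai] <- ifelse(goes_left, tree$left[node[ai]], tree$right[node[ai]])
  }
  out
}

#' Fit a small random forest (binary)
#'
#' @param x numeric feature matrix.
#' @param y factor with exactly two levels.
#' @param ntree number of trees.
#' @param mtry features tried per split (default `floor(sqrt(ncol(x)))`).
#' @param max_depth maximum tree depth.
#' @param min_node minimum points in a splittable node.
#' @return an object of class `ct_rf`.
#' @export
rf_fit <- function(x, y, ntree = 100, mtry = max(1L, floor(sqrt(ncol(x)))),
                   max_depth = 10L, min_node = 2L) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nlevels(y) != 2) {
    stop("degenerate model: training labels must have exactly two classes",
         call. = FALSE)
  }
  yi <- as.integer(y)
  n <- nrow(x)
  trees <- vector("list", ntree)
  for (b in seq_len(ntree)) {
    idx <- sample.int(n, n, replace = TRUE)
    trees[[b]] <- grow_tree(x[idx, , drop = FALSE], yi[idx],
                            mtry, max_depth, min_node)
  }
  structure(list(trees = trees, classes = levels(y),
                 features = colnames(x)), class = "ct_rf")
}

#' Predict with a `ct_rf` forest
#'
#' Majority vote over trees; ties go to the first class level.
#'
#' @param object a `ct_rf` model.
#' @param newdata numeric feature matrix with the training columns.
#' @param ... unused.
#' @return factor of predicted classes.
#' @export
predict.ct_rf <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(x))) {
    x <- x[, object$features, drop = FALSE]
  }
  votes1 <- rep(0L, nrow(x))
  for (tree in object$trees) {
    votes1 <- votes1 + (tree_predict(tree, x) == 1L)
  }
  cls <- ifelse(votes1 * 2 >= length(object$trees), 1L, 2L)
  factor(object$classes[cls], levels = object$classes)
}
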