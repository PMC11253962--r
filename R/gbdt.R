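#' Fit a single regression tree by greedy variance reduction
#'
#' CART-style regression tree for squared loss: each internal node takes
#' the (feature, threshold) split minimizing the summed within-child
#' squared error; leaf values are the mean of their training targets.
#' Split candidates are midpoints between consecutive sorted unique
#' feature values. Deterministic given input order: cost ties are broken
#' by the lowest feature index, then the lowest threshold.
#'
#' @param x numeric matrix (or data.frame) of features, one row per
#'   sample.
#' @param y numeric response (residuals, in a boosting context).
#' @param max_depth maximum tree depth (0 = single leaf).
#' @param min_samples_leaf minimum samples in each child.
#'
#' @return An object of class `"regression_tree"`: a node table with
#'   columns `feature`, `threshold`, `left`, `right`, `value`, `is_leaf`
#'   (row 1 is the root; `left`/`right` are row indices).
#' @examples
#' tr <- fit_tree(matrix(c(0, 1)), c(0, 10), max_depth = 1)
#' predict(tr, matrix(c(0.2, 0.9)))
#' @export
fit_tree <- function(x, y, max_depth = 3L, min_samples_leaf = 1L) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("features must be numeric", call. = FALSE)
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("need at least one sample and one feature", call. = FALSE)
  if (length(y) != nrow(x))
    stop("length(y) must equal nrow(x)", call. = FALSE)
  stopifnot(max_depth >= 0L, min_samples_leaf >= 1L)

  nodes <- list()
  new_node <- function() {
    nodes[[length(nodes) + 1L]] <<- list(feature = NA_integer_,
                                         threshold = NA_real_,
                                         left = NA_integer_,
                                         right = NA_integer_,
                                         value = NA_real_, is_leaf = TRUE)
    length(nodes)
  }

  build <- function(idx, depth) {
    id <- new_node()
    yi <- y[idx]
    nodes[[id]]$value <<- mean(yi)
    n <- length(idx)
    if (depth >= max_depth || n < 2L * min_samples_leaf ||
        all(yi == yi[1L]))
      return(id)
    best <- best_split(x[idx, , drop = FALSE], yi, min_samples_leaf)
    if (is.null(best)) return(id)
    go_left <- x[idx, best$feature] <= best$threshold
    nodes[[id]]$feature <<- best$feature
    nodes[[id]]$threshold <<- best$threshold
    nodes[[id]]$is_leaf <<- FALSE
    nodes[[id]]$left <<- build(idx[go_left], depth + 1L)
    nodes[[id]]$right <<- build(idx[!go_left], depth + 1L)
    id
  }
  build(seq_len(nrow(x)), 0L)

  tab <- do.call(rbind, lapply(nodes, function(nd)
    data.frame(feature = nd$feature, threshold = nd$threshold,
               left = nd$left, right = nd$right, value = nd$value,
               is_leaf = nd$is_leaf)))
  structure(list(nodes = tab, max_depth = max_depth,
                 min_samples_leaf = min_samples_leaf,
                 n_features = ncol(x)),
            class = "regression_tree")
}

# best (feature, threshold) by total child SSE; NULL when no valid split
# exists. Zero-gain splits are allowed (the node is only a leaf when its
# residuals are constant), so structures like XOR are solvable at depth 2.
# Ties: lowest feature index, then lowest threshold.
best_split <- function(x, y, min_samples_leaf) {
  n <- length(y)
  best <- NULL
  best_cost <- Inf
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j])
    xs <- x[o, j]; ys <- y[o]
    csum <- cumsum(ys); csq <- cumsum(ys^2)
    tot <- csum[n]; totsq <- csq[n]
    i <- seq_len(n - 1L)
    valid <- (xs[i] < xs[i + 1L]) & (i >= min_samples_leaf) &
      ((n - i) >= min_samples_leaf)
    if (!any(valid)) next
    i <- i[valid]
    sse_l <- csq[i] - csum[i]^2 / i
    sse_r <- (totsq - csq[i]) - (tot - csum[i])^2 / (n - i)
    cost <- sse_l + sse_r
    k <- which.min(cost)          # candidates ordered by threshold
    if (cost[k] < best_cost) {
      best_cost <- cost[k]
      best <- list(feature = j,
                   threshold = (xs[i[k]] + xs[i[k] + 1L]) / 2)
    }
  }
  best
}

#' @export
predict.regression_tree <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != object$n_features)
    stop("expected ", object$n_features, " feature(s), got ", ncol(x),
         call. = FALSE)
  tab <- object$nodes
  vapply(seq_len(nrow(x)), function(i) {
    id <- 1L
    while (!tab$is_leaf[id]) {
      id <- if (x[i, tab$feature[id]] <= tab$threshold[id])
        tab$left[id] else tab$right[id]
    }
    tab$value[id]
  }, numeric(1L))
}

#' @export
print.regression_tree <- function(x, ...) {
  cat(sprintf("Regression tree: %d node(s), %d leaf(ves), max depth %d\n",
              nrow(x$nodes), sum(x$nodes$is_leaf), x$max_depth))
  invisible(x)
}

#' Gradient-boosted regression trees for squared loss
#'
#' Builds the additive model \eqn{f_M(x) = f_0 + \nu \sum_{m=1}^M
#' T(x;\Xi_m)} by forward stagewise fitting: starting from the constant
#' \eqn{f_0} (0 by default), iteration m fits a regression tree to the
#' current residuals \eqn{r = y - f_{m-1}(x)} — the negative gradient of
#' the squared loss — and adds it with shrinkage \eqn{\nu}. With
#' \eqn{\nu = 1} this is the literal residual-fitting recursion; the
#' default \eqn{\nu = 0.1} is the usual regularized setting.
#'
#' @param x numeric feature matrix (or data.frame), one row per sample.
#' @param y numeric target (e.g. BIS values).
#' @param n_trees number of boosting iterations M (>= 1).
#' @param shrinkage learning rate \eqn{\nu} in (0, 1].
#' @param max_depth per-tree depth limit.
#' @param min_samples_leaf minimum samples per leaf.
#' @param f0 initial constant; 0 by default.
#'
#' @return An object of class `"gbdt"`: list with `trees`, `shrinkage`,
#'   `f0`, `train_mse` (staged training MSE after each tree,
#'   non-increasing for \eqn{\nu \le 1}), `feature_names`. Methods:
#'   `print`, `summary`, `predict` (with staged `n_trees` argument),
#'   `fitted`, `residuals`.
#' @examples
#' x <- matrix(seq(0, 1, length.out = 50))
#' y <- as.numeric(x > 0.5) * 10
#' fit <- gbdt_fit(x, y, n_trees = 50, shrinkage = 0.3, max_depth = 1)
#' tail(fit$train_mse, 1)
#' @export
gbdt_fit <- function(x, y, n_trees = 100L, shrinkage = 0.1,
                     max_depth = 3L, min_samples_leaf = 1L, f0 = 0) {
  x <- as.matrix(x)
  if (n_trees < 1L) stop("'n_trees' must be >= 1", call. = FALSE)
  if (shrinkage <= 0) stop("'shrinkage' must be > 0", call. = FALSE)
  if (length(y) != nrow(x))
    stop("length(y) must equal nrow(x)", call. = FALSE)

  pred <- rep(f0, length(y))
  trees <- vector("list", n_trees)
  train_mse <- numeric(n_trees)
  for (m in seq_len(n_trees)) {
    r <- y - pred
    tr <- fit_tree(x, r, max_depth = max_depth,
                   min_samples_leaf = min_samples_leaf)
    pred <- pred + shrinkage * predict(tr, x)
    trees[[m]] <- tr
    train_mse[m] <- mean((y - pred)^2)
  }
  structure(list(trees = trees, shrinkage = shrinkage, f0 = f0,
                 train_mse = train_mse,
                 feature_names = colnames(x),
                 fitted_values = pred, y = y),
            class = "gbdt")
}

#' Predict from a boosted ensemble
#'
#' @param object a `"gbdt"` model.
#' @param newdata feature matrix with the same number of columns as the
#'   training data.
#' @param n_trees use only the first `n_trees` trees (staged prediction);
#'   default all. `0` returns the constant `f0`.
#' @param ... unused.
#' @return Numeric predictions.
#' @export
predict.gbdt <- function(object, newdata, n_trees = NULL, ...) {
  x <- as.matrix(newdata)
  M <- length(object$trees)
  if (is.null(n_trees)) n_trees <- M
  if (n_trees > M) stop("ensemble has only ", M, " trees", call. = FALSE)
  pred <- rep(object$f0, nrow(x))
  for (m in seq_len(n_trees))
    pred <- pred + object$shrinkage * predict(object$trees[[m]], x)
  pred
}

#' @export
fitted.gbdt <- function(object, ...) object$fitted_values

#' @export
residuals.gbdt <- function(object, ...) object$y - object$fitted_values

#' @export
print.gbdt <- function(x, ...) {
  cat(sprintf("Gradient-boosted trees: %d trees, shrinkage %.3g, f0 = %g\n",
              length(x$trees), x$shrinkage, x$f0))
  cat(sprintf("  final training MSE: %.6g\n",
              x$train_mse[length(x$train_mse)]))
  invisible(x)
}

#' @export
summary.gbdt <- function(object, ...) {
  cat(sprintf("Boosted ensemble of %d regression trees (shrinkage %.3g)\n",
              length(object$trees), object$shrinkage))
  m <- length(object$train_mse)
  show <- unique(pmax(1L, round(seq(1L, m, length.out = 5L))))
  cat("  staged training MSE:\n")
  for (i in show)
    cat(sprintf("    m = %4d: %.6g\n", i, object$train_mse[i]))
  invisible(object)
}
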