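#' Regression forest with leaf-based posterior weighting
#'
#' Fits an ensemble of regression trees on bootstrap resamples with
#' feature-subsampled splits, for a univariate response (ABC-RF mode) or
#' a multivariate response (distributional mode). Splits maximize the
#' variance reduction summed over standardized response components; with
#' one component this is the usual CART regression criterion. Out-of-bag
#' (OOB) rows are tracked per tree for error estimation and permutation
#' importance, and each tree records the leaf of every training row so
#' that query points can be turned into posterior weights over training
#' rows ([forest_weights()]).
#'
#' @param X Numeric covariate matrix (rows = training simulations).
#' @param Y Numeric response vector or matrix (1 or more columns).
#' @param num_trees Number of trees. Default 500.
#' @param min_leaf Nodes of this size or smaller are not split. Default 5.
#' @param mtry Features tried per split. Default `ceiling(ncol(X)/3)`.
#' @param seed Optional integer seed.
#' @return An object of class `bd_forest`.
#' @examples
#' X <- matrix(rnorm(600), 200, 3)
#' y <- X[, 1] + rnorm(200, sd = 0.1)
#' fr <- bd_forest(X, y, num_trees = 50, seed = 1)
#' @export
bd_forest <- function(X, Y, num_trees = 500, min_leaf = 5,
                      mtry = ceiling(ncol(X) / 3), seed = NULL) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  storage.mode(X) <- "double"
  storage.mode(Y) <- "double"
  R <- nrow(X)
  if (nrow(Y) != R) stop("X and Y must have the same number of rows",
                         call. = FALSE)
  if (num_trees < 1) stop("`num_trees` must be >= 1", call. = FALSE)
  y_scale <- apply(Y, 2, sd)
  if (any(y_scale == 0)) {
    stop("degenerate response: a component has zero variance", call. = FALSE)
  }
  y_center <- colMeans(Y)
  Ys <- sweep(sweep(Y, 2, y_center), 2, y_scale, "/")
  if (!is.null(seed)) set.seed(seed)
  mtry <- max(1L, min(as.integer(mtry), ncol(X)))
  trees <- vector("list", num_trees)
  train_leaf <- matrix(0L, R, num_trees)
  inbag <- matrix(0L, R, num_trees)
  for (b in seq_len(num_trees)) {
    boot <- sample.int(R, R, replace = TRUE)
    tr <- cpp_build_tree(X, Ys, boot - 1L, mtry, as.integer(min_leaf))
    trees[[b]] <- tr
    train_leaf[, b] <- cpp_tree_leaves(tr$split_var, tr$split_val,
                                       tr$left, tr$right, X)
    inbag[, b] <- tabulate(boot, nbins = R)
  }
  structure(list(trees = trees, train_leaf = train_leaf, inbag = inbag,
                 X = X, Ys = Ys, y_center = y_center, y_scale = y_scale,
                 num_trees = num_trees, min_leaf = min_leaf, mtry = mtry,
                 feature_names = colnames(X),
                 response_names = colnames(Y)),
            class = "bd_forest")
}

#' @export
print.bd_forest <- function(x, ...) {
  cat(sprintf(
    "Regression forest: %d trees, %d x %d covariates, %d response component(s)\n",
    x$num_trees, nrow(x$X), ncol(x$X), ncol(x$Ys)))
  invisible(x)
}

# per-tree leaf means on the standardized scale (list of matrices
# indexed by leaf id + 1)
tree_leaf_means <- function(forest, b) {
  lt <- forest$train_leaf[, b]
  ib <- forest$inbag[, b]
  sel <- ib > 0
  num <- rowsum((forest$Ys * ib)[sel, , drop = FALSE], lt[sel])
  den <- rowsum(ib[sel], lt[sel])
  list(means = num / as.vector(den),
       leaves = as.integer(rownames(num)))
}

#' Posterior weights over training rows for query covariates
#'
#' The weight of training row `i` at query `x` is the average over trees
#' of the indicator that `i` falls in the leaf containing `x`, divided
#' by that leaf's size (number of training rows in it). Weights are
#' nonnegative and sum to 1; in distributional mode they equip the joint
#' empirical law of the responses.
#'
#' @param forest A [bd_forest()].
#' @param newdata Numeric vector (one query) or matrix (one query per
#'   row) of covariates.
#' @return A matrix of weights, one column per query row.
#' @export
forest_weights <- function(forest, newdata) {
  Q <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else
    as.matrix(newdata)
  if (ncol(Q) != ncol(forest$X)) {
    stop(sprintf("query has %d covariates; forest expects %d",
                 ncol(Q), ncol(forest$X)), call. = FALSE)
  }
  storage.mode(Q) <- "double"
  R <- nrow(forest$X)
  W <- matrix(0, R, nrow(Q))
  for (b in seq_len(forest$num_trees)) {
    tr <- forest$trees[[b]]
    lt <- forest$train_leaf[, b]
    qleaf <- cpp_tree_leaves(tr$split_var, tr$split_val, tr$left, tr$right, Q)
    for (iq in seq_len(nrow(Q))) {
      sel <- which(lt == qleaf[iq])
      W[sel, iq] <- W[sel, iq] + 1 / length(sel)
    }
  }
  W / forest$num_trees
}

#' Out-of-bag predictions of a regression forest
#'
#' Mean response (original scale) predicted for each training row using
#' only the trees in which the row is out of bag.
#'
#' @param forest A [bd_forest()].
#' @param num_trees Use only the first `num_trees` trees (default all),
#'   e.g. to trace the OOB error as the ensemble grows.
#' @return Matrix (rows x response components); `NA` for rows in the bag
#'   of every tree used.
#' @export
oob_predict <- function(forest, num_trees = forest$num_trees) {
  R <- nrow(forest$X)
  q <- ncol(forest$Ys)
  acc <- matrix(0, R, q)
  cnt <- integer(R)
  for (b in seq_len(num_trees)) {
    lm <- tree_leaf_means(forest, b)
    oob <- which(forest$inbag[, b] == 0L)
    idx <- match(forest$train_leaf[oob, b], lm$leaves)
    ok <- !is.na(idx)
    acc[oob[ok], ] <- acc[oob[ok], ] + lm$means[idx[ok], , drop = FALSE]
    cnt[oob[ok]] <- cnt[oob[ok]] + 1L
  }
  pred <- acc / cnt
  pred[cnt == 0L, ] <- NA_real_
  sweep(sweep(pred, 2, forest$y_scale, "*"), 2, forest$y_center, "+")
}

#' Out-of-bag mean squared error
#'
#' @param forest A [bd_forest()].
#' @param num_trees Use only the first `num_trees` trees.
#' @return MSE on the standardized response scale, summed over
#'   components.
#' @export
oob_error <- function(forest, num_trees = forest$num_trees) {
  pred <- oob_predict(forest, num_trees)
  preds <- sweep(sweep(pred, 2, forest$y_center), 2, forest$y_scale, "/")
  ok <- stats::complete.cases(preds)
  mean(rowSums((preds[ok, , drop = FALSE] -
                  forest$Ys[ok, , drop = FALSE])^2))
}

#' Permutation variable importance
#'
#' For each covariate, the OOB mean squared error increase (standardized
#' response scale, summed over components) when that covariate is
#' permuted among each tree's OOB rows, averaged over trees. Unused
#' covariates score 0.
#'
#' @param forest A [bd_forest()].
#' @param seed Optional integer seed for the permutations.
#' @return Named numeric vector of importance scores, sorted decreasing.
#' @export
forest_importance <- function(forest, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- ncol(forest$X)
  imp <- numeric(d)
  for (b in seq_len(forest$num_trees)) {
    tr <- forest$trees[[b]]
    lm <- tree_leaf_means(forest, b)
    oob <- which(forest$inbag[, b] == 0L)
    if (length(oob) < 2L) next
    Yo <- forest$Ys[oob, , drop = FALSE]
    base_idx <- match(forest$train_leaf[oob, b], lm$leaves)
    mse0 <- node_mse(lm, base_idx, Yo)
    used <- unique(tr$split_var[tr$split_var >= 0]) + 1L
    Xo <- forest$X[oob, , drop = FALSE]
    for (f in used) {
      Xp <- Xo
      Xp[, f] <- Xo[sample.int(length(oob)), f]
      pl <- cpp_tree_leaves(tr$split_var, tr$split_val, tr$left, tr$right, Xp)
      imp[f] <- imp[f] + (node_mse(lm, match(pl, lm$leaves), Yo) - mse0)
    }
  }
  imp <- imp / forest$num_trees
  names(imp) <- forest$feature_names %||% paste0("x", seq_len(d))
  sort(imp, decreasing = TRUE)
}

node_mse <- function(lm, idx, Yo) {
  ok <- !is.na(idx)
  pred <- lm$means[idx[ok], , drop = FALSE]
  mean(rowSums((pred - Yo[ok, , drop = FALSE])^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
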