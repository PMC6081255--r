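# Shallow random forest: bootstrap-sampled, feature-subsampled binary
# decision trees ("ten classification trees with three layers"), averaged to
# a probability score. Implemented natively so the tree structure is
# inspectable and seeds are portable.

gini_impurity <- function(n_pos, n_tot) {
  p <- n_pos / n_tot
  2 * p * (1 - p)
}

# Best split for one feature: returns c(gain, threshold) or NULL.
best_split_feature <- function(x, y, min_leaf) {
  o <- order(x, method = "radix")
  xs <- x[o]; ys <- y[o]
  n <- length(x)
  cum_pos <- cumsum(ys)
  tot_pos <- cum_pos[n]
  parent <- gini_impurity(tot_pos, n)
  # split after position k: left = 1..k; only between distinct values
  k <- seq_len(n - 1)
  valid <- xs[k] < xs[k + 1] & k >= min_leaf & (n - k) >= min_leaf
  if (!any(valid)) return(NULL)
  k <- k[valid]
  gl <- gini_impurity(cum_pos[k], k)
  gr <- gini_impurity(tot_pos - cum_pos[k], n - k)
  gain <- parent - (k / n) * gl - ((n - k) / n) * gr
  best <- which(gain == max(gain))[1]          # lowest threshold on ties
  c(gain = unname(gain[best]),
    threshold = unname(xs[k[best]] + xs[k[best] + 1]) / 2)
}

build_tree <- function(X, y, depth, max_depth, mtry, min_leaf,
                       always_try = integer(0)) {
  n <- length(y)
  prob <- mean(y)
  if (depth >= max_depth || n < 2 * min_leaf || prob == 0 || prob == 1) {
    return(list(leaf = TRUE, prob = prob, n = n))
  }
  d <- ncol(X)
  feats <- sort(union(sample.int(d, min(mtry, d)), always_try))
  splits <- lapply(feats, function(f) best_split_feature(X[, f], y, min_leaf))
  gains <- vapply(splits, function(s) if (is.null(s)) -Inf else s["gain"], 0)
  if (all(gains <= 0)) return(list(leaf = TRUE, prob = prob, n = n))
  b <- which(gains == max(gains))[1]           # lowest feature index on ties
  f <- feats[b]; thr <- splits[[b]]["threshold"]
  left <- X[, f] < thr
  # guard against floating-point midpoints that fail to separate the node
  if (!any(left) || all(left)) return(list(leaf = TRUE, prob = prob, n = n))
  list(leaf = FALSE, feature = colnames(X)[f], threshold = unname(thr), n = n,
       left = build_tree(X[left, , drop = FALSE], y[left],
                         depth + 1, max_depth, mtry, min_leaf, always_try),
       right = build_tree(X[!left, , drop = FALSE], y[!left],
                          depth + 1, max_depth, mtry, min_leaf, always_try))
}

#' Fit the shallow random forest
#'
#' Each tree is trained on a bootstrap resample of the patients; at every
#' node the best Gini-impurity split is searched over a random subset of
#' ceiling(sqrt(d)) features. Growth stops at `max_depth` (3 "layers" by
#' default: root plus two internal levels), node purity, or minimum node
#' size. Ties in the best split are broken toward the lowest feature index,
#' then the lowest threshold, so a fit is bit-reproducible from its seed.
#'
#' @param features data.frame (or matrix) of numeric features.
#' @param labels Binary labels (both classes must be present).
#' @param n_trees Number of trees (default 10).
#' @param max_depth Maximum depth (default 3).
#' @param min_leaf Minimum samples in a leaf (default 2).
#' @param mtry Features tried per split; default ceiling(sqrt(d)).
#' @param always_try Names of features added to every split's candidate
#'   subset (used by the combined model so a handful of conventional markers
#'   is not diluted among the radiomic features).
#' @param seed Integer seed.
#' @return An object of class `forest_model`.
#' @export
fit_forest <- function(features, labels, n_trees = 10L, max_depth = 3L,
                       min_leaf = 2L, mtry = NULL, always_try = character(0),
                       seed = 1L) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  rownames(X) <- NULL
  y <- as_binary_labels(labels)
  if (sum(y) == 0 || sum(!y) == 0) {
    stop("both classes must be present to fit the forest", call. = FALSE)
  }
  if (ncol(X) < 1L) stop("at least one feature required", call. = FALSE)
  if (is.null(mtry)) mtry <- ceiling(sqrt(ncol(X)))
  always_idx <- match(always_try, colnames(X))
  if (anyNA(always_idx)) stop("always_try features not in data", call. = FALSE)
  with_rng(seed, {
    trees <- lapply(seq_len(n_trees), function(t) {
      idx <- sample.int(nrow(X), nrow(X), replace = TRUE)
      build_tree(X[idx, , drop = FALSE], y[idx], 0L, max_depth, mtry,
                 min_leaf, always_idx)
    })
    structure(list(trees = trees, n_trees = n_trees, max_depth = max_depth,
                   min_leaf = min_leaf, mtry = mtry, seed = seed,
                   feature_names = colnames(X)),
              class = "forest_model")
  })
}

predict_tree <- function(node, X) {
  if (node$leaf) return(rep(node$prob, nrow(X)))
  out <- numeric(nrow(X))
  left <- X[, node$feature] < node$threshold
  if (any(left)) out[left] <- predict_tree(node$left, X[left, , drop = FALSE])
  if (any(!left)) out[!left] <- predict_tree(node$right, X[!left, , drop = FALSE])
  out
}

#' Forest probability score
#'
#' Mean of the per-tree leaf class-1 probabilities (default), or of hard
#' votes when `vote = "majority"`.
#'
#' @param model A `forest_model`.
#' @param features data.frame/matrix containing at least the training
#'   features (matched by name; extra columns ignored).
#' @param vote `"probability"` (leaf probability averaging, default) or
#'   `"majority"` (each tree votes 0/1 at probability 0.5).
#' @return Numeric vector of per-patient scores in \[0, 1\].
#' @export
predict_proba <- function(model, features, vote = c("probability", "majority")) {
  vote <- match.arg(vote)
  X <- as.matrix(as.data.frame(features))
  missing <- setdiff(model$feature_names, colnames(X))
  if (length(missing)) {
    stop("features missing from input: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  X <- X[, model$feature_names, drop = FALSE]
  storage.mode(X) <- "double"
  per_tree <- vapply(model$trees, function(tr) predict_tree(tr, X),
                     numeric(nrow(X)))
  if (is.null(dim(per_tree))) per_tree <- matrix(per_tree, nrow = 1L)
  if (vote == "majority") per_tree <- (per_tree >= 0.5) * 1
  rowMeans(per_tree)
}

#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf("<forest_model> %d trees, depth <= %d, mtry %d, %d features\n",
              x$n_trees, x$max_depth, x$mtry, length(x$feature_names)))
  invisible(x)
}

#' Serialise a forest to JSON (full tree structure)
#'
#' @param model A `forest_model`.
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
forest_to_json <- function(model, path = NULL) {
  js <- jsonlite::toJSON(unclass(model), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
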