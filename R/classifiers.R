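## The four classifier families on tf-idf vectors.
##
## None of the usual CRAN machinery (e1071, rpart, randomForest) is part of
## this package's dependency footprint, so the four models are implemented
## here directly:
##   svm           one-vs-rest linear SVM, squared-hinge (L2) loss, C = 1,
##                 fitted by BFGS on the convex primal objective;
##   naive_bayes   multinomial naive Bayes with Laplace smoothing alpha = 1;
##   decision_tree CART-style binary tree, Gini impurity, grown to purity;
##   random_forest bagged Gini trees with sqrt(p) feature sampling.
## All fits are deterministic given the seed.

CLASSIFIERS <- c("svm", "naive_bayes", "decision_tree", "random_forest")

#' Fit a cuisine classifier on a document-term matrix
#'
#' @param x numeric matrix (documents x terms), e.g. the tf-idf matrix
#'   from [build_tfidf()].
#' @param y factor or character vector of class labels, length `nrow(x)`.
#' @param method one of `"svm"`, `"naive_bayes"`, `"decision_tree"`,
#'   `"random_forest"`.
#' @param seed integer seed for any randomized component (forest
#'   bootstraps/feature sampling); ignored by deterministic fits.
#' @param control named list of hyperparameters: `cost` (SVM C, default 1),
#'   `alpha` (NB smoothing, default 1), `max_depth` (trees, default 30),
#'   `min_n` (minimum node size to split, default 2), `ntree` (forest size,
#'   default 100), `mtry` (features per node, default `floor(sqrt(p))`).
#' @return a `cuisine_classifier` object for [predict_classifier()].
#' @export
fit_classifier <- function(x, y, method = CLASSIFIERS, seed = 42,
                           control = list()) {
  method <- match.arg(method)
  y <- as.character(y)
  classes <- sort(unique(y))
  fit <- switch(method,
    svm = fit_svm_ovr(x, y, classes, cost = control$cost %||% 1),
    naive_bayes = fit_multinomial_nb(x, y, classes,
                                     alpha = control$alpha %||% 1),
    decision_tree = {
      set.seed(derive_seed(seed, 1))
      fit_gini_tree(x, match(y, classes),
                    n_class = length(classes), mtry = ncol(x),
                    max_depth = control$max_depth %||% 30,
                    min_n = control$min_n %||% 2)
    },
    random_forest = fit_forest(x, match(y, classes), length(classes),
                               seed = seed,
                               ntree = control$ntree %||% 100,
                               mtry = control$mtry %||% max(1, floor(sqrt(ncol(x)))),
                               max_depth = control$max_depth %||% 30,
                               min_n = control$min_n %||% 2))
  structure(list(method = method, classes = classes, fit = fit,
                 majority = classes[which.max(table(factor(y, classes)))]),
            class = "cuisine_classifier")
}

#' Predict classes for new documents
#'
#' @param object a `cuisine_classifier` from [fit_classifier()].
#' @param newx matrix in the same term space as the training matrix.
#' @return character vector of predicted class labels. Documents whose
#'   vector is all zero (no vocabulary ingredient) receive the training
#'   majority class.
#' @export
predict_classifier <- function(object, newx) {
  scores <- switch(object$method,
    svm = newx %*% object$fit$W + rep(1, nrow(newx)) %o% object$fit$b,
    naive_bayes = newx %*% object$fit$log_theta +
      rep(1, nrow(newx)) %o% object$fit$log_prior,
    decision_tree = tree_votes(object$fit, newx, length(object$classes)),
    random_forest = forest_votes(object$fit, newx, length(object$classes)))
  pred <- object$classes[max.col(scores, ties.method = "first")]
  empty <- rowSums(newx != 0) == 0
  pred[empty] <- object$majority
  pred
}

## ---- linear SVM (one-vs-rest, squared hinge, BFGS on the primal) --------

fit_svm_ovr <- function(x, y, classes, cost = 1) {
  p <- ncol(x); n <- nrow(x)
  W <- matrix(0, p, length(classes), dimnames = list(colnames(x), classes))
  b <- setNames(numeric(length(classes)), classes)
  for (c_idx in seq_along(classes)) {
    yb <- ifelse(y == classes[c_idx], 1, -1)
    obj <- function(th) {
      w <- th[1:p]; b0 <- th[p + 1]
      m <- pmax(0, 1 - yb * (x %*% w + b0))
      0.5 * sum(w^2) + cost * sum(m^2)
    }
    grad <- function(th) {
      w <- th[1:p]; b0 <- th[p + 1]
      m <- pmax(0, 1 - yb * (drop(x %*% w) + b0))
      gw <- w - 2 * cost * drop(crossprod(x, yb * m))
      gb <- -2 * cost * sum(yb * m)
      c(gw, gb)
    }
    opt <- stats::optim(numeric(p + 1), obj, grad, method = "BFGS",
                        control = list(maxit = 200, reltol = 1e-10))
    W[, c_idx] <- opt$par[1:p]
    b[c_idx] <- opt$par[p + 1]
  }
  list(W = W, b = b)
}

## ---- multinomial naive Bayes --------------------------------------------

fit_multinomial_nb <- function(x, y, classes, alpha = 1) {
  p <- ncol(x)
  log_theta <- matrix(0, p, length(classes),
                      dimnames = list(colnames(x), classes))
  log_prior <- setNames(numeric(length(classes)), classes)
  for (c_idx in seq_along(classes)) {
    xc <- x[y == classes[c_idx], , drop = FALSE]
    counts <- colSums(xc) + alpha
    log_theta[, c_idx] <- log(counts / sum(counts))
    log_prior[c_idx] <- log(nrow(xc) / nrow(x))
  }
  list(log_theta = log_theta, log_prior = log_prior)
}

## ---- Gini decision tree --------------------------------------------------

## flat node store: lists feature, threshold, left, right, leaf class.
## returns index of the created node.
grow_node <- function(env, x, y, idx, n_class, mtry, max_depth, min_n, depth) {
  counts <- tabulate(y[idx], n_class)
  node_id <- env$n_nodes + 1L
  env$n_nodes <- node_id
  majority <- which.max(counts) # ties: lowest class index
  make_leaf <- function() {
    env$nodes[[node_id]] <- list(leaf = TRUE, class = majority)
    node_id
  }
  n <- length(idx)
  if (sum(counts > 0) <= 1 || n < min_n || depth >= max_depth)
    return(make_leaf())
  feats <- if (mtry >= ncol(x)) seq_len(ncol(x)) else
    sort(sample.int(ncol(x), mtry))
  parent_gini <- 1 - sum((counts / n)^2)
  best <- list(gain = 1e-12, feature = NA_integer_, threshold = NA_real_)
  for (f in feats) {
    v <- x[idx, f]
    ord <- order(v)
    vs <- v[ord]; ys <- y[idx][ord]
    cut_pos <- which(diff(vs) > 0) # split between distinct values
    if (!length(cut_pos)) next
    onehot <- matrix(0L, n, n_class); onehot[cbind(seq_len(n), ys)] <- 1L
    cum <- apply(onehot, 2, cumsum)
    nl <- cut_pos; nr <- n - nl
    left_counts <- cum[cut_pos, , drop = FALSE]
    right_counts <- rep(counts, each = length(cut_pos)) - left_counts
    gl <- 1 - rowSums((left_counts / nl)^2)
    gr <- 1 - rowSums((right_counts / nr)^2)
    gain <- parent_gini - (nl * gl + nr * gr) / n
    k <- which.max(gain)
    if (gain[k] > best$gain) {
      best <- list(gain = gain[k], feature = f,
                   threshold = (vs[cut_pos[k]] + vs[cut_pos[k] + 1]) / 2)
    }
  }
  if (is.na(best$feature)) return(make_leaf())
  go_left <- x[idx, best$feature] <= best$threshold
  env$nodes[[node_id]] <- list(leaf = FALSE) # reserve slot before recursion
  left <- grow_node(env, x, y, idx[go_left], n_class, mtry, max_depth,
                    min_n, depth + 1)
  right <- grow_node(env, x, y, idx[!go_left], n_class, mtry, max_depth,
                     min_n, depth + 1)
  env$nodes[[node_id]] <- list(leaf = FALSE, feature = best$feature,
                               threshold = best$threshold,
                               left = left, right = right)
  node_id
}

fit_gini_tree <- function(x, y, n_class, mtry, max_depth, min_n) {
  env <- new.env(parent = emptyenv())
  env$nodes <- list(); env$n_nodes <- 0L
  grow_node(env, x, y, seq_len(nrow(x)), n_class, mtry, max_depth, min_n, 0)
  list(nodes = env$nodes, n_class = n_class)
}

predict_tree_idx <- function(tree, newx) {
  out <- integer(nrow(newx))
  for (i in seq_len(nrow(newx))) {
    node <- tree$nodes[[1]]
    while (!node$leaf) {
      node <- tree$nodes[[
        if (newx[i, node$feature] <= node$threshold) node$left else node$right]]
    }
    out[i] <- node$class
  }
  out
}

tree_votes <- function(tree, newx, n_class) {
  idx <- predict_tree_idx(tree, newx)
  votes <- matrix(0, nrow(newx), n_class)
  votes[cbind(seq_len(nrow(newx)), idx)] <- 1
  votes
}

## ---- bagged forest --------------------------------------------------------

fit_forest <- function(x, y, n_class, seed, ntree, mtry, max_depth, min_n) {
  set.seed(derive_seed(seed, 2))
  trees <- vector("list", ntree)
  n <- nrow(x)
  for (t in seq_len(ntree)) {
    boot <- sample.int(n, n, replace = TRUE)
    trees[[t]] <- fit_gini_tree(x[boot, , drop = FALSE], y[boot], n_class,
                                mtry, max_depth, min_n)
  }
  list(trees = trees, n_class = n_class)
}

forest_votes <- function(forest, newx, n_class) {
  votes <- matrix(0, nrow(newx), n_class)
  for (tree in forest$trees) {
    idx <- predict_tree_idx(tree, newx)
    votes[cbind(seq_len(nrow(newx)), idx)] <- votes[cbind(seq_len(nrow(newx)), idx)] + 1
  }
  votes
}
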