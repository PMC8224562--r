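## Stratified k-fold cross-validation of cuisine classifiers, with metrics
## computed from the pooled out-of-fold confusion matrix. The tf-idf
## vocabulary and idf weights are refit on each training fold so no test
## information leaks into the representation.

#' Per-class and macro metrics from a confusion matrix
#'
#' Rows are true classes, columns predicted. Precision of class c is
#' `cm[c,c] / colsum(c)`, recall `cm[c,c] / rowsum(c)`, F1 their harmonic
#' mean; macro metrics are the unweighted class means. A zero denominator
#' yields 0 with a warning.
#'
#' @param cm square non-negative count matrix with matching dimnames.
#' @return list with `per_class` (data frame `class`, `precision`,
#'   `recall`, `f1`, `support`) and `macro` (named numeric).
#' @export
metrics_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm))
    stop_rm("confusion matrix must be square", class = "recipemine_cm_error")
  diag_v <- diag(cm); rs <- rowSums(cm); cs <- colSums(cm)
  if (any(rs == 0) || any(cs == 0))
    warn_rm("class with zero row/column sum: metric reported as 0",
            class = "recipemine_degenerate_class")
  precision <- ifelse(cs > 0, diag_v / cs, 0)
  recall <- ifelse(rs > 0, diag_v / rs, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- data.frame(class = rownames(cm) %||% as.character(seq_len(nrow(cm))),
                          precision = precision, recall = recall, f1 = f1,
                          support = rs, stringsAsFactors = FALSE)
  rownames(per_class) <- NULL
  macro <- c(precision = mean(precision), recall = mean(recall), f1 = mean(f1))
  list(per_class = per_class, macro = macro)
}

## stratified fold ids (1..folds) for labels, deterministic under seed
stratified_folds <- function(labels, folds, seed) {
  fold_id <- integer(length(labels))
  set.seed(derive_seed(seed, 3))
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    if (length(idx) < folds)
      stop_rm("class '%s' has %d recipes, fewer than %d folds",
              cl, length(idx), folds, class = "recipemine_small_class")
    fold_id[idx] <- (seq_along(idx) - 1L) %% folds + 1L
    fold_id[idx] <- fold_id[idx][sample.int(length(idx))]
  }
  fold_id
}

#' Cross-validate a classifier on ingredient documents
#'
#' Stratified k-fold cross-validation. Within each fold the tf-idf model
#' is fit on the training recipes only, the held-out recipes are
#' transformed into that space, and out-of-fold predictions are pooled
#' into a single confusion matrix from which all metrics derive.
#'
#' @param docs a labeled `recipe_corpus` or list of canonical-ingredient
#'   character vectors.
#' @param labels class labels (taken from the corpus when `docs` is one).
#' @param classifier one of `"svm"`, `"naive_bayes"`, `"decision_tree"`,
#'   `"random_forest"`.
#' @param folds number of folds (default 10).
#' @param seed seed controlling fold assignment and any classifier
#'   randomness.
#' @param control hyperparameters, see [fit_classifier()].
#' @param holdout if `TRUE`, evaluate a single stratified 80/20 train/test
#'   split instead of k-fold CV (an alternative evaluation protocol; the
#'   k-fold report remains the default of record).
#' @return a `classification_report`: list with `classifier`, `folds`,
#'   `per_class`, `macro`, `confusion`.
#' @export
crossvalidate <- function(docs, labels = NULL, classifier = CLASSIFIERS,
                          folds = 10, seed = 42, control = list(),
                          holdout = FALSE) {
  classifier <- match.arg(classifier)
  if (inherits(docs, "recipe_corpus")) {
    labels <- labels %||% corpus_labels(docs)
    docs <- recipe_ingredient_sets(docs)
  }
  stopifnot(length(labels) == length(docs))
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (holdout) {
    fold_id <- ifelse(stratified_folds(labels, 5, seed) == 1L, 1L, 2L)
    eval_folds <- 1L
  } else {
    fold_id <- stratified_folds(labels, folds, seed)
    eval_folds <- seq_len(folds)
  }
  cm <- matrix(0L, length(classes), length(classes),
               dimnames = list(true = classes, predicted = classes))
  for (f in eval_folds) {
    tr <- fold_id != f; te <- fold_id == f
    tf <- build_tfidf(docs[tr])
    model <- fit_classifier(tf$dtm, labels[tr], classifier,
                            seed = derive_seed(seed, 100 + f), control = control)
    pred <- predict_classifier(model, tfidf_transform(tf$model, docs[te]))
    for (k in seq_along(pred))
      cm[labels[te][k], pred[k]] <- cm[labels[te][k], pred[k]] + 1L
  }
  mt <- metrics_from_confusion(cm)
  structure(list(classifier = classifier,
                 folds = if (holdout) 1L else folds,
                 per_class = mt$per_class, macro = mt$macro, confusion = cm),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification report> %s, %d fold(s)\n", x$classifier, x$folds))
  print(x$per_class, digits = 3)
  cat(sprintf("macro: precision %.3f  recall %.3f  F1 %.3f\n",
              x$macro["precision"], x$macro["recall"], x$macro["f1"]))
  invisible(x)
}

#' @export
as.data.frame.classification_report <- function(x, ...) {
  rbind(x$per_class,
        data.frame(class = "macro-average", precision = x$macro[["precision"]],
                   recall = x$macro[["recall"]], f1 = x$macro[["f1"]],
                   support = sum(x$per_class$support)))
}

#' Train on all labeled recipes and label the unknown ones
#'
#' @param labeled a labeled `recipe_corpus` (or list of ingredient sets
#'   with `labels`).
#' @param unknown a `recipe_corpus` of non-classified recipes (or list of
#'   ingredient sets).
#' @param labels labels for `labeled` when it is a plain list.
#' @param classifier classifier family (the linear SVM, the best performer
#'   in cross-validation, is the default).
#' @param seed,control see [fit_classifier()].
#' @return list with `labels` (named character, one per unknown recipe),
#'   `counts` (per-category table summing to the number of unknowns) and
#'   `flagged` (ids of recipes with no vocabulary ingredient, labeled by
#'   majority class).
#' @export
predict_unknown <- function(labeled, unknown, labels = NULL,
                            classifier = "svm", seed = 42, control = list()) {
  if (inherits(labeled, "recipe_corpus")) {
    labels <- labels %||% corpus_labels(labeled)
    labeled <- recipe_ingredient_sets(labeled)
  }
  if (inherits(unknown, "recipe_corpus")) unknown <- recipe_ingredient_sets(unknown)
  if (!length(unknown))
    return(list(labels = setNames(character(), character()),
                counts = table(factor(character(), sort(unique(as.character(labels))))),
                flagged = character()))
  tf <- build_tfidf(labeled)
  model <- fit_classifier(tf$dtm, labels, classifier, seed = seed,
                          control = control)
  newx <- tfidf_transform(tf$model, unknown)
  pred <- predict_classifier(model, newx)
  flagged <- names(unknown)[rowSums(newx != 0) == 0] %||% character()
  if (length(flagged))
    warn_rm("%d unknown recipe(s) had no vocabulary ingredient; assigned majority class",
            length(flagged), class = "recipemine_empty_doc")
  names(pred) <- names(unknown)
  list(labels = pred,
       counts = table(factor(pred, levels = model$classes)),
       flagged = flagged)
}
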