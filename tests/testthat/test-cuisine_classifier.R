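test_that("build_tfidf: binary tf, smoothed idf, L2 rows", {
  docs <- list(d1 = c("salt", "rice"), d2 = c("salt"))
  tf <- build_tfidf(docs)
  ## term in both docs: idf = ln(3/3) + 1 = 1; in one: ln(3/2) + 1
  expect_equal(tf$model$idf[["salt"]], 1)
  expect_equal(tf$model$idf[["rice"]], log(3 / 2) + 1)
  expect_equal(unname(rowSums(tf$dtm^2)), c(1, 1)) # L2-normalized
  ## single-ingredient doc is a unit vector
  expect_equal(unname(tf$dtm["d2", ]), c(0, 1))
  ## duplicated recipes give identical rows
  tf2 <- build_tfidf(list(a = c("x", "y"), b = c("x", "y")))
  expect_equal(unname(tf2$dtm[1, ]), unname(tf2$dtm[2, ]))
  expect_error(build_tfidf(list(character())), class = "recipemine_empty_vocab")
  ## out-of-vocabulary terms are dropped at transform time
  m <- tfidf_transform(tf$model, list(c("rice", "dragonfruit")))
  expect_equal(unname(m[1, "salt"]), 0)
  expect_equal(unname(m[1, "rice"]), 1)
})

test_that("metrics_from_confusion matches hand arithmetic", {
  cm <- matrix(c(8, 3, 2, 7), 2, dimnames = list(c("a", "b"), c("a", "b")))
  mt <- metrics_from_confusion(cm)
  expect_equal(mt$per_class$precision[1], 8 / 11)
  expect_equal(mt$per_class$recall[1], 8 / 10)
  expect_equal(mt$per_class$f1[1],
               2 * (8 / 11) * 0.8 / (8 / 11 + 0.8))
  expect_equal(mt$macro[["precision"]], mean(c(8 / 11, 7 / 9)))
  ## diagonal matrix: everything 1
  mt2 <- metrics_from_confusion(diag(c(4, 5, 6)))
  expect_true(all(mt2$per_class$f1 == 1))
  ## degenerate class: zero row -> recall 0 with warning
  cm3 <- matrix(c(5, 0, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(mt3 <- metrics_from_confusion(cm3),
                 class = "recipemine_degenerate_class")
  expect_equal(mt3$per_class$recall[2], 0)
  expect_error(metrics_from_confusion(matrix(0, 2, 3)),
               class = "recipemine_cm_error")
})

test_that("macro metrics are invariant to class relabeling", {
  cm <- matrix(c(8, 3, 1, 2, 7, 0, 1, 2, 9), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  perm <- c(3, 1, 2)
  cm_p <- cm[perm, perm]
  m1 <- metrics_from_confusion(cm)$macro
  m2 <- metrics_from_confusion(cm_p)$macro
  expect_equal(m1, m2)
})

separable_corpus <- function(n_per = 12, n_classes = 4, seed = 5) {
  set.seed(seed)
  pools <- lapply(seq_len(n_classes), function(c)
    sprintf("class%d_ing%02d", c, 1:8))
  recs <- list()
  for (c in seq_len(n_classes)) for (i in seq_len(n_per))
    recs[[length(recs) + 1]] <- mk_clean_recipe(
      sprintf("c%d_%02d", c, i), paste0("cuisine", c),
      sample(pools[[c]], sample(3:6, 1)))
  do.call(mk_corpus, recs)
}

test_that("all four classifier families separate a disjoint-pool corpus", {
  corpus <- separable_corpus()
  ## a single greedy tree is the weakest family on sparse tf-idf vectors
  ## (consistent with its cross-validated rank on real corpora), so it
  ## gets a lower bar on this 48-recipe fixture
  floor_of <- c(svm = 0.9, naive_bayes = 0.9, random_forest = 0.9,
                decision_tree = 0.75)
  for (clf in names(floor_of)) {
    rep_ <- crossvalidate(corpus, classifier = clf, folds = 4, seed = 9,
                          control = list(ntree = 25))
    expect_gte(rep_$macro[["f1"]], floor_of[[clf]])
    ## pooled confusion matrix total equals corpus size
    expect_equal(sum(rep_$confusion), length(corpus))
  }
})

test_that("crossvalidate is deterministic under a fixed seed and validates input", {
  corpus <- separable_corpus(n_per = 8, n_classes = 3)
  r1 <- crossvalidate(corpus, classifier = "random_forest", folds = 4,
                      seed = 11, control = list(ntree = 15))
  r2 <- crossvalidate(corpus, classifier = "random_forest", folds = 4,
                      seed = 11, control = list(ntree = 15))
  expect_identical(r1$confusion, r2$confusion)
  expect_identical(r1$macro, r2$macro)
  expect_error(crossvalidate(corpus, classifier = "perceptron"))
  expect_error(crossvalidate(corpus, folds = 9, classifier = "svm"),
               "cuisine", class = "recipemine_small_class")
  ## fold test sizes partition n
  labs <- sapply(corpus, `[[`, "label")
  folds <- recipemine:::stratified_folds(labs, 4, seed = 11)
  expect_equal(sum(table(folds)), length(corpus))
  expect_equal(length(unique(folds)), 4)
})

test_that("holdout evaluation uses a single 80/20 split", {
  corpus <- separable_corpus(n_per = 10, n_classes = 3)
  rep_ <- crossvalidate(corpus, classifier = "naive_bayes", seed = 3,
                        holdout = TRUE)
  expect_equal(rep_$folds, 1L)
  expect_equal(sum(rep_$confusion), length(corpus) / 5)
})

test_that("predict_unknown conserves counts and flags empty documents", {
  corpus <- separable_corpus(n_per = 10, n_classes = 3)
  unknown <- mk_corpus(
    mk_clean_recipe("u1", "unknown", c("class1_ing01", "class1_ing02")),
    mk_clean_recipe("u2", "unknown", c("class2_ing03", "class2_ing04")),
    mk_clean_recipe("u3", "unknown", c("never seen", "also unseen")))
  expect_warning(res <- predict_unknown(corpus, unknown, seed = 1),
                 class = "recipemine_empty_doc")
  expect_equal(sum(res$counts), 3)
  expect_equal(unname(res$labels[c("u1", "u2")]), c("cuisine1", "cuisine2"))
  expect_equal(res$flagged, "u3")
  ## empty unknown set -> empty distribution
  res0 <- predict_unknown(corpus, mk_corpus(), seed = 1)
  expect_equal(sum(res0$counts), 0)
  expect_length(res0$labels, 0)
})
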