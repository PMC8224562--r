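## tf-idf ingredient vectors.
##
## Term frequency is binary presence per recipe (ingredient lists rarely
## repeat a term, and the Specialty counts are presence-based too); the
## smoothed idf is ln((1+D)/(1+df)) + 1 with D the corpus size, and every
## document vector is L2-normalized. These choices are fixed so results
## are reproducible.

#' Build a tf-idf model and document-term matrix
#'
#' @param docs a `recipe_corpus` or a list of character vectors (the
#'   canonical ingredient set of each recipe).
#' @return list with `model` (a `tfidf_model`: `vocabulary`, `df`, `idf`,
#'   `D`) and `dtm` (documents x vocabulary numeric matrix, L2 rows).
#' @export
build_tfidf <- function(docs) {
  if (inherits(docs, "recipe_corpus")) docs <- recipe_ingredient_sets(docs)
  vocab <- sort(unique(unlist(docs)))
  if (!length(vocab)) stop_rm("empty vocabulary", class = "recipemine_empty_vocab")
  D <- length(docs)
  df <- setNames(integer(length(vocab)), vocab)
  tab <- table(unlist(lapply(docs, unique)))
  df[names(tab)] <- as.integer(tab)
  idf <- log((1 + D) / (1 + df)) + 1
  model <- structure(list(vocabulary = vocab, df = df, idf = idf, D = D),
                     class = "tfidf_model")
  list(model = model, dtm = tfidf_transform(model, docs))
}

#' Transform documents into tf-idf space of a fitted model
#'
#' Terms outside the model vocabulary are dropped (they carry no weight a
#' training fold could have learned).
#'
#' @param model a `tfidf_model` from [build_tfidf()].
#' @param docs a `recipe_corpus` or list of character vectors.
#' @return documents x vocabulary matrix with L2-normalized rows (all-zero
#'   rows stay zero).
#' @export
tfidf_transform <- function(model, docs) {
  if (inherits(docs, "recipe_corpus")) docs <- recipe_ingredient_sets(docs)
  m <- matrix(0, length(docs), length(model$vocabulary),
              dimnames = list(names(docs), model$vocabulary))
  for (k in seq_along(docs)) {
    hit <- intersect(unique(docs[[k]]), model$vocabulary)
    if (length(hit)) m[k, hit] <- model$idf[hit]
  }
  nrm <- sqrt(rowSums(m^2))
  nz <- nrm > 0
  m[nz, ] <- m[nz, , drop = FALSE] / nrm[nz]
  m
}

#' @export
print.tfidf_model <- function(x, ...) {
  cat(sprintf("<tf-idf model> %d terms over %d documents\n",
              length(x$vocabulary), x$D))
  invisible(x)
}
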