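## Featured-ingredient extraction by the Specialty score.
##
## For ingredient i and cuisine category j:
##   importance  p[i,j] = r[i,j] / s[j]   (fraction of j's recipes using i)
##   uniqueness  w[i]   = N / C[i]        (N categories, C[i] containing i)
##   Specialty   S[i,j] = p[i,j] * w[i]
## r counts recipes, not occurrences: duplicate lines within a recipe are
## collapsed. S is bounded by N, attained only by a category-exclusive
## ingredient used in every recipe of its category.

#' Presence counts per (ingredient, category)
#'
#' @param corpus a cleaned, labeled `recipe_corpus` (recipes labeled
#'   `"unknown"` are ignored).
#' @return list with `r` (ingredient x category recipe-count matrix), `s`
#'   (recipes per category), `C` (categories containing each ingredient)
#'   and `N` (number of categories).
#' @export
count_matrix <- function(corpus) {
  labs <- corpus_labels(corpus)
  corpus <- corpus[labs != "unknown"]
  if (length(corpus) == 0)
    stop_rm("no labeled recipes", class = "recipemine_empty_corpus")
  sets <- recipe_ingredient_sets(corpus)
  labs <- corpus_labels(corpus)
  cats <- sort(unique(labs))
  ings <- sort(unique(unlist(sets)))
  r <- matrix(0L, length(ings), length(cats), dimnames = list(ings, cats))
  for (k in seq_along(sets)) {
    if (length(sets[[k]]))
      r[sets[[k]], labs[k]] <- r[sets[[k]], labs[k]] + 1L
  }
  s <- setNames(as.integer(table(labs)[cats]), cats)
  C <- setNames(rowSums(r >= 1L), ings)
  list(r = r, s = s, C = C, N = length(cats))
}

#' Unique canonical ingredient set of each recipe
#' @param corpus a cleaned `recipe_corpus`.
#' @param substantive_only drop 0-gram (decorative) lines; default TRUE.
#' @return list of character vectors, one per recipe, named by recipe id.
#' @export
recipe_ingredient_sets <- function(corpus, substantive_only = TRUE) {
  out <- lapply(corpus, function(rec) {
    ln <- rec$lines
    keep <- !is.na(ln$canonical)
    if (substantive_only) keep <- keep & !is.na(ln$grams) & ln$grams > 0
    sort(unique(ln$canonical[keep]))
  })
  names(out) <- corpus_ids(corpus)
  out
}

#' Importance p = r / s
#' @param r recipes in the category containing the ingredient.
#' @param s recipes in the category.
#' @return p in \[0, 1\]. Vectorized.
#' @export
importance <- function(r, s) {
  if (any(s < 1)) stop_rm("category with no recipes (s = 0)",
                          class = "recipemine_undefined_category")
  r / s
}

#' Uniqueness w = N / C
#' @param N number of cuisine categories.
#' @param C number of categories containing the ingredient (>= 1).
#' @return w in \[1, N\]. Vectorized over C.
#' @export
uniqueness <- function(N, C) {
  if (any(C < 1)) stop_rm("ingredient absent from every category (C = 0)",
                          class = "recipemine_undefined_ingredient")
  N / C
}

#' Specialty score S = p * w
#' @param p importance from [importance()].
#' @param w uniqueness from [uniqueness()].
#' @return S in \[0, N\]. Vectorized.
#' @export
specialty_score <- function(p, w) p * w

#' Build the full Specialty table for a corpus
#'
#' @param corpus a cleaned, labeled `recipe_corpus`.
#' @param tau featured threshold on importance p (default 0.10; the
#'   threshold is chosen empirically, not printed in any reference table).
#' @return a `specialty_table`: list with `r`, `s`, `C`, `N`, `p`, `w`,
#'   `S`, `tau`, `categories`, `ingredients`.
#' @export
specialty_table <- function(corpus, tau = 0.10) {
  cm <- count_matrix(corpus)
  p <- sweep(cm$r, 2, cm$s, "/")
  w <- uniqueness(cm$N, cm$C)
  S <- p * w
  structure(c(cm, list(p = p, w = w, S = S, tau = tau,
                       categories = colnames(cm$r),
                       ingredients = rownames(cm$r))),
            class = "specialty_table")
}

#' @export
print.specialty_table <- function(x, ...) {
  cat(sprintf("<specialty table> %d ingredients x %d categories, tau = %g\n",
              length(x$ingredients), x$N, x$tau))
  invisible(x)
}

#' @export
as.data.frame.specialty_table <- function(x, ...) {
  long <- expand.grid(ingredient = x$ingredients, category = x$categories,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$r <- as.vector(x$r)
  long$s <- x$s[long$category]
  long$p <- as.vector(x$p)
  long$C <- x$C[long$ingredient]
  long$w <- x$w[long$ingredient]
  long$S <- as.vector(x$S)
  long[long$r > 0, , drop = FALSE]
}

#' Featured ingredients per category
#'
#' Ingredients whose importance p meets the threshold `tau`, ranked by
#' Specialty score (ties broken by higher p, then by key) and truncated to
#' `top_n` per category.
#'
#' @param table a [specialty_table()].
#' @param tau threshold on p in \[0, 1\]; defaults to the table's own.
#' @param top_n list length per category (default 10).
#' @return data frame `category`, `rank`, `ingredient`, `S`, `p`.
#' @export
featured_ingredients <- function(table, tau = table$tau, top_n = 10) {
  if (tau < 0 || tau > 1)
    stop_rm("tau must lie in [0, 1], got %g", tau, class = "recipemine_tau_error")
  out <- lapply(table$categories, function(j) {
    keep <- table$p[, j] >= tau & table$r[, j] >= 1
    if (!any(keep)) return(NULL)
    ing <- table$ingredients[keep]
    S <- table$S[keep, j]; p <- table$p[keep, j]
    ord <- order(-S, -p, ing)
    n <- min(top_n, length(ord))
    data.frame(category = j, rank = seq_len(n), ingredient = ing[ord][seq_len(n)],
               S = S[ord][seq_len(n)], p = p[ord][seq_len(n)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(category = character(), rank = integer(),
                      ingredient = character(), S = numeric(), p = numeric())
  rownames(out) <- NULL
  out
}

#' Common ingredients: present in every category
#'
#' @param table a [specialty_table()].
#' @return data frame `ingredient`, `C`, `min_p`, `max_p` for ingredients
#'   with C = N, sorted by decreasing minimum importance.
#' @export
common_ingredients <- function(table) {
  keep <- table$C == table$N
  ing <- table$ingredients[keep]
  if (!length(ing))
    return(data.frame(ingredient = character(), C = integer(),
                      min_p = numeric(), max_p = numeric()))
  pm <- table$p[keep, , drop = FALSE]
  out <- data.frame(ingredient = ing, C = table$C[keep],
                    min_p = apply(pm, 1, min), max_p = apply(pm, 1, max),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$min_p, out$ingredient), ]
  rownames(out) <- NULL
  out
}
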