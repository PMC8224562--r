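## Shared fixtures: tiny hand-built lexicons, unit tables and corpora, and
## the brute-force Specialty oracle that recomputes scores from raw
## membership sets with plain loops (independent of the matrix pipeline).

tiny_lexicon <- function() {
  synonym_lexicon(
    mapping = c("diced scallions" = "scallion",
                "chopped scallions" = "scallion",
                "fish sauce" = "fish sauce",
                "nam pla" = "fish sauce",
                salt = "salt", rice = "rice", tofu = "tofu",
                "soy sauce" = "soy sauce", sugar = "sugar",
                "white sesame" = "white sesame"),
    stop_terms = c("julienne", "preheated oven"),
    decorative_terms = "white sesame")
}

tiny_units <- function() {
  unit_table(data.frame(
    unit_phrase = c("g", "kg", "ml", "tbsp", "piece", "piece"),
    ingredient_class = c("", "", "", "", "", "tofu"),
    grams = c(1, 1000, 1, 15, 50, 300)))
}

raw_line <- function(raw, qty = 10, unit = "g") {
  data.frame(raw_name = raw, quantity_value = qty, unit = unit,
             stringsAsFactors = FALSE)
}

## a recipe that is already clean: canonical names, specified grams
mk_clean_recipe <- function(id, label, ings, grams = rep(10, length(ings))) {
  recipe_record(id, label, data.frame(
    raw_name = ings, canonical = ings, quantity_value = grams, unit = "g",
    quantity_kind = "specified", grams = grams, stringsAsFactors = FALSE))
}

mk_corpus <- function(...) structure(list(...), class = "recipe_corpus")

## random cleaned corpus over a small ingredient pool; every category used
random_corpus <- function(n_categories, n_recipes, n_ingredients) {
  cats <- paste0("cat", seq_len(n_categories))
  pool <- paste0("ing", seq_len(n_ingredients))
  recs <- lapply(seq_len(n_recipes), function(i) {
    mk_clean_recipe(paste0("r", i),
                    if (i <= n_categories) cats[i] else sample(cats, 1),
                    sample(pool, sample.int(min(8, n_ingredients), 1)))
  })
  do.call(mk_corpus, recs)
}

## Brute-force Specialty oracle: loops over recipes and raw sets only.
brute_specialty <- function(corpus) {
  labs <- vapply(corpus, `[[`, character(1), "label")
  keep <- labs != "unknown"
  corpus <- unclass(corpus)[keep]; labs <- labs[keep]
  sets <- lapply(corpus, function(rec)
    unique(rec$lines$canonical[rec$lines$grams > 0]))
  cats <- sort(unique(labs))
  ings <- sort(unique(unlist(sets)))
  N <- length(cats)
  S <- matrix(0, length(ings), length(cats), dimnames = list(ings, cats))
  for (ing in ings) {
    C_i <- 0
    for (j in cats) {
      in_j <- which(labs == j)
      r <- sum(vapply(in_j, function(k) ing %in% sets[[k]], logical(1)))
      if (r >= 1) C_i <- C_i + 1
    }
    for (j in cats) {
      in_j <- which(labs == j)
      r <- sum(vapply(in_j, function(k) ing %in% sets[[k]], logical(1)))
      S[ing, j] <- (r / length(in_j)) * (N / C_i)
    }
  }
  S
}

## unknown-label alias corpus written to a temp jsonl file
write_jsonl <- function(lines, path = tempfile(fileext = ".jsonl")) {
  writeLines(lines, path, useBytes = TRUE)
  path
}
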