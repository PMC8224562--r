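lex <- tiny_lexicon()
units <- tiny_units()

test_that("normalize_ingredient: synonyms, symbol stripping, stop terms, identity", {
  expect_equal(normalize_ingredient("diced scallions", lex), "scallion")
  expect_equal(normalize_ingredient("chopped scallions", lex), "scallion")
  expect_equal(normalize_ingredient("【Diced scallions!】", lex), "scallion")
  expect_true(is.na(normalize_ingredient("julienne", lex)))
  expect_true(is.na(normalize_ingredient("unicorn horn", lex)))
  expect_equal(normalize_ingredient("scallion", lex), "scallion") # fixed point
  expect_equal(normalize_ingredient(c("nam pla", "RICE"), lex),
               c("fish sauce", "rice"))
})

test_that("impute_quantity applies the three rules and flags decoratives", {
  mk <- function(canonical, qty, unit, kind)
    list(canonical = canonical, quantity_value = qty, unit = unit,
         quantity_kind = kind)
  ## vague: corpus mean of specified occurrences 4, 5, 6 g -> 5 g
  means <- c(salt = mean(c(4, 5, 6)))
  expect_equal(impute_quantity(mk("salt", NA, "few", "vague"), units, means), 5)
  ## vague with no specified occurrence: configurable default
  expect_equal(impute_quantity(mk("sugar", NA, "few", "vague"), units,
                               means, default_vague = 7), 7)
  ## piece unit through the replacement table, class-specific beats generic
  expect_equal(impute_quantity(mk("rice", 1, "piece", "piece_unit"), units), 50)
  expect_equal(impute_quantity(mk("tofu", 2, "piece", "piece_unit"), units), 600)
  ## specified mass/volume
  expect_equal(impute_quantity(mk("rice", 0.2, "kg", "specified"), units), 200)
  expect_equal(impute_quantity(mk("rice", 30, "ml", "specified"), units), 30)
  ## decorative -> 0 g
  expect_equal(impute_quantity(mk("white sesame", 5, "g", "decorative"), units), 0)
  ## unresolved unit
  expect_error(impute_quantity(mk("rice", 1, "hogshead", "piece_unit"), units),
               "hogshead", class = "recipemine_unresolved_unit")
})

test_that("clean_recipe keeps, canonicalizes and excludes correctly", {
  r_ok <- recipe_record("ok", "Thai", rbind(
    raw_line("nam pla", 30), raw_line("rice", 100), raw_line("salt", 5)))
  res <- clean_recipe(r_ok, lex, units)
  expect_equal(res$status, "kept")
  expect_equal(res$record$lines$canonical, c("fish sauce", "rice", "salt"))
  expect_equal(res$record$lines$grams, c(30, 100, 5))

  r_stop <- recipe_record("stops", "Thai",
                          rbind(raw_line("julienne"), raw_line("gibberish")))
  expect_equal(clean_recipe(r_stop, lex, units)$reason, "unrecognizable")

  r_single <- recipe_record("single", "Thai",
                            rbind(raw_line("rice", 100), raw_line("gibberish")))
  expect_equal(clean_recipe(r_single, lex, units)$reason, "single_ingredient")

  ## decorative-only mass does not count toward the two-ingredient minimum
  r_decor <- recipe_record("decor", "Thai",
                           rbind(raw_line("rice", 100), raw_line("white sesame", 2)))
  expect_equal(clean_recipe(r_decor, lex, units)$reason, "single_ingredient")
})

test_that("preprocess conserves ids and is idempotent", {
  corpus <- mk_corpus(
    recipe_record("a", "Thai", rbind(raw_line("nam pla", 30), raw_line("rice", 100))),
    recipe_record("b", "Thai", rbind(raw_line("julienne"))),
    recipe_record("c", "Chinese", rbind(raw_line("soy sauce", NA, "few"),
                                        raw_line("soy sauce", 10),
                                        raw_line("tofu", 1, "piece"))),
    recipe_record("d", "Chinese", rbind(raw_line("rice", 50))))
  out <- preprocess_corpus(corpus, lex, units)
  expect_setequal(c(sapply(out$kept, `[[`, "id"), out$excluded$id),
                  c("a", "b", "c", "d"))
  expect_equal(sort(out$excluded$reason), c("single_ingredient", "unrecognizable"))
  ## vague soy sauce imputed from its only specified occurrence (10 g)
  cr <- out$kept[[which(sapply(out$kept, `[[`, "id") == "c")]]
  expect_equal(cr$lines$grams, c(10, 10, 300))
  ## idempotence: cleaning the cleaned corpus changes nothing
  again <- preprocess_corpus(out$kept, lex, units)
  expect_equal(length(again$kept), length(out$kept))
  expect_equal(lapply(again$kept, `[[`, "lines"),
               lapply(out$kept, `[[`, "lines"))
})

test_that("adding a synonym never decreases the number of kept recipes", {
  set.seed(42)
  base_map <- c(rice = "rice", salt = "salt", tofu = "tofu")
  pool <- c("rice", "salt", "tofu", "mystery herb")
  corpus <- do.call(mk_corpus, lapply(1:12, function(i) {
    ings <- sample(pool, sample(2:3, 1))
    recipe_record(paste0("r", i), "Chinese",
                  do.call(rbind, lapply(ings, raw_line)))
  }))
  lex1 <- synonym_lexicon(base_map)
  lex2 <- synonym_lexicon(c(base_map, "mystery herb" = "coriander"))
  n1 <- length(preprocess_corpus(corpus, lex1, units)$kept)
  n2 <- length(preprocess_corpus(corpus, lex2, units)$kept)
  expect_gte(n2, n1)
})

test_that("corpus_stats computes half-up one-decimal conversion rates", {
  ## toy: X 4 -> 3, Y 2 -> 2; total 6 -> 5 = 83.3%
  st <- corpus_stats(c(X = 4, Y = 2), c(X = 3, Y = 2))
  expect_equal(st$conversion_rate[st$category == "X"], 75.0)
  expect_equal(st$conversion_rate[st$category == "Total"], 83.3)
  expect_equal(st$after[st$category == "Total"], 5)
  expect_error(corpus_stats(c(X = 4), c(X = 3, Z = 1)),
               class = "recipemine_consistency_error")
  expect_error(corpus_stats(c(X = 4), c(X = 5)),
               class = "recipemine_consistency_error")
  ## half-up, not banker's
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(91.65, 1), 91.7)
  expect_equal(round(0.25, 1), 0.2) # contrast with base R
})
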