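## Synthetic recipe corpora with planted ground truth.
##
## The generator emulates the structure of a real recipe-sharing corpus:
## eight cuisines drawing from a shared common-ingredient pool plus
## cuisine-exclusive featured pools, lognormal gram quantities with a
## stated fraction replaced by vague terms ("few", "適量"), occasional
## piece units and decorative garnishes, and synonym variants that the
## emitted lexicon resolves back to canonical keys. Each cuisine's
## featured pool is tied to a nutrient archetype so clustering structure
## is recoverable by construction.

.archetype_names <- c("high_carb", "high_sugar", "high_sodium",
                      "high_fiber", "high_fat", "balanced")

## fixed per-100g archetype templates (documented constants, not sampled)
.archetype_templates <- rbind(
  high_carb   = c(70,  6,  1,   0.3,  2,   3,   10),
  high_sugar  = c(85,  1,  0.5, 0.2,  0.5, 70,  20),
  high_sodium = c(12,  6,  2,   0.5,  1,   3,   3500),
  high_fiber  = c(30,  5,  1.5, 0.3,  12,  4,   15),
  high_fat    = c(5,   3,  65,  22,   0.5, 1,   50),
  balanced    = c(15, 10,  5,   1.5,  2,   3,   60))
colnames(.archetype_templates) <- .nutrient_cols

#' Archetype nutrient templates
#' @return matrix of the six per-100g nutrient archetypes used by the
#'   synthetic generator.
#' @export
archetype_templates <- function() .archetype_templates

#' Configuration for the synthetic corpus generator
#'
#' Defaults state a realistic small-scale world: 8 cuisines of 100
#' recipes, 10 signature ingredients per cuisine over a 15-ingredient
#' common pool, 4-10 ingredients per recipe (plus the staple), 60% of
#' draws from the cuisine's featured pool, lognormal quantities around
#' 30 g with 15% replaced by vague terms.
#'
#' @param n_cuisines number of cuisine categories (default 8).
#' @param recipes_per_cuisine labeled recipes per cuisine (default 100).
#' @param n_unknown non-classified recipes, each generated from a
#'   uniformly drawn cuisine recorded in the ground truth (default 50).
#' @param shared_pool_size size of the common-ingredient pool, including
#'   the staple (default 15).
#' @param featured_per_cuisine cuisine-exclusive ingredients per cuisine
#'   (default 10).
#' @param ingredients_per_recipe inclusive (min, max) recipe size range.
#' @param p_featured probability a drawn ingredient comes from the
#'   cuisine's featured pool (default 0.6).
#' @param vague_fraction fraction of quantity fields replaced by vague
#'   terms (default 0.15).
#' @param piece_fraction fraction of lines using a piece unit (default 0.1).
#' @param decorative_rate probability a recipe gets a decorative garnish
#'   line (default 0.05).
#' @param synonym_variants_per_ingredient spelling variants registered in
#'   the lexicon per canonical ingredient (default 2).
#' @param synonym_rate probability a line uses a variant instead of the
#'   canonical name (default 0.3).
#' @param archetypes character vector recycled over cuisines assigning
#'   each featured pool a nutrient archetype.
#' @param noise_sd relative Gaussian noise on archetype templates
#'   (default 0.1 = 10% of the template value).
#' @param staples ingredient(s) included in every recipe (default
#'   `"salt"`, part of the shared pool).
#' @param seed integer seed; all outputs are deterministic under it.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_cuisines = 8, recipes_per_cuisine = 100,
                             n_unknown = 50, shared_pool_size = 15,
                             featured_per_cuisine = 10,
                             ingredients_per_recipe = c(4, 10),
                             p_featured = 0.6, vague_fraction = 0.15,
                             piece_fraction = 0.1, decorative_rate = 0.05,
                             synonym_variants_per_ingredient = 2,
                             synonym_rate = 0.3,
                             archetypes = .archetype_names,
                             noise_sd = 0.1, staples = "salt", seed = 42) {
  stopifnot(n_cuisines >= 1, recipes_per_cuisine >= 1,
            length(ingredients_per_recipe) == 2,
            ingredients_per_recipe[1] >= 2,
            ingredients_per_recipe[1] <= ingredients_per_recipe[2])
  for (pr in c(p_featured, vague_fraction, piece_fraction, decorative_rate,
               synonym_rate))
    if (pr < 0 || pr > 1) stop_rm("probabilities must lie in [0,1]",
                                  class = "recipemine_config_error")
  if (ingredients_per_recipe[2] > shared_pool_size + featured_per_cuisine)
    stop_rm("recipe size exceeds combined pool capacity",
            class = "recipemine_config_error")
  if (!all(archetypes %in% .archetype_names))
    stop_rm("unknown archetype(s): %s",
            paste(setdiff(archetypes, .archetype_names), collapse = ", "),
            class = "recipemine_config_error")
  cuisines <- if (n_cuisines <= length(CUISINES)) CUISINES[seq_len(n_cuisines)]
  else c(CUISINES, sprintf("Cuisine%02d", seq_len(n_cuisines - length(CUISINES))))
  structure(list(
    n_cuisines = n_cuisines, cuisines = cuisines,
    recipes_per_cuisine = recipes_per_cuisine, n_unknown = n_unknown,
    shared_pool_size = shared_pool_size,
    featured_per_cuisine = featured_per_cuisine,
    ingredients_per_recipe = ingredients_per_recipe,
    p_featured = p_featured, vague_fraction = vague_fraction,
    piece_fraction = piece_fraction, decorative_rate = decorative_rate,
    synonym_variants_per_ingredient = synonym_variants_per_ingredient,
    synonym_rate = synonym_rate,
    archetype_of_cuisine = setNames(rep_len(archetypes, n_cuisines), cuisines),
    noise_sd = noise_sd, staples = staples, seed = seed),
    class = "synthetic_config")
}

synthetic_pools <- function(config) {
  shared <- unique(c(config$staples,
                     sprintf("shared_%02d", seq_len(config$shared_pool_size))))
  shared <- shared[seq_len(min(length(shared), config$shared_pool_size))]
  featured <- lapply(config$cuisines, function(cu)
    sprintf("%s_special_%02d", tolower(cu), seq_len(config$featured_per_cuisine)))
  names(featured) <- config$cuisines
  list(shared = shared, featured = featured, decorative = "sesame garnish")
}

.vague_pool <- c("few", "appropriate", "properly", "適量", "少許")
.piece_units <- c("piece", "slice", "carton")

#' Generate a synthetic labeled recipe corpus with ground truth
#'
#' @param config a [synthetic_config()].
#' @return list with `labeled` and `unknown` (`recipe_corpus`), `lexicon`
#'   (`synonym_lexicon`), `units` (`unit_table`) and `truth` (list:
#'   `featured` per cuisine, `shared`, `archetype_of` per ingredient,
#'   `unknown_truth` id -> generating cuisine, `recipe_cuisine` id ->
#'   generating cuisine for every recipe).
#' @export
generate_corpus <- function(config) {
  pools <- synthetic_pools(config)
  set.seed(derive_seed(config$seed, 10))
  units <- unit_table(data.frame(
    unit_phrase = c("g", "kg", "ml", "tbsp", "tsp", "piece", "slice", "carton"),
    ingredient_class = "",
    grams = c(1, 1000, 1, 15, 5, 50, 30, 200)))
  ## lexicon: canonical keys, variants, stop + decorative terms
  canon_all <- c(pools$shared, unlist(pools$featured), pools$decorative)
  variants <- list()
  if (config$synonym_variants_per_ingredient > 0) {
    for (ing in canon_all)
      for (v in seq_len(config$synonym_variants_per_ingredient))
        variants[[sprintf("%s variant %d", ing, v)]] <- ing
  }
  lexicon <- synonym_lexicon(
    mapping = c(setNames(canon_all, canon_all), unlist(variants)),
    stop_terms = c("julienne", "to taste", "preheated oven"),
    decorative_terms = pools$decorative)
  variant_names <- split(names(variants), unlist(variants))

  make_recipe <- function(id, cuisine, label) {
    size <- sample(seq(config$ingredients_per_recipe[1],
                       config$ingredients_per_recipe[2]), 1)
    n_feat <- stats::rbinom(1, size, config$p_featured)
    n_feat <- min(max(n_feat, size - length(pools$shared)),
                  config$featured_per_cuisine, size)
    feat <- sample(pools$featured[[cuisine]], n_feat)
    shared_pool <- setdiff(pools$shared, config$staples)
    shr <- if (size - n_feat > 0) sample(shared_pool, size - n_feat) else character()
    ings <- c(config$staples, feat, shr)
    n <- length(ings)
    grams <- stats::rlnorm(n, meanlog = log(30), sdlog = 0.5)
    unit <- rep("g", n)
    qty <- round(grams, 1)
    piece <- stats::runif(n) < config$piece_fraction
    unit[piece] <- sample(.piece_units, sum(piece), replace = TRUE)
    qty[piece] <- sample(1:3, sum(piece), replace = TRUE)
    vague <- stats::runif(n) < config$vague_fraction
    unit[vague] <- sample(.vague_pool, sum(vague), replace = TRUE)
    qty[vague] <- NA_real_
    raw <- ings
    use_var <- stats::runif(n) < config$synonym_rate &
      lengths(variant_names[ings]) > 0
    for (i in which(use_var))
      raw[i] <- sample(variant_names[[ings[i]]], 1)
    if (stats::runif(1) < config$decorative_rate) {
      raw <- c(raw, pools$decorative)
      qty <- c(qty, 1); unit <- c(unit, "g")
    }
    recipe_record(id, label,
                  data.frame(raw_name = raw, quantity_value = qty, unit = unit,
                             stringsAsFactors = FALSE),
                  title = sprintf("%s dish %s", cuisine, id))
  }

  labeled <- list(); recipe_cuisine <- character()
  for (cu in config$cuisines) {
    for (r in seq_len(config$recipes_per_cuisine)) {
      id <- sprintf("%s_%04d", tolower(cu), r)
      labeled[[length(labeled) + 1L]] <- make_recipe(id, cu, cu)
      recipe_cuisine[[id]] <- cu
    }
  }
  unknown <- list(); unknown_truth <- character()
  if (config$n_unknown > 0) {
    for (r in seq_len(config$n_unknown)) {
      cu <- sample(config$cuisines, 1)
      id <- sprintf("unknown_%04d", r)
      unknown[[length(unknown) + 1L]] <- make_recipe(id, cu, "unknown")
      unknown_truth[[id]] <- cu
      recipe_cuisine[[id]] <- cu
    }
  }
  archetype_of <- c(
    setNames(rep("balanced", length(pools$shared)), pools$shared),
    setNames(rep(config$archetype_of_cuisine, each = config$featured_per_cuisine),
             unlist(pools$featured)),
    setNames("balanced", pools$decorative))
  list(labeled = new_corpus(labeled), unknown = new_corpus(unknown),
       lexicon = lexicon, units = units,
       truth = list(featured = pools$featured, shared = pools$shared,
                    archetype_of = archetype_of,
                    unknown_truth = unknown_truth,
                    recipe_cuisine = recipe_cuisine))
}

#' Generate a toy food-composition table for a synthetic corpus
#'
#' Every pool ingredient gets its archetype's template plus relative
#' Gaussian noise (sd = `noise_sd` times the template value), clipped at
#' zero and adjusted so sugar <= carbohydrate, saturated fat <= fat and
#' carbohydrate + protein + fat <= 100 g always hold.
#'
#' @param config a [synthetic_config()].
#' @return a [nutrient_db()] covering every generated ingredient.
#' @export
generate_nutrient_db <- function(config) {
  pools <- synthetic_pools(config)
  set.seed(derive_seed(config$seed, 11))
  archetype_of <- c(
    setNames(rep("balanced", length(pools$shared)), pools$shared),
    setNames(rep(config$archetype_of_cuisine, each = config$featured_per_cuisine),
             unlist(pools$featured)),
    setNames("balanced", pools$decorative))
  ings <- names(archetype_of)
  rows <- t(vapply(ings, function(ing) {
    tmpl <- .archetype_templates[archetype_of[[ing]], ]
    v <- pmax(tmpl * (1 + stats::rnorm(length(tmpl), sd = config$noise_sd)), 0)
    v["sugar_g"] <- min(v["sugar_g"], v["carbohydrate_g"])
    v["saturated_fat_g"] <- min(v["saturated_fat_g"], v["fat_g"])
    macro <- v["carbohydrate_g"] + v["protein_g"] + v["fat_g"]
    if (macro > 100) {
      sc <- 100 / macro
      v[c("carbohydrate_g", "protein_g", "fat_g")] <-
        v[c("carbohydrate_g", "protein_g", "fat_g")] * sc
      v["sugar_g"] <- min(v["sugar_g"], v["carbohydrate_g"])
      v["saturated_fat_g"] <- min(v["saturated_fat_g"], v["fat_g"])
    }
    v
  }, numeric(length(.nutrient_cols))))
  nutrient_db(data.frame(ingredient = ings, rows, stringsAsFactors = FALSE))
}

#' Consistency report between a generated corpus and its configuration
#'
#' Checks that per-cuisine recipe counts match the configuration exactly
#' and that the empirical featured-pool draw fraction (over non-staple,
#' non-decorative lines of labeled recipes) lies within 3 binomial
#' standard deviations of `p_featured`.
#'
#' @param dataset output of [generate_corpus()].
#' @param config the generating [synthetic_config()].
#' @return list with `counts_ok`, `fraction`, `fraction_ok`, `n_draws`,
#'   `bound` (the 3-sigma half-width) and `counts` (per-cuisine table).
#' @export
expected_counts_check <- function(dataset, config) {
  labs <- corpus_labels(dataset$labeled)
  counts <- table(labs)
  counts_ok <- all(sort(names(counts)) == sort(config$cuisines)) &&
    all(counts == config$recipes_per_cuisine) &&
    length(dataset$unknown) == config$n_unknown
  featured_all <- unlist(dataset$truth$featured)
  n_feat <- 0L; n_draws <- 0L
  for (rec in dataset$labeled) {
    canon <- normalize_ingredient(rec$lines$raw_name, dataset$lexicon)
    canon <- canon[!is.na(canon)]
    canon <- setdiff(canon, c(config$staples, "sesame garnish"))
    n_draws <- n_draws + length(canon)
    n_feat <- n_feat + sum(canon %in% featured_all)
  }
  frac <- n_feat / n_draws
  bound <- 3 * sqrt(config$p_featured * (1 - config$p_featured) / n_draws)
  list(counts_ok = counts_ok, fraction = frac,
       fraction_ok = abs(frac - config$p_featured) <= bound,
       n_draws = n_draws, bound = bound, counts = counts)
}
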