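## Ingredient-line normalization, gram imputation and recipe exclusion.
##
## Matching is exact lexicon lookup after symbol stripping (no word
## segmentation): ingredient fields are short noun phrases, and the lexicon
## controls recall explicitly. All comparison happens on NFC-normalized,
## lower-cased text.

#' Default vague-quantity vocabulary
#'
#' Quantity descriptions that carry no measurable amount and trigger
#' corpus-mean imputation.
#' @export
VAGUE_TERMS <- c("few", "a few", "appropriate", "properly", "some",
                 "少許", "適量")

## mass/volume units converted directly (ml treated as g, density 1)
.mass_units <- c(g = 1, gram = 1, grams = 1, kg = 1000, ml = 1, l = 1000)

strip_symbols <- function(x) {
  out <- stringi::stri_replace_all_regex(x, "[\\p{P}\\p{S}\\p{Co}]+", " ")
  out <- stringi::stri_replace_all_regex(out, "\\s+", " ")
  tolower(nfc(out))
}

#' Normalize a raw ingredient string to its canonical key
#'
#' Strips bracket symbols, punctuation and emoji, squashes whitespace,
#' lower-cases and NFC-normalizes, then exact-matches the lexicon. Stop
#' terms (cooking techniques, appliances) and lexicon misses return `NA`.
#'
#' @param raw free-text ingredient name(s); vectorized.
#' @param lexicon a [synonym_lexicon()].
#' @return character vector of canonical keys, `NA` where unrecognized.
#' @examples
#' lex <- synonym_lexicon(c("diced scallions" = "scallion",
#'                          "chopped scallions" = "scallion"),
#'                        stop_terms = "julienne")
#' normalize_ingredient(c("Diced scallions!", "julienne", "scallion"), lex)
#' @export
normalize_ingredient <- function(raw, lexicon) {
  key <- strip_symbols(raw)
  out <- unname(lexicon$mapping[key])
  out[key %in% lexicon$stop_terms] <- NA_character_
  out
}

## classify one line into specified / vague / piece_unit / decorative
classify_line <- function(canonical, quantity_value, unit, lexicon,
                          vague_terms = VAGUE_TERMS) {
  if (!is.na(canonical) && canonical %in% lexicon$decorative_terms)
    return("decorative")
  u <- if (is.na(unit)) NA_character_ else tolower(nfc(unit))
  if ((!is.na(u) && u %in% vague_terms) || (is.na(quantity_value) && is.na(u)))
    return("vague")
  if (!is.na(u) && !(u %in% names(.mass_units)))
    return("piece_unit")
  if (is.na(quantity_value)) return("vague")
  "specified"
}

#' Impute the gram weight of one ingredient line
#'
#' Three imputation rules mirror how free-form quantities are resolved:
#' specified mass/volume quantities convert directly (ml treated as g);
#' piece-like units ("a piece of", "carton") go through the replacement
#' unit table; vague quantities ("few", "appropriate") take the corpus
#' mean of specified gram amounts for that canonical ingredient, falling
#' back to a configured default; decorative garnishes get 0 g and are
#' excluded from nutrient calculation downstream.
#'
#' @param line a one-row list/data frame with `canonical`,
#'   `quantity_value`, `unit`, `quantity_kind`.
#' @param units a [unit_table()].
#' @param corpus_means named numeric: canonical ingredient -> mean grams of
#'   its specified occurrences (see [corpus_mean_grams()]).
#' @param default_vague fallback grams for a vague quantity with no
#'   specified occurrence anywhere in the corpus (default 5 g, a typical
#'   seasoning amount).
#' @return grams (a single non-negative number).
#' @export
impute_quantity <- function(line, units, corpus_means = numeric(),
                            default_vague = 5) {
  kind <- line$quantity_kind
  if (kind == "decorative") return(0)
  if (kind == "vague") {
    m <- if (line$canonical %in% names(corpus_means))
      corpus_means[[line$canonical]] else NA_real_
    return(if (is.finite(m)) m else default_vague)
  }
  u <- tolower(nfc(line$unit))
  if (kind == "specified") {
    g1 <- .mass_units[[u]]
    return(line$quantity_value * g1)
  }
  ## piece_unit: replacement-table lookup, implied count 1 when missing
  g1 <- unit_grams(units, u, line$canonical)
  if (is.na(g1))
    stop_rm("unresolved unit '%s' (no unit-table entry)", u,
            class = "recipemine_unresolved_unit")
  (if (is.na(line$quantity_value)) 1 else line$quantity_value) * g1
}

#' Mean specified grams per canonical ingredient
#'
#' Computed over lines whose quantity is concretely specified (mass/volume
#' value or resolvable piece unit), before any vague imputation, so the
#' means do not depend on their own output.
#'
#' @param corpus a `recipe_corpus` (raw or cleaned).
#' @inheritParams impute_quantity
#' @param lexicon a [synonym_lexicon()].
#' @param vague_terms vague-quantity vocabulary.
#' @return named numeric vector of mean grams.
#' @export
corpus_mean_grams <- function(corpus, lexicon, units,
                              vague_terms = VAGUE_TERMS) {
  acc_key <- character(); acc_g <- numeric()
  for (rec in corpus) {
    ln <- rec$lines
    if (!nrow(ln)) next
    canon <- normalize_ingredient(ln$raw_name, lexicon)
    for (i in seq_len(nrow(ln))) {
      if (is.na(canon[i])) next
      kind <- classify_line(canon[i], ln$quantity_value[i], ln$unit[i],
                            lexicon, vague_terms)
      if (kind %in% c("specified", "piece_unit")) {
        g <- tryCatch(
          impute_quantity(list(canonical = canon[i],
                               quantity_value = ln$quantity_value[i],
                               unit = ln$unit[i], quantity_kind = kind),
                          units),
          recipemine_unresolved_unit = function(e) NA_real_)
        if (is.finite(g)) { acc_key <- c(acc_key, canon[i]); acc_g <- c(acc_g, g) }
      }
    }
  }
  if (!length(acc_key)) return(setNames(numeric(), character()))
  tapply(acc_g, acc_key, mean)
}

#' Clean one recipe: canonicalize, impute, or exclude
#'
#' Applies [normalize_ingredient()] then [impute_quantity()] to every
#' line, drops unrecognized lines, and excludes the recipe when no
#' canonical ingredient remains (`unrecognizable`) or exactly one remains
#' (`single_ingredient`). Duplicate canonical lines are kept (presence
#' semantics are applied downstream); decorative lines are kept with 0 g.
#'
#' @param recipe a `recipe_record`.
#' @inheritParams corpus_mean_grams
#' @param corpus_means from [corpus_mean_grams()].
#' @param default_vague see [impute_quantity()].
#' @return a list with `status` (`"kept"` or `"excluded"`), `record` (the
#'   cleaned record, when kept), `reason` (when excluded) and `dropped`
#'   (character vector of dropped raw names).
#' @export
clean_recipe <- function(recipe, lexicon, units, corpus_means = numeric(),
                         default_vague = 5, vague_terms = VAGUE_TERMS) {
  ln <- recipe$lines
  canon <- if (nrow(ln)) normalize_ingredient(ln$raw_name, lexicon) else character()
  keep <- !is.na(canon)
  dropped <- ln$raw_name[!keep]
  ln <- ln[keep, , drop = FALSE]
  canon <- canon[keep]
  if (nrow(ln)) {
    for (i in seq_len(nrow(ln))) {
      kind <- classify_line(canon[i], ln$quantity_value[i], ln$unit[i],
                            lexicon, vague_terms)
      g <- tryCatch(
        impute_quantity(list(canonical = canon[i],
                             quantity_value = ln$quantity_value[i],
                             unit = ln$unit[i], quantity_kind = kind),
                        units, corpus_means, default_vague),
        recipemine_unresolved_unit = function(e)
          stop_rm("recipe '%s': %s", recipe$id, conditionMessage(e),
                  class = "recipemine_unresolved_unit"))
      ln$canonical[i] <- canon[i]
      ln$quantity_kind[i] <- kind
      ln$grams[i] <- g
    }
  }
  n_substantive <- length(unique(ln$canonical[ln$grams > 0]))
  if (n_substantive == 0)
    return(list(status = "excluded", reason = "unrecognizable", dropped = dropped))
  if (n_substantive == 1)
    return(list(status = "excluded", reason = "single_ingredient", dropped = dropped))
  rec <- recipe
  rec$lines <- ln
  list(status = "kept", record = rec, dropped = dropped)
}

#' Preprocess a whole corpus
#'
#' Computes corpus-wide specified-gram means, then cleans every recipe.
#' Every input id lands in exactly one of `kept` or `excluded`.
#'
#' @inheritParams clean_recipe
#' @param corpus a `recipe_corpus`.
#' @return a `preprocess_outcome`: list with `kept` (`recipe_corpus`),
#'   `excluded` (data frame `id`, `reason`) and `drop_log` (data frame
#'   `id`, `raw_name`).
#' @export
preprocess_corpus <- function(corpus, lexicon, units, default_vague = 5,
                              vague_terms = VAGUE_TERMS) {
  means <- corpus_mean_grams(corpus, lexicon, units, vague_terms)
  kept <- list(); exc_id <- character(); exc_reason <- character()
  log_id <- character(); log_raw <- character()
  for (rec in corpus) {
    res <- clean_recipe(rec, lexicon, units, means, default_vague, vague_terms)
    if (length(res$dropped)) {
      log_id <- c(log_id, rep(rec$id, length(res$dropped)))
      log_raw <- c(log_raw, res$dropped)
    }
    if (res$status == "kept") {
      kept[[length(kept) + 1L]] <- res$record
    } else {
      exc_id <- c(exc_id, rec$id); exc_reason <- c(exc_reason, res$reason)
    }
  }
  structure(list(
    kept = new_corpus(kept),
    excluded = data.frame(id = exc_id, reason = exc_reason,
                          stringsAsFactors = FALSE),
    drop_log = data.frame(id = log_id, raw_name = log_raw,
                          stringsAsFactors = FALSE)),
    class = "preprocess_outcome")
}

#' Per-category recipe counts and conversion rates
#'
#' Before/after counts per cuisine category with the percentage of recipes
#' surviving preprocessing, rounded half-up to one decimal, plus a totals
#' row.
#'
#' @param before the raw `recipe_corpus` (or a named vector of per-category
#'   counts).
#' @param after a `preprocess_outcome` (or a named vector of counts).
#' @return a `corpus_stats` data frame with columns `category`, `before`,
#'   `after`, `conversion_rate`.
#' @export
corpus_stats <- function(before, after) {
  count_by <- function(x) {
    if (inherits(x, "recipe_corpus")) table(corpus_labels(x))
    else if (inherits(x, "preprocess_outcome")) table(corpus_labels(x$kept))
    else x
  }
  nb <- count_by(before); na_ <- count_by(after)
  extra <- setdiff(names(na_), names(nb))
  if (length(extra))
    stop_rm("category present after but not before preprocessing: %s",
            paste(extra, collapse = ", "), class = "recipemine_consistency_error")
  cats <- intersect(c(CUISINES, "unknown"), names(nb))
  cats <- c(cats, setdiff(names(nb), cats)) # any nonstandard categories last
  b <- as.numeric(nb[cats]); a <- as.numeric(na_[cats]); a[is.na(a)] <- 0
  if (any(a > b))
    stop_rm("after count exceeds before count", class = "recipemine_consistency_error")
  df <- data.frame(category = c(cats, "Total"),
                   before = c(b, sum(b)), after = c(a, sum(a)),
                   stringsAsFactors = FALSE)
  df$conversion_rate <- round_half_up(100 * df$after / df$before, 1)
  structure(df, class = c("corpus_stats", "data.frame"))
}
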