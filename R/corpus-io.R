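## Corpus, lexicon, unit-table and composition-table I/O.
## Recipes travel as JSON Lines (one JSON object per line) so parse errors
## are line-addressable; all CSV I/O is UTF-8 and ingredient keys are
## NFC-normalized so CJK terms compare reliably.

#' The eight cuisine categories
#'
#' Regional cuisine labels used throughout the package, plus the special
#' `"unknown"` label for non-classified recipes.
#' @export
CUISINES <- c("Chinese", "Japanese", "Korean", "Thai",
              "American", "Italian", "French", "Spanish")

## fixed alias table applied at read time; one-letter codes follow the
## C/J/K/T/A/I/F/S convention
.label_aliases <- c(
  C = "Chinese", J = "Japanese", K = "Korean", T = "Thai",
  A = "American", I = "Italian", F = "French", S = "Spanish",
  China = "Chinese", Chinese = "Chinese",
  Japan = "Japanese", Japanese = "Japanese",
  Korea = "Korean", Korean = "Korean",
  Thailand = "Thai", Thai = "Thai",
  America = "American", American = "American", US = "American", USA = "American",
  Italy = "Italian", Italian = "Italian",
  France = "French", French = "French",
  Spain = "Spanish", Spanish = "Spanish",
  N = "unknown", unknown = "unknown", Unknown = "unknown", unclassified = "unknown"
)

## strict = TRUE (file readers): anything outside the alias table is NA so
## the caller can warn and fall back to "unknown". strict = FALSE (in-memory
## construction): unrecognized labels pass through verbatim, so ad-hoc
## category names in small studies keep working.
normalize_label <- function(label, strict = FALSE) {
  if (is.null(label) || is.na(label) || !nzchar(label)) return("unknown")
  hit <- unname(.label_aliases[nfc(label)])
  if (!is.na(hit)) hit else if (strict) NA_character_ else nfc(label)
}

empty_lines_df <- function() {
  data.frame(raw_name = character(), canonical = character(),
             quantity_value = numeric(), unit = character(),
             quantity_kind = character(), grams = numeric(),
             stringsAsFactors = FALSE)
}

#' Construct a recipe record
#'
#' @param id opaque recipe identifier (unique within a corpus).
#' @param label cuisine label; aliases such as `"Japan"` or one-letter codes
#'   are normalized, anything unrecognized becomes `"unknown"` with a warning.
#' @param lines a data frame with columns `raw_name`, `quantity_value`,
#'   `unit` (further columns `canonical`, `quantity_kind`, `grams` are
#'   added/kept; missing ones are initialized to `NA`).
#' @param title optional free-text title.
#' @param strict_label if `TRUE` (the file-reader contract) labels outside
#'   the alias table become `"unknown"` with a warning; if `FALSE`
#'   (default) they pass through verbatim, so ad-hoc category names can be
#'   used in small studies.
#' @return an object of class `recipe_record`.
#' @export
recipe_record <- function(id, label = "unknown", lines = empty_lines_df(),
                          title = NA_character_, strict_label = FALSE) {
  lab <- normalize_label(label, strict = strict_label)
  if (is.na(lab)) {
    warn_rm("unrecognized cuisine label '%s' for recipe '%s'; using 'unknown'",
            label, id, class = "recipemine_label_warning")
    lab <- "unknown"
  }
  lines <- as.data.frame(lines, stringsAsFactors = FALSE)
  for (col in c("raw_name", "unit", "canonical", "quantity_kind")) {
    if (is.null(lines[[col]])) lines[[col]] <- rep(NA_character_, nrow(lines))
    lines[[col]] <- as.character(lines[[col]])
  }
  for (col in c("quantity_value", "grams")) {
    if (is.null(lines[[col]])) lines[[col]] <- rep(NA_real_, nrow(lines))
    lines[[col]] <- as.numeric(lines[[col]])
  }
  lines <- lines[c("raw_name", "canonical", "quantity_value", "unit",
                   "quantity_kind", "grams")]
  structure(list(id = as.character(id), label = lab,
                 title = if (is.null(title)) NA_character_ else as.character(title),
                 lines = lines),
            class = "recipe_record")
}

#' @export
print.recipe_record <- function(x, ...) {
  cat(sprintf("<recipe %s> [%s] %d ingredient line(s)\n",
              x$id, x$label, nrow(x$lines)))
  invisible(x)
}

new_corpus <- function(records) {
  ids <- vapply(records, `[[`, character(1), "id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop_rm("duplicate recipe id(s): %s", paste(dup, collapse = ", "),
            class = "recipemine_duplicate_id")
  structure(records, class = "recipe_corpus")
}

#' @export
print.recipe_corpus <- function(x, ...) {
  labs <- vapply(x, `[[`, character(1), "label")
  cat(sprintf("<recipe corpus> %d recipes (%d labeled, %d unknown)\n",
              length(x), sum(labs != "unknown"), sum(labs == "unknown")))
  invisible(x)
}

#' @export
`[.recipe_corpus` <- function(x, i) new_corpus(unclass(x)[i])

corpus_labels <- function(corpus) vapply(corpus, `[[`, character(1), "label")
corpus_ids <- function(corpus) vapply(corpus, `[[`, character(1), "id")

#' Read a recipe corpus from a JSON Lines file
#'
#' One JSON object per line: `{"id": ..., "label": ..., "title": ...,
#' "lines": [{"raw_name": ..., "quantity_value": ..., "unit": ...}, ...]}`.
#' Labels are normalized through a fixed alias table; unrecognized labels
#' map to `"unknown"` with a warning.
#'
#' @param path path to a `.jsonl` file (UTF-8).
#' @return a `recipe_corpus` (records in file order).
#' @seealso [write_recipes()]
#' @export
read_recipes <- function(path) {
  if (!file.exists(path)) stop_rm("recipe file not found: %s", path,
                                  class = "recipemine_io_error")
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  records <- vector("list", length(raw))
  for (k in seq_along(raw)) {
    obj <- tryCatch(jsonlite::fromJSON(raw[[k]], simplifyDataFrame = TRUE),
                    error = function(e)
                      stop_rm("malformed recipe JSON at line %d: %s", k,
                              conditionMessage(e), class = "recipemine_parse_error"))
    if (is.null(obj$id))
      stop_rm("recipe at line %d has no id", k, class = "recipemine_parse_error")
    lines <- obj$lines
    if (is.null(lines) || length(lines) == 0) lines <- empty_lines_df()
    records[[k]] <- recipe_record(obj$id, obj$label %||% "unknown",
                                  lines, obj$title %||% NA_character_,
                                  strict_label = TRUE)
  }
  new_corpus(records)
}

#' Write a recipe corpus as JSON Lines
#'
#' Inverse of [read_recipes()]: each record becomes one JSON object per
#' line. Canonicalized fields (`canonical`, `quantity_kind`, `grams`) are
#' included when present so cleaned corpora round-trip.
#'
#' @param corpus a `recipe_corpus`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recipes <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (rec in corpus) {
    obj <- list(id = rec$id, label = rec$label, title = rec$title,
                lines = rec$lines)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, na = "null",
                                dataframe = "rows", digits = NA), con)
  }
  invisible(path)
}

#' Read a synonym lexicon
#'
#' CSV with columns `raw_term, canonical, kind` where `kind` is one of
#' `synonym`, `stop`, `decorative`. Canonical keys are made fixed points of
#' the mapping; stop terms may not also be mapped synonyms.
#'
#' @param path CSV path.
#' @return an object of class `synonym_lexicon`: list with `mapping`
#'   (named character, raw term to canonical key), `stop_terms` and
#'   `decorative_terms` (character vectors of canonical keys).
#' @export
read_lexicon <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("raw_term", "canonical", "kind")
  if (!all(need %in% names(df)))
    stop_rm("lexicon is missing column(s): %s",
            paste(setdiff(need, names(df)), collapse = ", "),
            class = "recipemine_schema_error")
  synonym_lexicon(
    mapping = setNames(nfc(df$canonical[df$kind != "stop"]),
                       nfc(df$raw_term[df$kind != "stop"])),
    stop_terms = nfc(df$raw_term[df$kind == "stop"]),
    decorative_terms = nfc(unique(df$canonical[df$kind == "decorative"]))
  )
}

#' Construct a synonym lexicon
#'
#' @param mapping named character vector: raw term -> canonical key.
#' @param stop_terms non-ingredient terms (cooking techniques, appliances).
#' @param decorative_terms canonical keys of decoration/garnish ingredients.
#' @return a `synonym_lexicon`.
#' @export
synonym_lexicon <- function(mapping = character(), stop_terms = character(),
                            decorative_terms = character()) {
  ## lookup keys get the same normalization as query text (symbol strip,
  ## lower case, NFC) so matching is consistent; canonical values keep
  ## their identifier form, only case/NFC-normalized
  mapping <- setNames(tolower(nfc(unname(mapping))), strip_symbols(names(mapping)))
  stop_terms <- strip_symbols(stop_terms)
  decorative_terms <- tolower(nfc(decorative_terms))
  canon <- unique(unname(mapping))
  missing_fp <- canon[!(strip_symbols(canon) %in% names(mapping))]
  if (length(missing_fp)) # canonical keys are fixed points of the mapping
    mapping <- c(mapping, setNames(missing_fp, strip_symbols(missing_fp)))
  clash <- intersect(stop_terms, names(mapping))
  if (length(clash))
    stop_rm("term(s) both mapped and stop: %s", paste(clash, collapse = ", "),
            class = "recipemine_lexicon_error")
  structure(list(mapping = mapping, stop_terms = unique(stop_terms),
                 decorative_terms = unique(decorative_terms)),
            class = "synonym_lexicon")
}

#' Write a synonym lexicon to CSV
#' @param lexicon a `synonym_lexicon`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  df <- rbind(
    data.frame(raw_term = names(lexicon$mapping),
               canonical = unname(lexicon$mapping),
               kind = ifelse(unname(lexicon$mapping) %in% lexicon$decorative_terms,
                             "decorative", "synonym"),
               stringsAsFactors = FALSE),
    if (length(lexicon$stop_terms))
      data.frame(raw_term = lexicon$stop_terms, canonical = "",
                 kind = "stop", stringsAsFactors = FALSE)
  )
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a unit-to-grams table
#'
#' CSV with columns `unit_phrase, ingredient_class, grams` (the
#' `ingredient_class` column may be empty for generic units). Grams must be
#' strictly positive.
#'
#' @param path CSV path.
#' @return a `unit_table` data frame.
#' @export
read_unit_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("unit_phrase", "ingredient_class", "grams")
  if (!all(need %in% names(df)))
    stop_rm("unit table is missing column(s): %s",
            paste(setdiff(need, names(df)), collapse = ", "),
            class = "recipemine_schema_error")
  unit_table(df)
}

#' Construct a unit table
#' @param df data frame with columns `unit_phrase`, `ingredient_class`
#'   (NA/empty for generic entries) and `grams` (> 0).
#' @return a `unit_table`.
#' @export
unit_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$unit_phrase <- nfc(as.character(df$unit_phrase))
  df$ingredient_class <- as.character(df$ingredient_class)
  df$ingredient_class[is.na(df$ingredient_class)] <- ""
  df$grams <- as.numeric(df$grams)
  if (any(!is.finite(df$grams) | df$grams <= 0))
    stop_rm("unit table grams must be > 0", class = "recipemine_unit_error")
  structure(df[c("unit_phrase", "ingredient_class", "grams")],
            class = c("unit_table", "data.frame"))
}

## grams for one unit phrase, preferring an ingredient-class-specific row
unit_grams <- function(units, unit, ingredient_class = "") {
  u <- nfc(unit)
  hit <- units$unit_phrase == u &
    units$ingredient_class == (ingredient_class %||% "")
  if (!any(hit)) hit <- units$unit_phrase == u & units$ingredient_class == ""
  if (!any(hit)) return(NA_real_)
  units$grams[which(hit)[1]]
}

.nutrient_cols <- c("carbohydrate_g", "protein_g", "fat_g", "saturated_fat_g",
                    "fiber_g", "sugar_g", "sodium_mg")

#' Read a food-composition table
#'
#' CSV with columns `ingredient` plus the seven per-100g nutrients
#' `carbohydrate_g, protein_g, fat_g, saturated_fat_g, fiber_g, sugar_g,
#' sodium_mg`. Rows violating the soft consistency checks (sugar above
#' carbohydrate, saturated fat above fat, macronutrients above 100 g) are
#' loaded with a validation warning — real composition tables contain
#' rounding violations. Negative values are hard errors.
#'
#' @param path CSV path.
#' @param substitutes optional CSV path with columns `from, to` mapping
#'   unlinked ingredients to their closest tabulated ingredient.
#' @return an object of class `nutrient_db`: list with `table` (data frame
#'   keyed by `ingredient`, with derived `energy_kcal` and a logical
#'   `valid` flag) and `substitutes` (named character vector).
#' @export
read_nutrient_db <- function(path, substitutes = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("ingredient", .nutrient_cols)
  if (!all(need %in% names(df)))
    stop_rm("nutrient table is missing column(s): %s",
            paste(setdiff(need, names(df)), collapse = ", "),
            class = "recipemine_schema_error")
  sub_map <- character()
  if (!is.null(substitutes)) {
    sm <- utils::read.csv(substitutes, stringsAsFactors = FALSE, encoding = "UTF-8")
    if (!all(c("from", "to") %in% names(sm)))
      stop_rm("substitute map needs columns from,to", class = "recipemine_schema_error")
    sub_map <- setNames(nfc(sm$to), nfc(sm$from))
  }
  nutrient_db(df, substitutes = sub_map)
}

#' Construct a nutrient database
#' @param df data frame with `ingredient` and the seven nutrient columns.
#' @param substitutes named character vector: unmapped ingredient -> closest
#'   ingredient present in `df`.
#' @return a `nutrient_db`.
#' @export
nutrient_db <- function(df, substitutes = character()) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$ingredient <- nfc(as.character(df$ingredient))
  for (col in .nutrient_cols) df[[col]] <- as.numeric(df[[col]])
  bad_rows <- which(apply(df[.nutrient_cols], 1, function(v) any(!is.finite(v) | v < 0)))
  if (length(bad_rows))
    stop_rm("negative or non-numeric nutrient value in row(s): %s",
            paste(bad_rows, collapse = ", "), class = "recipemine_row_error")
  valid <- df$sugar_g <= df$carbohydrate_g + 1e-9 &
    df$saturated_fat_g <= df$fat_g + 1e-9 &
    df$carbohydrate_g + df$protein_g + df$fat_g <= 100 + 1e-9
  if (any(!valid))
    warn_rm("%d composition row(s) violate nutrient consistency checks (kept, flagged)",
            sum(!valid), class = "recipemine_validation_warning")
  df$valid <- valid
  df$energy_kcal <- energy(df)
  if (length(substitutes)) {
    missing_target <- setdiff(unname(substitutes), df$ingredient)
    if (length(missing_target))
      stop_rm("substitute target(s) absent from table: %s",
              paste(missing_target, collapse = ", "),
              class = "recipemine_schema_error")
  }
  structure(list(table = df[c("ingredient", .nutrient_cols, "energy_kcal", "valid")],
                 substitutes = substitutes),
            class = "nutrient_db")
}

#' @export
print.nutrient_db <- function(x, ...) {
  cat(sprintf("<nutrient db> %d ingredients, %d substitute(s)\n",
              nrow(x$table), length(x$substitutes)))
  invisible(x)
}

## per-100g vector lookup; NA-row of length 7 when absent
db_lookup <- function(db, ingredient) {
  i <- match(ingredient, db$table$ingredient)
  if (is.na(i)) return(NULL)
  as.numeric(db$table[i, .nutrient_cols])
}
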