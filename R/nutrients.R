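## Per-100g nutrient profiles of recipes via the composition table, energy
## from the 4/4/9 kcal/g factors, and the nutrient Pearson correlation
## matrix. Profiles use raw ingredient mass (cooking losses are not
## modeled); sodium stays in mg/100 g — correlations are unit-invariant.

#' Energy from macronutrients (4/4/9 kcal per gram)
#'
#' Carbohydrate and protein provide 4 kcal/g, fat 9 kcal/g; dietary fiber
#' and sodium provide none.
#'
#' @param v a named numeric nutrient vector or a data frame with columns
#'   `carbohydrate_g`, `protein_g`, `fat_g`.
#' @return energy in kcal per 100 g.
#' @examples
#' energy(c(carbohydrate_g = 20, protein_g = 5, fat_g = 10)) # 190
#' @export
energy <- function(v) {
  if (is.data.frame(v))
    4 * v$carbohydrate_g + 4 * v$protein_g + 9 * v$fat_g
  else
    4 * v[["carbohydrate_g"]] + 4 * v[["protein_g"]] + 9 * v[["fat_g"]]
}

#' Per-100g nutrient profile of one recipe
#'
#' Mass-weighted mean of the ingredients' per-100g nutrient densities over
#' all substantive (non-decorative, positive-gram) lines, normalized to
#' 100 g of total raw ingredient mass. Ingredients absent from the table
#' are resolved through the database's substitute map; unmapped
#' ingredients below `low_usage_threshold` of total recipe mass are
#' dropped from the calculation, and anything heavier raises an error.
#'
#' @param recipe a cleaned `recipe_record` (canonical names and grams set).
#' @param db a [nutrient_db()].
#' @param low_usage_threshold mass fraction below which an unmapped
#'   ingredient is silently excluded (default 0.02).
#' @return named numeric vector: the seven nutrients plus `energy_kcal`,
#'   with attribute `dropped` listing excluded unmapped ingredients.
#' @export
recipe_nutrients <- function(recipe, db, low_usage_threshold = 0.02) {
  ln <- recipe$lines
  keep <- !is.na(ln$canonical) & !is.na(ln$grams) & ln$grams > 0 &
    ln$quantity_kind != "decorative"
  ln <- ln[keep, , drop = FALSE]
  total_mass <- sum(ln$grams)
  if (!nrow(ln) || total_mass <= 0)
    stop_rm("recipe '%s' has no substantive mass", recipe$id,
            class = "recipemine_zero_mass")
  dropped <- character()
  acc <- setNames(numeric(length(.nutrient_cols)), .nutrient_cols)
  used_mass <- 0
  for (i in seq_len(nrow(ln))) {
    key <- ln$canonical[i]
    row <- db_lookup(db, key)
    if (is.null(row) && key %in% names(db$substitutes))
      row <- db_lookup(db, db$substitutes[[key]])
    if (is.null(row)) {
      if (ln$grams[i] / total_mass < low_usage_threshold) {
        dropped <- c(dropped, key)
        next
      }
      stop_rm("recipe '%s': ingredient '%s' (%.1f%% of mass) not in composition table and no substitute",
              recipe$id, key, 100 * ln$grams[i] / total_mass,
              class = "recipemine_unmapped_ingredient")
    }
    acc <- acc + ln$grams[i] * row
    used_mass <- used_mass + ln$grams[i]
  }
  if (used_mass <= 0)
    stop_rm("recipe '%s': all mass excluded from nutrient calculation",
            recipe$id, class = "recipemine_zero_mass")
  profile <- acc / used_mass # per-100g in, per-100g out
  out <- c(profile, energy_kcal = unname(energy(profile)))
  attr(out, "dropped") <- unique(dropped)
  out
}

#' Nutrient profile matrix for a corpus
#'
#' @param corpus a cleaned `recipe_corpus`.
#' @inheritParams recipe_nutrients
#' @return matrix (recipes x 8) of the seven nutrients plus `energy_kcal`,
#'   rownames = recipe ids.
#' @export
corpus_nutrients <- function(corpus, db, low_usage_threshold = 0.02) {
  rows <- lapply(corpus, function(rec)
    recipe_nutrients(rec, db, low_usage_threshold))
  out <- do.call(rbind, rows)
  rownames(out) <- corpus_ids(corpus)
  out
}

#' Pearson correlation matrix of nutrients and energy
#'
#' @param profiles matrix from [corpus_nutrients()] (>= 3 recipes).
#' @return symmetric correlation matrix with unit diagonal; columns with
#'   zero variance give `NA` rows/columns and are listed in the
#'   `undefined` attribute (with a warning), never silently 0.
#' @export
nutrient_correlations <- function(profiles) {
  if (nrow(profiles) < 3)
    stop_rm("need at least 3 recipes for correlations",
            class = "recipemine_too_few")
  sds <- apply(profiles, 2, stats::sd)
  constant <- colnames(profiles)[sds == 0]
  if (length(constant))
    warn_rm("constant column(s), correlation undefined: %s",
            paste(constant, collapse = ", "),
            class = "recipemine_constant_column")
  cm <- suppressWarnings(stats::cor(profiles, method = "pearson"))
  d <- diag(cm)
  d[!(colnames(profiles) %in% constant)] <- 1
  d[colnames(profiles) %in% constant] <- NA_real_ # 0/0, undefined
  diag(cm) <- d
  attr(cm, "undefined") <- constant
  cm
}
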