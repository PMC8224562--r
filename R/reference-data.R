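## Aggregate reference counts for the iCook.tw recipe corpus. The corpus
## itself (and the TFDA composition table) is not redistributable; only
## these published per-category totals ship with the package, as inputs
## for arithmetic checks and for scaling synthetic corpora realistically.

#' Reference per-category recipe counts (iCook.tw corpus)
#'
#' Recipe counts per cuisine category before and after preprocessing of
#' the original ~15k-recipe corpus, with the conversion rates as
#' originally reported. Note the reported rates are not all consistent
#' with half-up rounding of the counts themselves (e.g. 1211/1321 =
#' 91.7%, reported 91.6%); recompute with [corpus_stats()] semantics when
#' exact arithmetic matters.
#'
#' @return data frame `category`, `before`, `after`, `reported_rate`.
#' @export
icook_reference_counts <- function() {
  utils::read.csv(system.file("extdata", "icook_reference_counts.csv",
                              package = "recipemine", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Reference predicted-category distribution of unclassified recipes
#'
#' How the 5349 preprocessed non-classified recipes of the reference
#' corpus were distributed over the eight cuisines by the best
#' cross-validated classifier (linear SVM).
#'
#' @return data frame `category`, `count`.
#' @export
icook_predicted_distribution <- function() {
  utils::read.csv(system.file("extdata", "icook_predicted_distribution.csv",
                              package = "recipemine", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
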