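#' Round half away from zero
#'
#' Commercial ("half-up") rounding to a fixed number of decimals. Base R's
#' `round()` rounds half to even, which is the wrong convention for
#' reporting conversion percentages.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' round_half_up(c(0.5, 1.5, 91.65), c(0, 0, 1))
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## NFC normalization + trim; tolerant of NA
nfc <- function(x) {
  out <- stringi::stri_trans_nfc(x)
  stringi::stri_trim_both(out)
}

stop_rm <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "recipemine_error")))
}

warn_rm <- function(fmt, ..., class = "recipemine_warning") {
  warning(warningCondition(sprintf(fmt, ...), class = c(class, "recipemine_warning")))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 means identical partitions, 0 is the expected value for independent
#' random partitions.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return a single number in \[-1, 1\].
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y"))
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1) # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

## deterministic child seed derived from a user seed; kept below 2^31
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) * 7L + 13L
}
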