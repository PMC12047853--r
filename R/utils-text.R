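#' Normalize text for lexicon matching
#'
#' Lowercases, folds accents to ASCII (e.g. \code{"épuisée"} to
#' \code{"epuisee"}) and collapses runs of whitespace. All lexicon matching in
#' the package operates on folded text because case and diacritics vary wildly
#' in forum writing.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @export
fold_text <- function(x) {
  x <- stringi::stri_trans_general(tolower(as.character(x)), "Latin-ASCII")
  stringi::stri_replace_all_regex(x, "\\s+", " ")
}

# Build a boundary-anchored regex for one folded term. Multi-word terms match
# across any whitespace; apostrophes in terms match both ' and folded variants.
term_regex <- function(term) {
  term <- fold_text(term)
  esc <- stringi::stri_replace_all_regex(term, "([.^$*+?()\\[\\]{}|\\\\])", "\\\\$1")
  esc <- stringi::stri_replace_all_fixed(esc, " ", "\\s+")
  paste0("\\b", esc, "\\b")
}

#' Count lexicon term occurrences in text
#'
#' Matches each term of `terms` case- and accent-insensitively on token
#' boundaries and returns the total number of occurrences per element of `x`.
#'
#' @param x character vector of texts (raw; folding is applied internally).
#' @param terms character vector of terms or phrases.
#' @return integer vector, total hits per text.
#' @export
count_term_hits <- function(x, terms) {
  folded <- fold_text(x)
  hits <- integer(length(x))
  for (term in terms) {
    hits <- hits + stringi::stri_count_regex(folded, term_regex(term))
  }
  hits
}

#' Test whether any lexicon term occurs in text
#'
#' @inheritParams count_term_hits
#' @return logical vector.
#' @export
matches_any_term <- function(x, terms) {
  folded <- fold_text(x)
  out <- rep(FALSE, length(x))
  for (term in terms) {
    out <- out | stringi::stri_detect_regex(folded, term_regex(term))
    if (all(out)) break
  }
  out
}

# Simple whitespace/punctuation tokenizer on folded text.
fold_tokens <- function(x) {
  toks <- stringi::stri_split_regex(fold_text(x), "[^a-z0-9']+")
  lapply(toks, function(t) t[nzchar(t)])
}

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going up (0.5 -> 1), the convention
#' used in all printed percentage tables, as opposed to base R's banker
#' rounding.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # the epsilon absorbs binary-representation error just below .5 boundaries
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Percentage with explicit denominator and half-up rounding
#'
#' @param count numeric numerator.
#' @param denominator numeric denominator.
#' @param digits decimal places of the printed percentage.
#' @return numeric vector of rounded percentages (0 where denominator is 0).
#' @export
percentage <- function(count, denominator, digits = 0) {
  raw <- 100 * count / denominator
  out <- round_half_up(raw, digits)
  out[!is.finite(raw)] <- 0
  out
}
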