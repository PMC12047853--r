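# Corpus inclusion and the exclusion cascade: a message enters the analysis
# corpus iff it contains an antibiotic keyword (or synonym) AND a phrase of
# the inefficiency lexical field, and then survives removal of non-French
# messages, animal-related messages and messages carrying a study-specific
# exclusion word. Rules are exact (lexicon driven), not statistical.

# regex for the "ne <up to gap tokens> VERB ... pas" negation family around
# efficacy verbs, on folded text
negation_regex <- function(verbs, gap = 5) {
  paste0(
    "\\bne\\s+(?:[a-z']+\\s+){0,", gap, "}?(?:",
    paste(verbs, collapse = "|"),
    ")\\b[a-z' ]{0,30}?\\bpas\\b"
  )
}

#' Inclusion rule: antibiotic keyword conjoined with inefficiency
#'
#' A message is included iff at least one inclusion keyword or synonym AND
#' at least one inefficiency-field phrase both occur in the same message.
#' The inefficiency field combines fixed phrases with a bounded-gap
#' negation pattern ("ne ... pas" around an efficacy verb, at most
#' `gap` intervening tokens). Matching is case- and accent-insensitive on
#' token boundaries.
#'
#' @param text character vector of message texts (or a posts data frame,
#'   whose `text` column is used).
#' @param lexicons a lexicon set.
#' @param gap maximum tokens between "ne" and the efficacy verb.
#' @return logical vector.
#' @export
matches_inclusion <- function(text, lexicons = default_lexicons(), gap = 5) {
  if (is.data.frame(text)) text <- text$text
  has_kw <- matches_any_term(text, lexicons$inclusion_keywords)
  has_ineff <- matches_any_term(text, lexicons$inefficiency_field)
  verbs <- lexicons$inefficiency_negation_verbs
  if (length(verbs) > 0) {
    has_ineff <- has_ineff |
      stringi::stri_detect_regex(fold_text(text), negation_regex(verbs, gap))
  }
  has_kw & has_ineff
}

#' Stopword-profile language detection
#'
#' Scores each text against per-language function-word profiles and returns
#' the highest-scoring tag. Texts with fewer than `min_tokens` tokens, or
#' with no profile hit at all, are tagged `"undetermined"` (and are kept by
#' the filter: absence of evidence is not evidence of a foreign language).
#' Ties are resolved in favour of the target language, then alphabetically.
#'
#' @param text character vector.
#' @param lexicons lexicon set carrying `language_profiles` and
#'   `target_language`.
#' @param min_tokens minimum token count below which the tag is
#'   `"undetermined"`.
#' @return character vector of language tags.
#' @export
detect_language <- function(text, lexicons = default_lexicons(), min_tokens = 4) {
  if (is.data.frame(text)) text <- text$text
  toks <- fold_tokens(text)
  profiles <- lapply(lexicons$language_profiles, fold_text)
  langs <- names(profiles)
  target <- lexicons$target_language
  ord <- c(target, sort(setdiff(langs, target))) # tie-break preference
  vapply(toks, function(t) {
    if (length(t) < min_tokens) return("undetermined")
    score <- vapply(profiles, function(p) sum(t %in% p), numeric(1))
    if (all(score == 0)) return("undetermined")
    ord[which.max(score[ord])]
  }, character(1))
}

#' Exclusion cascade over an inclusion-matching corpus
#'
#' Applies the removal rules in a fixed order -- non-target language, animal
#' vocabulary, study exclusion word -- attributing every removed post to the
#' first rule that fires, and returns the analysis corpus together with a
#' balancing filter report.
#'
#' @param posts data frame of posts that already pass [matches_inclusion()].
#' @param lexicons lexicon set.
#' @return list with `corpus` (kept posts), `report` (class
#'   `abx_filter_report`) and `removed` (removed posts with a `reason`
#'   column).
#' @export
apply_exclusions <- function(posts, lexicons = default_lexicons()) {
  n <- nrow(posts)
  if (is.null(n) || n == 0) {
    report <- new_filter_report(0L, c(non_target_language = 0L,
                                      animal_vocabulary = 0L,
                                      exclusion_word = 0L), 0L)
    return(list(corpus = posts, report = report,
                removed = cbind(posts, reason = character(0))))
  }
  reason <- rep(NA_character_, n)
  lang <- detect_language(posts$text, lexicons)
  foreign <- !lang %in% c(lexicons$target_language, "undetermined")
  reason[foreign] <- "non_target_language"
  todo <- is.na(reason)
  animal <- todo & matches_any_term(posts$text, lexicons$animal_vocabulary)
  reason[animal] <- "animal_vocabulary"
  todo <- is.na(reason)
  excl <- todo & matches_any_term(posts$text, lexicons$exclusion_words)
  reason[excl] <- "exclusion_word"
  kept <- is.na(reason)
  removed_counts <- c(
    non_target_language = sum(reason == "non_target_language", na.rm = TRUE),
    animal_vocabulary = sum(reason == "animal_vocabulary", na.rm = TRUE),
    exclusion_word = sum(reason == "exclusion_word", na.rm = TRUE)
  )
  removed <- posts[!kept, , drop = FALSE]
  removed$reason <- reason[!kept]
  list(
    corpus = posts[kept, , drop = FALSE],
    report = new_filter_report(n, removed_counts, sum(kept)),
    removed = removed
  )
}

new_filter_report <- function(input, removed, output) {
  stopifnot(input == output + sum(removed))
  structure(
    list(input = as.integer(input),
         removed = vapply(removed, as.integer, integer(1)),
         output = as.integer(output)),
    class = "abx_filter_report"
  )
}

#' @export
print.abx_filter_report <- function(x, ...) {
  cat("Corpus filter report\n")
  cat("  input posts:  ", x$input, "\n")
  for (r in names(x$removed)) {
    cat(sprintf("  removed (%s): %d\n", r, x$removed[[r]]))
  }
  cat("  analysis corpus:", x$output, "\n")
  invisible(x)
}

#' Full corpus filter: inclusion rule plus exclusion cascade
#'
#' Convenience wrapper that first drops posts failing the
#' keyword-and-inefficiency inclusion rule (attributed `no_inclusion`),
#' then runs [apply_exclusions()] on the remainder. The report counts both
#' stages and always balances: input = output + sum(removed).
#'
#' @inheritParams apply_exclusions
#' @return list with `corpus`, `report`, and `reasons` (a data frame of
#'   post id and attributed reason, `"kept"` for surviving posts).
#' @export
filter_corpus <- function(posts, lexicons = default_lexicons()) {
  incl <- matches_inclusion(posts$text, lexicons)
  staged <- apply_exclusions(posts[incl, , drop = FALSE], lexicons)
  removed <- c(no_inclusion = sum(!incl), staged$report$removed)
  report <- new_filter_report(nrow(posts), removed, staged$report$output)
  reasons <- data.frame(id = posts$id, reason = "kept",
                        stringsAsFactors = FALSE)
  reasons$reason[!incl] <- "no_inclusion"
  reasons$reason[match(staged$removed$id, reasons$id)] <- staged$removed$reason
  list(corpus = staged$corpus, report = report, reasons = reasons)
}

#' Anonymize a post
#'
#' Replaces the author handle by a salted one-way hash and masks @-mentions
#' and URLs in the text with fixed placeholders. Idempotent: applying it
#' twice yields the output of the first application.
#'
#' @param posts posts data frame.
#' @param salt character salt for the keyed hash.
#' @return the posts data frame with hashed authors and masked text.
#' @export
anonymize_posts <- function(posts, salt = "abxtalk") {
  hash_one <- function(author) {
    if (grepl("^anon[0-9a-f]{12}$", author)) return(author) # already hashed
    digest_hex(paste0(salt, ":", author))
  }
  posts$author <- vapply(posts$author, hash_one, character(1), USE.NAMES = FALSE)
  txt <- posts$text
  txt <- stringi::stri_replace_all_regex(txt, "(https?://|www\\.)[^\\s]+", "<URL>")
  txt <- stringi::stri_replace_all_regex(txt, "(?<![\\w<])@[A-Za-z0-9_.-]+", "<USER>")
  posts$text <- txt
  posts
}

# small multiplicative hex digest (two independent 32-bit accumulators kept
# exact in doubles); stable across platforms, not cryptographic --
# sufficient for pseudonymization of research corpora
digest_hex <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h1 <- 2166136261; h2 <- 40389
  for (b in bytes) {
    h1 <- (h1 * 69069 + b) %% 4294967296
    h2 <- (h2 * 30269 + b * 131) %% 4294967296
  }
  hex32 <- function(h) sprintf("%04x%04x", as.integer(h %/% 65536),
                               as.integer(h %% 65536))
  paste0("anon", hex32(h1), substr(hex32(h2), 1, 4))
}
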