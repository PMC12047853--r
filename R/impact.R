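# Two-stage quality-of-life impact classifier: a binary gate decides
# whether a message expresses any QoL impact at all; five one-vs-rest
# gradient-boosted models then flag the impacted domains (physical,
# psychic, activity, relational, financial). One message may carry several
# domains. All six models share one feature extractor built from
# sentiment, grammar/conjugation and per-domain lexical-field signals.

.qol_categories <- c("physical", "psychic", "activity", "relational", "financial")

#' Extract the QoL feature vector of one or more messages
#'
#' Deterministic counts and rates per feature family: sentiment-lexicon
#' hits, first-person pronoun count, verb-tense markers (past participle /
#' present / conditional-imperfect endings), negation count, one hit count
#' per QoL-domain lexical field, punctuation and message length. Count
#' features are exactly additive over text concatenation.
#'
#' @param text character vector of message texts.
#' @param lexicons lexicon set with sentiment and `qol_domains` families.
#' @return numeric matrix, one row per message, fixed column order.
#' @export
extract_features <- function(text, lexicons = default_lexicons()) {
  if (is.data.frame(text)) text <- text$text
  folded <- fold_text(text)
  toks <- fold_tokens(text)
  n_tok <- vapply(toks, length, numeric(1))
  feats <- cbind(
    n_pos_sentiment = count_term_hits(text, lexicons$sentiment_positive),
    n_neg_sentiment = count_term_hits(text, lexicons$sentiment_negative),
    n_first_person = vapply(toks, function(t) {
      sum(t %in% c("je", "j'ai", "j", "me", "moi", "mon", "ma", "mes"))
    }, numeric(1)),
    n_past = stringi::stri_count_regex(folded, "\\b(?:ai|a|avais|avait)\\s+[a-z]+[eiu]s?\\b"),
    n_present = stringi::stri_count_regex(folded, "\\b(?:suis|est|sont|fait|prends?|continue)\\b"),
    n_conditional = stringi::stri_count_regex(folded, "\\b[a-z]+r(?:ais|ait|aient)\\b"),
    n_negation = stringi::stri_count_regex(folded, "\\b(?:ne|n'|pas|plus|jamais|rien|aucune?)\\b"),
    n_exclaim = stringi::stri_count_fixed(text, "!"),
    n_tokens = n_tok
  )
  dom <- vapply(.qol_categories, function(cat) {
    count_term_hits(text, lexicons$qol_domains[[cat]])
  }, numeric(length(text)))
  dom <- matrix(dom, nrow = length(text),
                dimnames = list(NULL, paste0("qol_", .qol_categories)))
  cbind(feats, dom)
}

fit_binary_xgb <- function(features, label, name, nrounds, max_depth, eta,
                           seed, balance = FALSE) {
  if (length(unique(label)) < 2) {
    stop("cannot train '", name, "' model: its target has a single class")
  }
  dtrain <- xgboost::xgb.DMatrix(as.matrix(features), label = as.numeric(label))
  params <- list(objective = "binary:logistic", max_depth = max_depth,
                 eta = eta, nthread = 1, seed = seed)
  # rare domains (e.g. financial, ~1% of impact posts) need reweighting for
  # their probabilities to saturate past the decision threshold
  if (balance) params$scale_pos_weight <- sum(!label) / sum(label)
  xgboost::xgb.train(params, dtrain, nrounds = nrounds, verbose = 0)
}

#' Train the two-stage impact classifier
#'
#' Fits one gate model (any impact vs none) on all labeled posts and five
#' one-vs-rest domain models on the impact-positive posts only, all
#' gradient-boosted trees with a fixed seed for reproducible training.
#'
#' @param features numeric matrix from [extract_features()].
#' @param has_impact logical vector, gate label.
#' @param categories logical matrix (posts x 5) named by the QoL domains.
#' @param nrounds,max_depth,eta boosting parameters (defaults 200 rounds,
#'   depth 4).
#' @param seed integer seed.
#' @return object of class `abx_impact_models`.
#' @export
impact_train <- function(features, has_impact, categories,
                         nrounds = 200, max_depth = 4, eta = 0.3, seed = 1L) {
  stopifnot(nrow(features) == length(has_impact),
            nrow(features) == nrow(categories))
  if (!all(.qol_categories %in% colnames(categories))) {
    stop("categories must have columns ", paste(.qol_categories, collapse = ", "))
  }
  set.seed(seed)
  gate <- fit_binary_xgb(features, has_impact, "impact gate",
                         nrounds, max_depth, eta, seed)
  pos <- which(has_impact)
  if (length(pos) < 2) stop("too few impact-positive posts to train domain models")
  cat_models <- lapply(.qol_categories, function(cat) {
    fit_binary_xgb(features[pos, , drop = FALSE], categories[pos, cat],
                   paste0("category '", cat, "'"), nrounds, max_depth, eta,
                   seed, balance = TRUE)
  })
  names(cat_models) <- .qol_categories
  structure(
    list(gate = gate, categories = cat_models,
         feature_names = colnames(features), seed = seed,
         format = "abxtalk-impact", version = 1L),
    class = "abx_impact_models"
  )
}

#' Classify messages with the two-stage algorithm
#'
#' Stage 1 scores the gate; only for messages whose gate probability
#' reaches `threshold` are the five domain models evaluated, and several
#' domains may fire on one message. Gate-negative messages always have an
#' empty category set.
#'
#' @param models `abx_impact_models` bundle.
#' @param features numeric matrix from [extract_features()].
#' @param threshold decision threshold shared by all six models.
#' @return data frame of class `abx_impact_prediction`: `gate_prob`,
#'   `has_impact`, one probability and one flag column per domain.
#' @export
impact_classify <- function(models, features, threshold = 0.5) {
  if (!inherits(models, "abx_impact_models")) {
    stop("untrained impact bundle: call impact_train() first")
  }
  features <- as.matrix(features)[, models$feature_names, drop = FALSE]
  d <- xgboost::xgb.DMatrix(features)
  gate_prob <- predict(models$gate, d)
  has_impact <- gate_prob >= threshold
  out <- data.frame(gate_prob = gate_prob, has_impact = has_impact)
  for (cat in .qol_categories) {
    p <- predict(models$categories[[cat]], d)
    out[[paste0("prob_", cat)]] <- p
    out[[cat]] <- has_impact & (p >= threshold)
  }
  class(out) <- c("abx_impact_prediction", class(out))
  out
}

#' Summarize impact predictions under both percentage conventions
#'
#' Emits, per QoL domain, (a) the share of impact-bearing messages that
#' carry the domain (message-share, the "78% of messages" convention) and
#' (b) the domain's share of all domain mentions (mention-share, the
#' summary-table convention), always printing the denominators. Percentages
#' are rounded half-up to integers.
#'
#' @param predictions an `abx_impact_prediction` data frame, or a named
#'   numeric vector of per-domain counts.
#' @param n_messages total messages scored; taken from `predictions` when
#'   it is a prediction frame.
#' @param n_impact number of impact-bearing messages; derived when absent.
#' @return data frame: category, count, message-share and mention-share
#'   percentages with their denominators.
#' @export
impact_summary <- function(predictions, n_messages = NULL, n_impact = NULL) {
  if (is.data.frame(predictions)) {
    counts <- vapply(.qol_categories,
                     function(cat) sum(predictions[[cat]]), numeric(1))
    if (is.null(n_messages)) n_messages <- nrow(predictions)
    if (is.null(n_impact)) n_impact <- sum(predictions$has_impact)
  } else {
    counts <- predictions[.qol_categories]
    if (is.null(n_impact)) stop("n_impact is required with raw counts")
    if (is.null(n_messages)) n_messages <- NA_integer_
  }
  total_mentions <- sum(counts)
  out <- data.frame(
    category = .qol_categories,
    count = as.numeric(counts),
    message_share_pct = percentage(as.numeric(counts), n_impact),
    message_denominator = n_impact,
    mention_share_pct = percentage(as.numeric(counts), total_mentions),
    mention_denominator = total_mentions,
    stringsAsFactors = FALSE
  )
  attr(out, "n_messages") <- n_messages
  attr(out, "impact_rate_pct") <- if (!is.na(n_messages) && n_messages > 0) {
    percentage(n_impact, n_messages)
  } else NA_real_
  out
}
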