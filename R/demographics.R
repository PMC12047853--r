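# User demographics: scored gender prediction from username + message
# content, and age via regular expressions with a gradient-boosted model
# fallback for users who never state their age.

#' Score gender evidence for one user
#'
#' Evidence is additive: a first name in the username contributes
#' `weight_name` (default 3, names being the strongest signal), a gendered
#' username affix `weight_affix`, each gendered lexical-field phrase and
#' each gendered adjective/participle agreement in the user's messages 1
#' per occurrence. Scores are sums, hence nonnegative, permutation-invariant
#' over posts and monotone as posts are added.
#'
#' @param username the user's handle.
#' @param texts character vector of the user's message texts (may be empty).
#' @param lexicons lexicon set with name/affix/phrase/agreement families.
#' @param weight_name,weight_affix evidence weights for username matches.
#' @return named numeric vector `c(female = ..., male = ...)`.
#' @export
score_gender <- function(username, texts = character(0),
                         lexicons = default_lexicons(),
                         weight_name = 3, weight_affix = 1) {
  uname <- fold_text(username)
  f <- 0; m <- 0
  # names and affixes are matched as substrings of the handle ("marie75")
  if (any(vapply(lexicons$female_names, function(n) grepl(n, uname, fixed = TRUE),
                 logical(1)))) f <- f + weight_name
  if (any(vapply(lexicons$male_names, function(n) grepl(n, uname, fixed = TRUE),
                 logical(1)))) m <- m + weight_name
  if (any(vapply(lexicons$female_affixes, function(n) grepl(n, uname, fixed = TRUE),
                 logical(1)))) f <- f + weight_affix
  if (any(vapply(lexicons$male_affixes, function(n) grepl(n, uname, fixed = TRUE),
                 logical(1)))) m <- m + weight_affix
  if (length(texts) > 0) {
    f <- f + sum(count_term_hits(texts, lexicons$female_phrases)) +
      sum(count_term_hits(texts, lexicons$female_agreements))
    m <- m + sum(count_term_hits(texts, lexicons$male_phrases)) +
      sum(count_term_hits(texts, lexicons$male_agreements))
  }
  c(female = f, male = m)
}

#' Predict gender from scores
#'
#' @param scores output of [score_gender()].
#' @return `"female"`, `"male"`, or `"unknown"` on a tie (including 0-0).
#' @export
predict_gender <- function(scores) {
  if (scores[["female"]] > scores[["male"]]) "female"
  else if (scores[["male"]] > scores[["female"]]) "male"
  else "unknown"
}

# ---- age: regular expressions -------------------------------------------

# guard tokens that turn "N ans" into a duration, not an age, when they
# occur among the three tokens preceding the number ("depuis 20 ans",
# "j'ai pris 3 ans", "il y a 20 ans")
.age_guards <- c("pris", "prends", "pendant", "depuis", "dans", "apres",
                 "fait", "attendu", "dure", "y")

age_matches_one <- function(text, year) {
  folded <- fold_text(text)
  ages <- numeric(0)
  # "N ans" family ("j'ai 34 ans", "maman, 41 ans"), with duration guards
  locs <- stringi::stri_locate_all_regex(folded, "\\b\\d{1,3}\\s+ans\\b")[[1]]
  if (!all(is.na(locs))) {
    for (r in seq_len(nrow(locs))) {
      frag <- substr(folded, locs[r, 1], locs[r, 2])
      val <- as.numeric(stringi::stri_extract_first_regex(frag, "\\d+"))
      prefix <- fold_tokens(substr(folded, 1, locs[r, 1] - 1))[[1]]
      ctx <- utils::tail(prefix, 3)
      if (!any(ctx %in% .age_guards)) ages <- c(ages, val)
    }
  }
  # birth year: "nee en 1985" / "ne en 1985", converted with the post year
  m <- stringi::stri_match_all_regex(folded, "\\bnee?\\s+en\\s+((?:19|20)\\d{2})\\b")[[1]]
  if (!all(is.na(m))) ages <- c(ages, year - as.numeric(m[, 2]))
  ages[ages >= 10 & ages <= 100]
}

#' Extract a user's age by regular expressions
#'
#' Scans all of a user's posts for age statements of the families
#' "j'ai N ans", bare "N ans" (with duration guards such as "depuis",
#' "pendant", "pris"), and "ne(e) en YYYY" converted using the post's
#' timestamp. Values outside 10-100 years are rejected. Multiple matches
#' are resolved by majority, ties by the most recent post carrying a
#' majority value.
#'
#' @param texts character vector of one user's message texts.
#' @param timestamps ISO-8601 timestamps parallel to `texts` (used for
#'   birth-year conversion and recency tie-breaks).
#' @return integer age, or `NA` when no pattern matches.
#' @export
extract_age_regex <- function(texts, timestamps = NULL) {
  if (length(texts) == 0) return(NA_integer_)
  if (is.null(timestamps)) timestamps <- rep(NA_character_, length(texts))
  years <- suppressWarnings(as.integer(substr(as.character(timestamps), 1, 4)))
  years[is.na(years)] <- as.integer(format(Sys.Date(), "%Y"))
  per_post <- lapply(seq_along(texts),
                     function(i) age_matches_one(texts[i], years[i]))
  all_ages <- unlist(per_post)
  if (length(all_ages) == 0) return(NA_integer_)
  tab <- table(all_ages)
  winners <- as.numeric(names(tab)[tab == max(tab)])
  if (length(winners) == 1) return(as.integer(winners))
  # tie: value appearing in the most recent post
  ord <- order(as.character(timestamps), decreasing = TRUE)
  for (i in ord) {
    hit <- intersect(per_post[[i]], winners)
    if (length(hit) > 0) return(as.integer(hit[1]))
  }
  as.integer(min(winners))
}

# ---- age: model fallback ------------------------------------------------

#' Stylometric features of one user for the age model
#'
#' Aggregates writing-style signals over a user's posts: post count, mean
#' tokens per post, exclamation/emoticon/question rates, sentiment-lexicon
#' hit rates, first-person rate and a one-hot encoding of the user's
#' dominant source.
#'
#' @param texts the user's message texts.
#' @param sources parallel source names.
#' @param lexicons lexicon set (sentiment families).
#' @param source_levels fixed source vocabulary for the one-hot block.
#' @return named numeric vector with a fixed, documented ordering.
#' @export
age_features <- function(texts, sources, lexicons = default_lexicons(),
                         source_levels = character(0)) {
  n <- length(texts)
  toks <- fold_tokens(texts)
  n_tok <- vapply(toks, length, numeric(1))
  exclam <- stringi::stri_count_fixed(texts, "!")
  quest <- stringi::stri_count_fixed(texts, "?")
  emot <- stringi::stri_count_regex(texts, "[:;][-]?[)(/\\\\]")
  neg <- count_term_hits(texts, lexicons$sentiment_negative)
  pos <- count_term_hits(texts, lexicons$sentiment_positive)
  fp <- vapply(toks, function(t) sum(t %in% c("je", "j'ai", "j", "me", "moi",
                                              "mon", "ma", "mes")), numeric(1))
  out <- c(
    n_posts = n,
    mean_tokens = mean(n_tok),
    exclam_rate = mean(exclam),
    question_rate = mean(quest),
    emoticon_rate = mean(emot),
    neg_sentiment_rate = mean(neg),
    pos_sentiment_rate = mean(pos),
    first_person_rate = mean(fp / pmax(n_tok, 1))
  )
  if (length(source_levels) > 0) {
    dominant <- names(sort(table(sources), decreasing = TRUE))[1]
    onehot <- as.numeric(source_levels == dominant)
    names(onehot) <- paste0("src_", source_levels)
    out <- c(out, onehot)
  }
  out
}

#' Train the fallback age model
#'
#' Gradient-boosted regression of author age on stylometric features, used
#' only for users whose posts contain no explicit age statement. The
#' "probabilistic" nature of the prediction is exposed through companion
#' quantile models giving a central 80% prediction interval.
#'
#' @param features numeric matrix (users x features).
#' @param ages numeric vector of known ages.
#' @param nrounds,max_depth,eta boosting parameters.
#' @param quantiles lower/upper quantile levels of the interval models;
#'   `NULL` skips interval training.
#' @param seed integer seed for reproducible training.
#' @return object of class `abx_age_model`.
#' @export
train_age_model <- function(features, ages, nrounds = 200, max_depth = 4,
                            eta = 0.1, quantiles = c(0.1, 0.9), seed = 1L) {
  stopifnot(nrow(features) == length(ages), nrow(features) >= 2)
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(as.matrix(features), label = ages)
  params <- list(objective = "reg:squarederror", max_depth = max_depth,
                 eta = eta, nthread = 1, seed = seed,
                 base_score = mean(ages))
  fit <- xgboost::xgb.train(params, dtrain, nrounds = nrounds, verbose = 0)
  qfits <- NULL
  if (!is.null(quantiles)) {
    qfits <- lapply(quantiles, function(q) {
      qp <- list(objective = "reg:quantileerror", quantile_alpha = q,
                 max_depth = max_depth, eta = eta, nthread = 1, seed = seed,
                 base_score = stats::quantile(ages, q))
      xgboost::xgb.train(qp, dtrain, nrounds = nrounds, verbose = 0)
    })
    names(qfits) <- paste0("q", quantiles)
  }
  structure(
    list(model = fit, quantile_models = qfits,
         feature_names = colnames(features), train_mean = mean(ages)),
    class = "abx_age_model"
  )
}

#' Predict age from the fallback model
#'
#' @param model an `abx_age_model`.
#' @param features numeric matrix or vector of [age_features()].
#' @return data frame with `age` (clamped to 10-100) and, when interval
#'   models were trained, `age_lo` / `age_hi`.
#' @export
predict_age_model <- function(model, features) {
  if (!inherits(model, "abx_age_model")) {
    stop("age model is not trained: call train_age_model() first")
  }
  if (is.null(dim(features))) features <- matrix(features, nrow = 1,
                                                 dimnames = list(NULL, names(features)))
  features <- as.matrix(features[, model$feature_names, drop = FALSE])
  d <- xgboost::xgb.DMatrix(features)
  age <- pmin(pmax(predict(model$model, d), 10), 100)
  out <- data.frame(age = age)
  if (!is.null(model$quantile_models)) {
    qs <- vapply(model$quantile_models,
                 function(m) pmin(pmax(predict(m, d), 10), 100),
                 numeric(nrow(features)))
    qs <- matrix(qs, nrow = nrow(features))
    out$age_lo <- pmin(qs[, 1], age)
    out$age_hi <- pmax(qs[, ncol(qs)], age)
  }
  out
}

#' Build per-user demographic profiles
#'
#' Groups posts by author, scores gender, extracts regex ages and (when a
#' trained model is supplied) falls back to the model for users without an
#' explicit age statement. The model is never invoked for regex-resolved
#' users.
#'
#' @param posts posts data frame (id, source, timestamp, author, text).
#' @param lexicons lexicon set.
#' @param age_model optional `abx_age_model` for the fallback path.
#' @param source_levels source vocabulary used when building model features;
#'   defaults to the sources present in `posts`.
#' @return data frame with one row per author: gender scores, predicted
#'   gender, age, and `age_method` in {"regex", "model", "none"}.
#' @export
user_profiles <- function(posts, lexicons = default_lexicons(),
                          age_model = NULL,
                          source_levels = sort(unique(posts$source))) {
  authors <- unique(posts$author)
  idx <- split(seq_len(nrow(posts)), posts$author)[authors]
  rows <- lapply(authors, function(a) {
    i <- idx[[a]]
    sc <- score_gender(a, posts$text[i], lexicons)
    age <- extract_age_regex(posts$text[i], posts$timestamp[i])
    method <- if (!is.na(age)) "regex" else "none"
    data.frame(
      user = a, n_posts = length(i),
      female_score = sc[["female"]], male_score = sc[["male"]],
      gender = predict_gender(sc), age = as.numeric(age),
      age_method = method, stringsAsFactors = FALSE
    )
  })
  prof <- do.call(rbind, rows)
  if (!is.null(age_model)) {
    need <- which(is.na(prof$age))
    if (length(need) > 0) {
      feats <- t(vapply(need, function(r) {
        i <- idx[[prof$user[r]]]
        age_features(posts$text[i], posts$source[i], lexicons, source_levels)
      }, numeric(8 + length(source_levels))))
      pred <- predict_age_model(age_model, feats)
      prof$age[need] <- round(pred$age)
      prof$age_method[need] <- "model"
    }
  }
  prof
}
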