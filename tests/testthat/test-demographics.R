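lex <- default_lexicons()

test_that("gender scoring accumulates username and content evidence", {
  s <- score_gender("marie75", character(0), lex)
  expect_gt(s[["female"]], 0)
  expect_equal(s[["male"]], 0)

  s2 <- score_gender("user001",
                     "je suis allée chez le médecin, je suis inquiète", lex)
  expect_gte(s2[["female"]], 2) # "allée" + "inquiète" agreements
  expect_equal(s2[["male"]], 0)

  # additivity and permutation invariance over posts
  posts <- c("je suis allée au travail", "mon mari est là", "je suis contente")
  full <- score_gender("x", posts, lex)
  parts <- Reduce(`+`, lapply(posts, function(p) score_gender("x", p, lex))) -
    2 * score_gender("x", character(0), lex)
  expect_equal(full, parts)
  expect_equal(full, score_gender("x", rev(posts), lex))

  # monotone as posts are added
  expect_true(all(score_gender("x", posts, lex) >=
                    score_gender("x", posts[1:2], lex)))
})

test_that("gender prediction compares the two scores, tie means unknown", {
  expect_identical(predict_gender(c(female = 3, male = 1)), "female")
  expect_identical(predict_gender(c(female = 0, male = 2)), "male")
  expect_identical(predict_gender(c(female = 2, male = 2)), "unknown")
  expect_identical(predict_gender(c(female = 0, male = 0)), "unknown")
})

test_that("age regular expressions capture stated ages and reject durations", {
  expect_equal(extract_age_regex("j'ai 34 ans et je tousse"), 34L)
  expect_equal(extract_age_regex("née en 1985, je consulte",
                                 "2020-03-01T00:00:00Z"), 35L)
  expect_true(is.na(extract_age_regex("j'ai pris 3 ans de traitement")))
  expect_true(is.na(extract_age_regex("malade depuis 20 ans")))
  expect_true(is.na(extract_age_regex("j'ai 250 ans"))) # outside [10, 100]
  expect_true(is.na(extract_age_regex("aucun age ici")))
  # bare "N ans" without a duration guard is accepted
  expect_equal(extract_age_regex("maman de deux enfants, 41 ans, épuisée"), 41L)
  # majority across posts, then recency
  expect_equal(extract_age_regex(
    c("j'ai 30 ans", "j'ai 30 ans", "j'ai 31 ans"),
    c("2015-01-01", "2016-01-01", "2017-01-01")), 30L)
  expect_equal(extract_age_regex(
    c("j'ai 30 ans", "j'ai 31 ans"),
    c("2015-01-01", "2017-01-01")), 31L)
})

test_that("the model fallback is trained, bounded, and never silently defaults", {
  expect_error(predict_age_model(list(), matrix(0, 1, 2)), "not trained")
  # constant features: prediction collapses to the training mean
  f <- matrix(1, nrow = 50, ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  ages <- c(rep(20, 25), rep(50, 25))
  m <- train_age_model(f, ages, quantiles = NULL, seed = 2)
  p <- predict_age_model(m, f[1:5, ])
  expect_equal(p$age, rep(mean(ages), 5), tolerance = 0.5)
})

test_that("profiles dispatch regex before model and recover synthetic demographics", {
  g <- cached_corpus(400, 42)
  res <- filter_corpus(g$posts, lex)
  prof <- user_profiles(res$corpus, lex)
  expect_true(all(prof$age_method %in% c("regex", "none")))
  gt <- g$users[match(prof$user, g$users$username), ]

  # regex ages are exact
  reg <- prof$age_method == "regex"
  expect_gt(mean(reg), 0.4) # the regex path is actually exercised
  expect_equal(prof$age[reg], gt$age[reg])

  # gender accuracy 1 on users whose posts or username carry a marker
  marked <- vapply(seq_len(nrow(prof)), function(i) {
    ids <- res$corpus$author == prof$user[i]
    any(g$ground_truth$has_gender_marker[
      match(res$corpus$id[ids], g$ground_truth$id)])
  }, logical(1))
  acc <- mean(prof$gender[marked] == gt$gender[marked])
  expect_gte(acc, 0.95)

  # population marginals approximate the configured cohort
  det <- prof$gender != "unknown"
  expect_equal(mean(prof$gender[det] == "female"), 0.8622, tolerance = 0.05)
})

test_that("untrained-age users get model predictions within the plausible range", {
  g <- cached_corpus(400, 42)
  res <- filter_corpus(g$posts, lex)
  sl <- sort(unique(res$corpus$source))
  idx <- split(seq_len(nrow(res$corpus)), res$corpus$author)
  feats <- t(vapply(idx, function(i) {
    age_features(res$corpus$text[i], res$corpus$source[i], lex, sl)
  }, numeric(8 + length(sl))))
  truth <- g$users$age[match(names(idx), g$users$username)]
  m <- train_age_model(feats, truth, nrounds = 60, quantiles = NULL, seed = 3)
  prof <- user_profiles(res$corpus, lex, age_model = m, source_levels = sl)
  expect_false(any(is.na(prof$age)))
  expect_true(all(prof$age >= 10 & prof$age <= 100))
  expect_true(all(prof$age_method %in% c("regex", "model")))
  # regex users keep their extracted value: the model is never invoked there
  p0 <- user_profiles(res$corpus, lex)
  reg <- p0$age_method == "regex"
  expect_equal(prof$age[reg], p0$age[reg])
})
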