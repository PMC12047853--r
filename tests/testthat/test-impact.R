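lex <- default_lexicons()

test_that("feature extraction is deterministic, zero-based and additive", {
  f <- extract_features("je suis épuisée, douleurs partout", lex)
  expect_gte(f[1, "qol_physical"], 2) # "épuisée" + "douleurs"
  expect_gt(f[1, "n_first_person"], 0)
  f0 <- extract_features("zorp blup", lex)
  expect_true(all(f0[1, grep("^qol_", colnames(f0))] == 0))
  expect_true(all(is.finite(f)) && all(f >= 0))
  # count features double exactly under text concatenation
  txt <- "j'ai des douleurs et une angoisse permanente, pas de sport !"
  f1 <- extract_features(txt, lex)
  f2 <- extract_features(paste(txt, txt), lex)
  count_cols <- setdiff(colnames(f1), character(0))
  expect_equal(unname(f2[1, count_cols]), unname(2 * f1[1, count_cols]))
})

test_that("training requires two classes and is reproducible", {
  g <- cached_corpus(400, 42)
  gt <- g$ground_truth
  feats <- extract_features(g$posts$text, lex)
  cats <- category_matrix(gt)
  expect_error(
    impact_train(feats, rep(TRUE, nrow(feats)), cats, nrounds = 5),
    "single class"
  )
  m1 <- impact_train(feats, gt$has_impact, cats, nrounds = 30, seed = 6)
  m2 <- impact_train(feats, gt$has_impact, cats, nrounds = 30, seed = 6)
  p1 <- impact_classify(m1, feats)
  p2 <- impact_classify(m2, feats)
  expect_equal(p1, p2)
  expect_error(impact_classify(structure(list(), class = "list"), feats),
               "untrained")
})

test_that("the gate controls the category stage and recovery meets the oracle", {
  g <- cached_corpus(2470, 5)
  gt <- g$ground_truth
  feats <- extract_features(g$posts$text, lex)
  cats <- category_matrix(gt)
  n <- nrow(feats)
  set.seed(1)
  train <- sample(n, floor(0.7 * n))
  mod <- impact_train(feats[train, ], gt$has_impact[train], cats[train, ],
                      seed = 9)
  pred <- impact_classify(mod, feats[-train, ])

  # gating invariant: never a category on a gate-negative post
  cat_cols <- as.matrix(pred[, qol_cats])
  expect_false(any(!pred$has_impact & rowSums(cat_cols) > 0))

  expect_gte(mean(pred$has_impact == gt$has_impact[-train]), 0.9)
  for (cat in qol_cats) {
    pos <- which(gt$has_impact[-train] & cats[-train, cat])
    expect_gte(mean(pred[[cat]][pos]), 0.85)
  }

  # a post with planted physical+psychic markers triggers both categories
  both <- which(gt$has_impact[-train] & cats[-train, "physical"] &
                  cats[-train, "psychic"])
  expect_gte(mean(pred$physical[both] & pred$psychic[both]), 0.85)

  # gate probability below threshold empties the categories regardless
  forced <- impact_classify(mod, feats[-train, ], threshold = 1.0000001)
  expect_true(all(rowSums(as.matrix(forced[, qol_cats])) == 0))
})

test_that("label shuffling collapses accuracy to the base rate", {
  g <- cached_corpus(2470, 5)
  gt <- g$ground_truth
  feats <- extract_features(g$posts$text, lex)
  cats <- category_matrix(gt)
  n <- nrow(feats)
  set.seed(3)
  train <- sample(n, floor(0.7 * n))
  shuffled <- sample(gt$has_impact[train])
  mod <- impact_train(feats[train, ], shuffled, cats[train, ],
                      nrounds = 60, seed = 9)
  pred <- impact_classify(mod, feats[-train, ])
  acc <- mean(pred$has_impact == gt$has_impact[-train])
  base <- max(mean(gt$has_impact[-train]), 1 - mean(gt$has_impact[-train]))
  # within binomial noise of guessing the majority class
  expect_lt(acc, base + 3 * sqrt(base * (1 - base) / (n - length(train))))
})

test_that("impact summaries report both percentage conventions with denominators", {
  counts <- c(physical = 1866, psychic = 1551, activity = 745,
              relational = 602, financial = 28)
  s <- impact_summary(counts, n_messages = 3773, n_impact = 2384)
  expect_equal(s$message_share_pct, c(78, 65, 31, 25, 1))
  expect_equal(s$mention_share_pct, c(39, 32, 16, 13, 1))
  expect_equal(unique(s$message_denominator), 2384)
  expect_equal(unique(s$mention_denominator), 4792)
  expect_equal(attr(s, "impact_rate_pct"), 63)

  # one message, one category: both shares 100
  one <- impact_summary(c(physical = 1, psychic = 0, activity = 0,
                          relational = 0, financial = 0),
                        n_messages = 1, n_impact = 1)
  expect_equal(one$message_share_pct[1], 100)
  expect_equal(one$mention_share_pct[1], 100)

  # empty input: zeroed table
  empty_pred <- structure(
    data.frame(gate_prob = numeric(0), has_impact = logical(0),
               prob_physical = numeric(0), physical = logical(0),
               prob_psychic = numeric(0), psychic = logical(0),
               prob_activity = numeric(0), activity = logical(0),
               prob_relational = numeric(0), relational = logical(0),
               prob_financial = numeric(0), financial = logical(0)),
    class = c("abx_impact_prediction", "data.frame")
  )
  z <- impact_summary(empty_pred)
  expect_true(all(z$count == 0) && all(z$message_share_pct == 0))
})
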