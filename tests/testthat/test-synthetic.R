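test_that("planted topic distributions are normalized, disjoint and block-concentrated", {
  # single topic: forced normalization over the whole vocabulary
  phi1 <- planted_topic_distributions(1, 50, seed = 1)
  expect_equal(dim(phi1), c(50, 1))
  expect_equal(sum(phi1), 1, tolerance = 1e-12)

  phi <- planted_topic_distributions(3, 300, seed = 7)
  expect_equal(unname(colSums(phi)), rep(1, 3), tolerance = 1e-12)
  tops <- lapply(1:3, function(k) order(-phi[, k])[1:10])
  for (i in 1:2) for (j in (i + 1):3) {
    expect_length(intersect(tops[[i]], tops[[j]]), 0)
  }
  # >= 90% of each topic's mass on its own block of floor(V/K) tokens
  for (k in 1:3) {
    block <- ((k - 1) * 100 + 1):(k * 100)
    expect_gte(sum(phi[block, k]), 0.9)
  }
})

test_that("huge concentration gives a uniform block and small V errors out", {
  phi <- planted_topic_distributions(2, 20, concentration = 1e9, seed = 3)
  block1 <- phi[1:10, 1]
  expect_equal(block1, rep(block1[1], 10), tolerance = 1e-3)
  expect_error(planted_topic_distributions(3, 20), "vocabulary too small")
  expect_error(planted_topic_distributions(2, 20, concentration = -1), "positive")
})

test_that("generation is byte-reproducible under a fixed seed", {
  g1 <- generate_corpus(generation_config(n_users = 60, seed = 42))
  g2 <- generate_corpus(generation_config(n_users = 60, seed = 42))
  expect_identical(g1, g2)
  g3 <- generate_corpus(generation_config(n_users = 60, seed = 43))
  expect_false(identical(g1$posts$text, g3$posts$text))
})

test_that("ground truth bookkeeping: ids unique, reasons a closed partition", {
  g <- cached_corpus(400, 42)
  expect_false(any(duplicated(g$posts$id)))
  expect_setequal(g$posts$id, g$ground_truth$id)
  expect_true(all(g$ground_truth$filter_reason %in%
                    c("kept", "no_inclusion", "non_target_language",
                      "animal_vocabulary", "exclusion_word")))
  expect_identical(g$ground_truth$should_survive_filter,
                   g$ground_truth$filter_reason == "kept")
  # one topic per post, impact categories empty or multiple
  expect_true(all(g$ground_truth$true_topic %in% seq_len(13)))
  n_cats <- rowSums(category_matrix(g$ground_truth))
  expect_true(all(n_cats[!g$ground_truth$has_impact] == 0))
  expect_true(all(n_cats[g$ground_truth$has_impact] >= 1))
  expect_gt(max(n_cats), 1) # multi-domain messages exist
})

test_that("configuration invariants are enforced", {
  expect_error(generation_config(female_rate = 1.2), "probabilities")
  expect_error(generation_config(posts_per_user_mean = 0.5), "posts_per_user_mean")
  expect_error(generation_config(n_topics = 5, vocab_size = 30), "vocab_size")
  expect_error(generation_config(distractor_rates = c(
    no_inclusion = 0.5, language = 0.3, animal = 0.2, exclusion = 0.1
  )), "sum to < 1")
})

test_that("cohort marginals converge to the configured rates", {
  g <- cached_corpus(10000, 99)
  cfg <- generation_config(n_users = 10000, seed = 99)

  # female share inside the exact binomial 99.9% interval
  n_f <- sum(g$users$gender == "female")
  bounds <- qbinom(c(0.0005, 0.9995), 10000, cfg$female_rate)
  expect_gte(n_f, bounds[1])
  expect_lte(n_f, bounds[2])

  # mean age: ages are rejection-sampled from a truncated normal, so the
  # analytic truncated mean is the target; CLT band at ~3.3 sd
  target_age <- truncnorm_mean(cfg$age_mean, cfg$age_sd, 10, 100)
  expect_lt(abs(mean(g$users$age) - target_age),
            3.3 * cfg$age_sd / sqrt(10000) + 0.05)

  # posts per user: 1 + Poisson(0.62), CLT band
  expect_lt(abs(mean(g$users$n_posts) - cfg$posts_per_user_mean),
            3.3 * sqrt(cfg$posts_per_user_mean - 1) / sqrt(10000))

  # impact rate over all posts
  n_posts <- nrow(g$posts)
  expect_lt(abs(mean(g$ground_truth$has_impact) - cfg$impact_rate),
            3.3 * sqrt(0.63 * 0.37 / n_posts))

  # per-category rates among impact-bearing posts (law of large numbers)
  imp <- g$ground_truth[g$ground_truth$has_impact, ]
  rates <- colMeans(category_matrix(imp))
  expect_equal(unname(rates), unname(cfg$impact_category_probs),
               tolerance = 0.025)
})

test_that("seasonality: November-March volume exceeds April-October by the amplitude", {
  g <- cached_corpus(10000, 99)
  mv <- monthly_volume(g$posts)
  expect_equal(mv$seasonality_index, 2, tolerance = 0.1)
  flat <- generate_corpus(generation_config(n_users = 3000, seasonal_amplitude = 1,
                                            seed = 12))
  expect_equal(monthly_volume(flat$posts)$seasonality_index, 1, tolerance = 0.12)
})

test_that("posts survive a JSON-lines round trip", {
  g <- generate_corpus(generation_config(n_users = 15, seed = 8))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_posts_jsonl(g$posts, path)
  back <- read_posts_jsonl(path)
  rownames(back) <- NULL
  rownames(g$posts) <- NULL
  expect_equal(back, g$posts)
})
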