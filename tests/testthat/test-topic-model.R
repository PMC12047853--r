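toy_corpus <- function(texts, stopwords = character(0)) {
  preprocess_corpus(texts, stopwords = stopwords)
}

test_that("preprocessing folds, filters and indexes deterministically", {
  corp <- preprocess_corpus("Les antibiotiques ne marchent PAS!",
                            stopwords = c("les", "ne", "pas"))
  expect_identical(corp$vocabulary, c("antibiotiques", "marchent"))
  corp2 <- preprocess_corpus(c("Xyzzy abcde", "Xyzzy abcde"),
                             stopwords = character(0))
  expect_identical(corp2$documents[[1]], corp2$documents[[2]])
  # all-stopword document is flagged and yields no biterm
  corp3 <- preprocess_corpus(c("le la les", "grand chien noir"),
                             stopwords = c("le", "la", "les"))
  expect_true(corp3$short[1])
  expect_identical(extract_biterms(corp3$documents[[1]]),
                   matrix(integer(0), ncol = 2))
  expect_error(preprocess_corpus("le la", stopwords = c("le", "la")),
               "empty vocabulary")
})

test_that("biterm extraction enumerates all position pairs", {
  expect_equal(extract_biterms(c(1L, 2L, 3L)),
               cbind(c(1L, 1L, 2L), c(2L, 3L, 3L)))
  # repeated token gives a self-pair
  expect_equal(extract_biterms(c(4L, 4L)), cbind(4L, 4L))
  # a document of n tokens yields exactly n(n-1)/2 biterms
  for (n in c(2, 5, 9)) {
    expect_equal(nrow(extract_biterms(seq_len(n))), n * (n - 1) / 2)
  }
  expect_equal(nrow(extract_biterms(1L)), 0)
})

test_that("count invariants hold after fitting and states are seed-reproducible", {
  g <- cached_corpus(400, 42)
  texts <- filter_corpus(g$posts)$corpus$text[1:120]
  corp <- preprocess_corpus(texts, c(default_stopwords(),
                                     generator_scaffold_tokens()))
  fit <- btm_fit(corp, K = 4, n_iter = 60, burn_in = 30, seed = 5)
  expect_equal(sum(fit$n_k), fit$B)
  expect_equal(unname(colSums(fit$n_wk)), 2 * fit$n_k)
  expect_true(all(fit$n_wk >= 0))
  # averaged counts satisfy the same balance
  expect_equal(unname(colSums(fit$avg_n_wk)), 2 * fit$avg_n_k)
  fit2 <- btm_fit(corp, K = 4, n_iter = 60, burn_in = 30, seed = 5)
  expect_identical(fit$z, fit2$z)
  expect_equal(fit$avg_n_wk, fit2$avg_n_wk)
})

test_that("phi and theta are proper distributions; K=1 is the smoothed frequency", {
  corp <- toy_corpus(c("aaa bbb ccc", "bbb ccc ddd", "aaa ddd"))
  fit <- btm_fit(corp, K = 3, alpha = 1, beta = 0.05, n_iter = 80,
                 burn_in = 40, seed = 2)
  phi <- btm_phi(fit)
  expect_equal(unname(colSums(phi)), rep(1, 3), tolerance = 1e-10)
  expect_equal(sum(btm_theta(fit)), 1, tolerance = 1e-10)

  f1 <- btm_fit(corp, K = 1, alpha = 1, beta = 0.1, n_iter = 10,
                burn_in = 5, seed = 1)
  expect_true(all(f1$z == 1))
  expect_equal(btm_theta(f1), 1)
  wcount <- tabulate(c(f1$biterms), f1$V)
  expect_equal(unname(btm_phi(f1)[, 1]),
               (wcount + 0.1) / (2 * f1$B + f1$V * 0.1), tolerance = 1e-12)

  # an empty topic's phi column is pure smoothing: uniform 1/V
  expect_warning(
    fit_many <- btm_fit(corp, K = 50, alpha = 0.1, beta = 0.01, n_iter = 30,
                        burn_in = 29, seed = 3),
    "degenerate"
  )
  empty <- which(fit_many$avg_n_k == 0)
  if (length(empty) > 0) {
    expect_equal(unname(btm_phi(fit_many)[, empty[1]]),
                 rep(1 / fit_many$V, fit_many$V), tolerance = 1e-12)
  }
})

test_that("huge beta drives all topics to the uniform distribution", {
  corp <- toy_corpus(c("aaa bbb ccc ddd", "aaa ccc eee"))
  fit <- btm_fit(corp, K = 2, alpha = 1, beta = 1e8, n_iter = 40,
                 burn_in = 20, seed = 1)
  phi <- btm_phi(fit)
  expect_equal(unname(phi), matrix(1 / corp$V, corp$V, 2), tolerance = 1e-6)
})

test_that("Gibbs assignment frequencies match the exact enumerated posterior", {
  # corpus of 2 documents -> 4 biterms over 4 words, K = 2
  corp <- toy_corpus(c("aaa bbb ccc", "bbb ddd"))
  bits <- do.call(rbind, lapply(corp$documents, extract_biterms))
  expect_equal(nrow(bits), 4)
  exact <- btm_enumerate_posterior(bits, corp$V, K = 2, alpha = 1, beta = 0.1)
  expect_equal(rowSums(exact$marginal), rep(1, 4), tolerance = 1e-12)
  fit <- btm_fit(corp, K = 2, alpha = 1, beta = 0.1, n_iter = 21000,
                 burn_in = 1000, seed = 7, record_assignments = TRUE)
  expect_lt(max(abs(fit$assign_freq - exact$marginal)), 0.02)
})

test_that("document assignment follows the mixture formula with stable ties", {
  corp <- toy_corpus(c("aaa bbb", "aaa bbb", "ccc ddd", "ccc ddd"))
  fit <- btm_fit(corp, K = 2, alpha = 1, beta = 0.01, n_iter = 200,
                 burn_in = 100, seed = 11)
  # single-biterm document: argmax_k theta_k phi_w1k phi_w2k
  phi <- btm_phi(fit); theta <- btm_theta(fit)
  expect_equal(btm_assign(corp$documents[[1]], fit),
               which.max(theta * phi[1, ] * phi[2, ]))
  # K = 1: everything in topic 1; empty document unassigned
  f1 <- btm_fit(corp, K = 1, n_iter = 10, burn_in = 5, seed = 1)
  expect_equal(btm_assign_corpus(corp, f1), rep(1L, 4))
  expect_true(is.na(btm_assign(integer(0), fit)))
  # single-token document uses the one-token mixture
  expect_equal(btm_assign(1L, fit), which.max(theta * phi[1, ] / sum(theta * phi[1, ])))
})

test_that("characteristic tokens use the cross-topic inverse weighting", {
  phi <- matrix(c(0.30, 0.01, 0.02,
                  0.70, 0.98, 0.98), nrow = 2, byrow = TRUE,
                dimnames = list(c("tok_a", "tok_b"), NULL))
  cs <- characteristic_tokens(phi, 1, n = 2)
  expect_equal(cs$weight[cs$token == "tok_a"], 0.3 / 0.03) # = 10
  # token uniform across topics has weight 1/(K-1) everywhere
  phiu <- matrix(1 / 3, nrow = 4, ncol = 3,
                 dimnames = list(paste0("w", 1:4), NULL))
  cu <- characteristic_tokens(phiu, 2, n = 4)
  expect_equal(cu$weight, rep(1 / 2, 4))
  # ranked strictly by weight with deterministic output length min(15, V)
  expect_equal(nrow(characteristic_tokens(phiu, 1, n = 15)), 4)
  expect_true(all(diff(cs$weight) <= 0))
})

test_that("planted topics are recovered from a synthetic corpus", {
  cfg <- generation_config(n_users = 700, n_topics = 3, vocab_size = 300,
                           seed = 21)
  g <- generate_corpus(cfg)
  res <- filter_corpus(g$posts)
  corp <- preprocess_corpus(res$corpus$text,
                            c(default_stopwords(), generator_scaffold_tokens()))
  fit <- btm_fit(corp, K = 3, n_iter = 600, burn_in = 300, seed = 2)
  planted <- g$topics
  rownames(planted) <- g$vocab
  common <- intersect(rownames(planted), corp$vocabulary)
  phi <- btm_phi(fit)[common, ]
  al <- align_topics(phi, planted[common, ], n_top = 10)
  blocks <- apply(planted, 1, which.max)
  in_block <- vapply(1:3, function(k) {
    top10 <- rownames(phi)[order(-phi[, k])[1:10]]
    mean(blocks[match(top10, rownames(planted))] == al$perm[k], na.rm = TRUE)
  }, numeric(1))
  expect_gte(mean(in_block), 0.9)
  # and each topic's characteristic tokens fall inside its planted block
  ts <- topic_summaries(fit, 15)
  for (k in 1:3) {
    toks <- ts$token[ts$topic == k]
    frac <- mean(blocks[match(toks, rownames(planted))] == al$perm[k],
                 na.rm = TRUE)
    expect_gte(frac, 13 / 15)
  }
})

test_that("a fitted model survives the versioned JSON round trip", {
  corp <- toy_corpus(c("aaa bbb ccc", "bbb ddd eee", "aaa eee"))
  fit <- btm_fit(corp, K = 2, n_iter = 30, burn_in = 15, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_btm(fit, path)
  back <- read_btm(path)
  expect_equal(btm_phi(back), btm_phi(fit))
  expect_equal(btm_theta(back), btm_theta(fit))
  expect_identical(back$z, fit$z)
  expect_error(read_btm(withr::local_tempfile(lines = "{\"format\": \"x\"}")),
               "not an abxtalk BTM bundle")
})
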