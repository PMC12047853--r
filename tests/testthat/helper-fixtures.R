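# shared synthetic fixtures, built once per test run
.fixture_env <- new.env(parent = emptyenv())

cached_corpus <- function(n_users, seed) {
  key <- sprintf("corpus_%d_%d", n_users, seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_corpus(
      generation_config(n_users = n_users, seed = seed)
    )
  }
  .fixture_env[[key]]
}

qol_cats <- c("physical", "psychic", "activity", "relational", "financial")

category_matrix <- function(ground_truth) {
  m <- as.matrix(ground_truth[, paste0("impact_", qol_cats)])
  colnames(m) <- qol_cats
  m
}

# mean of a normal truncated to [lo, hi] (closed form; oracle for the
# generator's rejection-sampled ages)
truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}
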