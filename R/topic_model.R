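# Biterm topic model (BTM) for short forum/microblog messages: the corpus-
# wide set of within-message token pairs (biterms) is modelled as a mixture
# of K topics, each topic a distribution over tokens. Fitting is by
# collapsed Gibbs sampling (Rcpp core); phi and theta are posterior-mean
# estimates averaged over post-burn-in samples.

#' Tokenize and index a corpus for topic modelling
#'
#' Lowercases, folds accents, splits on non-letters, then drops stopwords
#' and tokens shorter than `min_chars`. The vocabulary is ordered by first
#' occurrence, so identical input always produces identical token ids.
#' Documents left with fewer than 2 tokens are flagged: they contribute no
#' biterm.
#'
#' @param texts character vector of message texts.
#' @param stopwords folded stopword tokens; see [default_stopwords()].
#' @param min_chars minimum token length kept.
#' @return list of class `abx_corpus`: `documents` (integer-id vectors),
#'   `vocabulary`, `V`, `short` (logical flag per document).
#' @export
preprocess_corpus <- function(texts, stopwords = default_stopwords(),
                              min_chars = 3) {
  toks <- stringi::stri_split_regex(fold_text(texts), "[^a-z]+")
  toks <- lapply(toks, function(t) {
    t <- t[nzchar(t) & nchar(t) >= min_chars]
    t[!t %in% stopwords]
  })
  vocab <- unique(unlist(toks, use.names = FALSE))
  if (length(vocab) == 0) {
    stop("empty vocabulary: every token was filtered out")
  }
  docs <- lapply(toks, function(t) match(t, vocab))
  structure(
    list(documents = docs, vocabulary = vocab, V = length(vocab),
         short = vapply(docs, length, integer(1)) < 2L),
    class = "abx_corpus"
  )
}

#' Extract the biterms of one document
#'
#' All unordered pairs of distinct token positions in the document (the
#' whole short message is the co-occurrence window), stored as
#' (min id, max id); a repeated token yields a self-pair. A document of n
#' tokens yields exactly n(n-1)/2 biterms; fewer than 2 tokens yield none.
#'
#' @param doc integer vector of token ids.
#' @return 2-column integer matrix, one row per biterm.
#' @export
extract_biterms <- function(doc) {
  n <- length(doc)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  pairs <- utils::combn(n, 2)
  cbind(pmin(doc[pairs[1, ]], doc[pairs[2, ]]),
        pmax(doc[pairs[1, ]], doc[pairs[2, ]]))
}

corpus_biterms <- function(corpus) {
  mats <- lapply(corpus$documents, extract_biterms)
  do.call(rbind, mats)
}

#' Fit a biterm topic model by collapsed Gibbs sampling
#'
#' @param corpus an `abx_corpus` from [preprocess_corpus()].
#' @param K number of topics.
#' @param alpha Dirichlet hyperparameter over topics (default 50/K).
#' @param beta Dirichlet hyperparameter over tokens (default 0.01).
#' @param n_iter total Gibbs sweeps.
#' @param burn_in sweeps discarded before averaging.
#' @param sample_every thinning interval of the count averages.
#' @param seed integer seed; identical seeds give identical states.
#' @param record_assignments also keep per-biterm topic frequencies over
#'   all post-burn-in sweeps (used for exactness checks on tiny corpora).
#' @return object of class `abx_btm` holding assignments, final and
#'   averaged count statistics, and the fitting metadata.
#' @export
btm_fit <- function(corpus, K, alpha = 50 / K, beta = 0.01,
                    n_iter = 1000, burn_in = 500, sample_every = 10,
                    seed = 1L, record_assignments = FALSE) {
  stopifnot(inherits(corpus, "abx_corpus"))
  if (K < 1) stop("K must be >= 1")
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  biterms <- corpus_biterms(corpus)
  B <- nrow(biterms)
  if (B < 1) stop("corpus contains no biterm (all documents too short)")
  if (K > B) {
    warning("K = ", K, " exceeds the number of biterms (", B,
            "); the model is degenerate but will run")
  }
  set.seed(seed)
  res <- btm_gibbs_cpp(biterms - 1L, corpus$V, as.integer(K),
                       alpha, beta, as.integer(n_iter), as.integer(burn_in),
                       as.integer(sample_every), isTRUE(record_assignments))
  structure(
    list(
      K = as.integer(K), V = corpus$V, alpha = alpha, beta = beta,
      vocabulary = corpus$vocabulary,
      biterms = biterms, B = B,
      z = res$z + 1L, n_k = as.numeric(res$n_k), n_wk = res$n_wk,
      avg_n_k = as.numeric(res$avg_n_k), avg_n_wk = res$avg_n_wk,
      n_samples = res$n_samples,
      assign_freq = res$assign_freq,
      n_iter = n_iter, burn_in = burn_in, sample_every = sample_every,
      seed = as.integer(seed)
    ),
    class = "abx_btm"
  )
}

#' @export
print.abx_btm <- function(x, ...) {
  cat("Biterm topic model: K =", x$K, ", V =", x$V, ", B =", x$B, "\n")
  cat("  alpha =", x$alpha, ", beta =", x$beta,
      ",", x$n_samples, "posterior samples\n")
  invisible(x)
}

check_fitted <- function(state) {
  if (!inherits(state, "abx_btm") || is.null(state$n_k)) {
    stop("not a fitted biterm topic model")
  }
}

#' Topic-token distribution phi (V x K)
#'
#' Posterior-mean estimator `phi[w, k] = (n_wk + beta) / (2 n_k + V beta)`
#' applied to the post-burn-in count averages; every column sums to 1. An
#' empty topic yields the uniform smoothing-only column 1/V.
#'
#' @param state fitted `abx_btm`.
#' @param use_average use averaged counts (default) or the final sweep.
#' @return V x K matrix with vocabulary rownames.
#' @export
btm_phi <- function(state, use_average = TRUE) {
  check_fitted(state)
  n_wk <- if (use_average) state$avg_n_wk else state$n_wk
  n_k <- if (use_average) state$avg_n_k else state$n_k
  phi <- sweep(n_wk + state$beta, 2, 2 * n_k + state$V * state$beta, "/")
  rownames(phi) <- state$vocabulary
  phi
}

#' Corpus topic distribution theta (length K)
#'
#' `theta[k] = (n_k + alpha) / (B + K alpha)`; sums to 1.
#'
#' @inheritParams btm_phi
#' @return numeric vector of length K.
#' @export
btm_theta <- function(state, use_average = TRUE) {
  check_fitted(state)
  n_k <- if (use_average) state$avg_n_k else state$n_k
  (n_k + state$alpha) / (state$B + state$K * state$alpha)
}

#' Assign one document to its single most probable topic
#'
#' `P(k | d)` is the average over the document's biterms of
#' `P(k | b)` with `P(k | b)` proportional to
#' `theta_k phi[w1, k] phi[w2, k]`; the document is assigned to the argmax
#' topic with deterministic ties to the lowest index. A document with
#' exactly one token uses the single-token mixture
#' `P(k | w)` proportional to `theta_k phi[w, k]`; an empty document
#' returns `NA`.
#'
#' @param doc integer token-id vector (from an `abx_corpus` built with the
#'   model's vocabulary).
#' @param state fitted `abx_btm`.
#' @return integer topic id, or `NA` for an empty document.
#' @export
btm_assign <- function(doc, state) {
  check_fitted(state)
  doc <- doc[!is.na(doc)]
  if (length(doc) == 0) return(NA_integer_)
  phi <- btm_phi(state)
  theta <- btm_theta(state)
  if (length(doc) == 1) {
    p <- theta * phi[doc, ]
    return(which.max(p / sum(p)))
  }
  bits <- extract_biterms(doc)
  pk <- numeric(state$K)
  for (i in seq_len(nrow(bits))) {
    pb <- theta * phi[bits[i, 1], ] * phi[bits[i, 2], ]
    pk <- pk + pb / sum(pb)
  }
  which.max(pk)
}

#' Assign every document of a corpus
#'
#' @param corpus `abx_corpus` tokenized with the model's vocabulary (use
#'   [align_vocabulary()] when it was preprocessed independently).
#' @param state fitted `abx_btm`.
#' @return integer vector of topic ids (`NA` for empty documents).
#' @export
btm_assign_corpus <- function(corpus, state) {
  vapply(corpus$documents, btm_assign, integer(1), state = state)
}

#' Re-index a corpus onto a model's vocabulary
#'
#' Tokens unknown to the model are dropped.
#'
#' @param corpus `abx_corpus`.
#' @param state fitted `abx_btm`.
#' @return `abx_corpus` whose ids refer to the model's vocabulary.
#' @export
align_vocabulary <- function(corpus, state) {
  docs <- lapply(corpus$documents, function(d) {
    m <- match(corpus$vocabulary[d], state$vocabulary)
    m[!is.na(m)]
  })
  structure(
    list(documents = docs, vocabulary = state$vocabulary,
         V = length(state$vocabulary),
         short = vapply(docs, length, integer(1)) < 2L),
    class = "abx_corpus"
  )
}

#' Characteristic tokens of a topic
#'
#' Each token's in-topic probability is weighted by the inverse of its
#' probability in the other topics:
#' `weight(t, k) = phi[t, k] / sum over k' != k of phi[t, k']`, so tokens
#' spread evenly across topics (weight 1/(K-1)) never look characteristic.
#' The top `n` tokens by weight are returned, ties broken by raw phi then
#' token id. With a single topic the ranking falls back to raw phi.
#'
#' @param phi V x K topic-token matrix with vocabulary rownames.
#' @param k topic index.
#' @param n number of characteristic tokens (default 15, capped at V).
#' @return data frame of class `abx_topic_summary`: rank, token, weight,
#'   phi, plus a `label` attribute slot for manual naming.
#' @export
characteristic_tokens <- function(phi, k, n = 15) {
  K <- ncol(phi)
  V <- nrow(phi)
  n <- min(n, V)
  if (K >= 2) {
    other <- rowSums(phi[, -k, drop = FALSE])
    weight <- phi[, k] / other
  } else {
    weight <- phi[, 1]
  }
  ord <- order(-weight, -phi[, k], seq_len(V))
  top <- ord[seq_len(n)]
  out <- data.frame(
    topic = k, rank = seq_len(n),
    token = if (is.null(rownames(phi))) as.character(top) else rownames(phi)[top],
    weight = weight[top], phi = phi[top, k],
    stringsAsFactors = FALSE
  )
  attr(out, "label") <- NA_character_
  class(out) <- c("abx_topic_summary", class(out))
  out
}

#' Characteristic-token summaries for all topics
#'
#' @param state fitted `abx_btm`.
#' @param n tokens per topic.
#' @return data frame stacking [characteristic_tokens()] over topics.
#' @export
topic_summaries <- function(state, n = 15) {
  phi <- btm_phi(state)
  do.call(rbind, lapply(seq_len(state$K),
                        function(k) characteristic_tokens(phi, k, n)))
}

#' Exact collapsed posterior over biterm assignments
#'
#' Enumerates all K^B topic-assignment configurations of a (tiny) biterm
#' set and computes the collapsed posterior
#' `P(z) proportional to prod_k Gamma(n_k + alpha) *
#' prod_k [ prod_w Gamma(n_wk + beta) / Gamma(2 n_k + V beta) ]`,
#' returning the marginal assignment probabilities per biterm. Serves as
#' the brute-force oracle for the Gibbs sampler; feasible for
#' `K^B` up to ~1e6.
#'
#' @param biterms 2-column integer matrix of token ids (1-based).
#' @param V vocabulary size.
#' @param K number of topics.
#' @param alpha,beta hyperparameters.
#' @return list: `marginal` (B x K matrix of exact `P(z_b = k)`),
#'   `log_joint` (vector over configurations).
#' @export
btm_enumerate_posterior <- function(biterms, V, K, alpha, beta) {
  B <- nrow(biterms)
  if (K^B > 2e6) stop("enumeration infeasible: K^B too large")
  configs <- as.matrix(expand.grid(rep(list(seq_len(K)), B)))
  logp <- apply(configs, 1, function(z) {
    n_k <- tabulate(z, K)
    lp <- sum(lgamma(n_k + alpha))
    for (k in seq_len(K)) {
      idx <- which(z == k)
      words <- c(biterms[idx, 1], biterms[idx, 2])
      n_w <- tabulate(words, V)
      lp <- lp + sum(lgamma(n_w + beta)) - V * lgamma(beta) -
        lgamma(2 * n_k[k] + V * beta) + lgamma(V * beta)
    }
    lp
  })
  w <- exp(logp - max(logp))
  w <- w / sum(w)
  marginal <- matrix(0, B, K)
  for (k in seq_len(K)) {
    marginal[, k] <- colSums(w * (configs == k))
  }
  list(marginal = marginal, log_joint = logp)
}

#' Topic-coherence sweep over candidate K
#'
#' Fits the model for each candidate K and reports mean UMass coherence of
#' the top-`n_top` tokens per topic, a standard aid for choosing the number
#' of topics when no external criterion exists.
#'
#' @param corpus `abx_corpus`.
#' @param k_values candidate topic counts.
#' @param n_top tokens per topic entering the coherence score.
#' @param ... passed to [btm_fit()].
#' @return data frame with `K` and `coherence` (higher is better).
#' @export
btm_sweep_k <- function(corpus, k_values = 5:20, n_top = 10, ...) {
  docsets <- lapply(corpus$documents, unique)
  doc_count <- function(w) sum(vapply(docsets, function(d) w %in% d, logical(1)))
  co_count <- function(w1, w2) {
    sum(vapply(docsets, function(d) (w1 %in% d) && (w2 %in% d), logical(1)))
  }
  rows <- lapply(k_values, function(K) {
    fit <- btm_fit(corpus, K, ...)
    phi <- btm_phi(fit)
    coh <- vapply(seq_len(K), function(k) {
      top <- order(-phi[, k])[seq_len(min(n_top, nrow(phi)))]
      s <- 0
      for (i in 2:length(top)) {
        for (j in 1:(i - 1)) {
          s <- s + log((co_count(top[i], top[j]) + 1) /
                         max(doc_count(top[j]), 1))
        }
      }
      s
    }, numeric(1))
    data.frame(K = K, coherence = mean(coh))
  })
  do.call(rbind, rows)
}

#' Serialize / restore a fitted topic model as versioned JSON
#'
#' All count statistics, assignments and metadata are written as plain
#' JSON with a format-version header, so fitted models survive as text.
#'
#' @param state fitted `abx_btm`.
#' @param path file path.
#' @return `read_btm` returns the restored `abx_btm`.
#' @export
write_btm <- function(state, path) {
  check_fitted(state)
  payload <- list(
    format = "abxtalk-btm", version = 1L,
    K = state$K, V = state$V, alpha = state$alpha, beta = state$beta,
    vocabulary = state$vocabulary, biterms = state$biterms,
    B = state$B, z = state$z, n_k = state$n_k, n_wk = state$n_wk,
    avg_n_k = state$avg_n_k, avg_n_wk = state$avg_n_wk,
    n_samples = state$n_samples, n_iter = state$n_iter,
    burn_in = state$burn_in, sample_every = state$sample_every,
    seed = state$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_btm
#' @export
read_btm <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "abxtalk-btm")) stop("not an abxtalk BTM bundle")
  if (p$version != 1L) stop("unsupported BTM bundle version: ", p$version)
  state <- p[setdiff(names(p), c("format", "version"))]
  state$biterms <- matrix(as.integer(state$biterms), ncol = 2)
  state$n_wk <- matrix(as.numeric(state$n_wk), nrow = state$V)
  state$avg_n_wk <- matrix(as.numeric(state$avg_n_wk), nrow = state$V)
  state$assign_freq <- NULL
  class(state) <- "abx_btm"
  state
}

#' Align fitted topics to reference topics by best-match permutation
#'
#' Maximizes total top-`n_top` token overlap between fitted and reference
#' topic-token distributions over all topic permutations (exhaustive for
#' K <= 8, greedy beyond).
#'
#' @param phi_fit,phi_ref V x K matrices over the same vocabulary order.
#' @param n_top tokens compared per topic.
#' @return list: `perm` (reference topic matched to each fitted topic),
#'   `overlap` (mean fraction of shared top tokens under the matching).
#' @export
align_topics <- function(phi_fit, phi_ref, n_top = 10) {
  K <- ncol(phi_fit)
  stopifnot(ncol(phi_ref) == K)
  tops_fit <- lapply(seq_len(K), function(k) order(-phi_fit[, k])[seq_len(n_top)])
  tops_ref <- lapply(seq_len(K), function(k) order(-phi_ref[, k])[seq_len(n_top)])
  score <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      score[i, j] <- length(intersect(tops_fit[[i]], tops_ref[[j]]))
    }
  }
  if (K <= 8) {
    perms <- all_permutations(K)
    best <- perms[which.max(vapply(seq_len(nrow(perms)), function(r) {
      sum(score[cbind(seq_len(K), perms[r, ])])
    }, numeric(1))), ]
  } else {
    best <- integer(K)
    avail <- seq_len(K)
    for (i in order(-apply(score, 1, max))) {
      j <- avail[which.max(score[i, avail])]
      best[i] <- j
      avail <- setdiff(avail, j)
    }
  }
  list(perm = best,
       overlap = sum(score[cbind(seq_len(K), best)]) / (K * n_top))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  unname(out)
}
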