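# Synthetic-corpus generator: posts with the statistical structure the
# analysis assumes (cohort demographics, seasonality, planted topic
# structure, QoL impact labels, filter distractors) plus full latent ground
# truth, so every downstream stage can be validated without any real data.

# run expr under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Deterministic pseudo-lexicon
#'
#' Builds `n` pronounceable six-letter tokens (three consonant-vowel
#' syllables) indexed in a fixed base-70 code, so the same index always maps
#' to the same token. Used as the content vocabulary of synthetic posts;
#' tokens are distinct from every marker/lexicon word and survive the topic
#' model's token-length filter.
#'
#' @param n number of tokens.
#' @return character vector of length `n`.
#' @export
pseudo_vocab <- function(n) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vows <- c("a", "e", "i", "o", "u")
  syll <- as.vector(outer(vows, cons, function(v, c) paste0(c, v)))
  if (n > length(syll)^3) stop("pseudo_vocab supports at most ", length(syll)^3, " tokens")
  i <- seq_len(n) - 1L
  paste0(
    syll[(i %/% (70L * 70L)) %% 70L + 1L],
    syll[(i %/% 70L) %% 70L + 1L],
    syll[i %% 70L + 1L]
  )
}

#' Planted per-topic token distributions
#'
#' Each of the K topics concentrates at least 90% of its probability mass
#' (by construction, 97%) on its own disjoint block of `floor(V / K)`
#' tokens; in-block weights are drawn from a symmetric Dirichlet with the
#' given concentration, the residual 3% is spread uniformly over all other
#' tokens. With a single topic the whole mass stays in the one block.
#'
#' @param K number of topics (>= 1).
#' @param V vocabulary size; must satisfy `V >= 10 * K`.
#' @param concentration Dirichlet concentration of in-block weights; large
#'   values approach a uniform block.
#' @param seed optional integer; the caller's RNG state is restored.
#' @return a `V x K` matrix; each column is a probability vector.
#' @export
planted_topic_distributions <- function(K, V, concentration = 1, seed = NULL) {
  if (K < 1) stop("K must be >= 1")
  if (V < 10 * K) {
    stop("vocabulary too small: V = ", V, " but V >= 10 * K = ", 10 * K,
         " is required for disjoint topic blocks")
  }
  if (concentration <= 0) stop("concentration must be positive")
  with_seed(seed, {
    m <- V %/% K
    phi <- matrix(0, nrow = V, ncol = K)
    in_mass <- if (K == 1) 1 else 0.97
    for (k in seq_len(K)) {
      block <- ((k - 1L) * m + 1L):(k * m)
      w <- stats::rgamma(m, shape = concentration)
      if (all(w == 0)) w <- rep(1, m) # guards rgamma underflow at tiny shape
      phi[block, k] <- in_mass * w / sum(w)
      out <- setdiff(seq_len(V), block)
      if (length(out) > 0) phi[out, k] <- (1 - in_mass) / length(out)
    }
    phi
  })
}

# exact fixed point: adjusted Bernoulli parameters p' such that independent
# draws conditioned on a non-empty set have marginals exactly `p`
conditional_category_probs <- function(p, tol = 1e-12, max_iter = 200) {
  if (sum(p) <= 0) stop("at least one impact-category probability must be > 0")
  p_adj <- p
  for (i in seq_len(max_iter)) {
    q <- prod(1 - p_adj)
    p_new <- p * (1 - q)
    if (any(p_new >= 1)) stop("impact-category probabilities are infeasible")
    if (max(abs(p_new - p_adj)) < tol) return(p_new)
    p_adj <- p_new
  }
  p_adj
}

draw_impact_categories <- function(p_adj) {
  repeat {
    draw <- stats::runif(length(p_adj)) < p_adj
    if (any(draw)) return(draw)
  }
}

#' Configuration of the synthetic-corpus generator
#'
#' Defaults reproduce the study-level conditions of the analysed cohort:
#' 86.22% female authors, mean age about 35 years, a mean of 1.62 posts per
#' user, posting between January 2014 and July 2020 with elevated
#' November-March volume, about 13 discussion themes, and a 63% rate of
#' messages expressing at least one quality-of-life impact with per-domain
#' shares of 78/65/31/25/1 percent among impact-bearing messages.
#'
#' @param n_users number of distinct authors.
#' @param posts_per_user_mean mean posts per author (>= 1); counts are drawn
#'   as 1 + Poisson(mean - 1).
#' @param female_rate probability an author is female.
#' @param age_mean,age_sd normal age distribution, truncated to 10-100 years
#'   by rejection.
#' @param date_range character vector `c("YYYY-MM", "YYYY-MM")`, first and
#'   last calendar month of posting activity.
#' @param seasonal_amplitude multiplier of expected November-March monthly
#'   volume relative to April-October (1 = no seasonality).
#' @param n_topics,vocab_size,topic_concentration planted topic structure;
#'   see [planted_topic_distributions()].
#' @param impact_rate probability a message expresses at least one impact.
#' @param impact_category_probs named probabilities, per QoL domain, that an
#'   impact-bearing message carries that domain (one message may carry
#'   several).
#' @param distractor_rates named probabilities that a message is generated
#'   as a filter distractor: `no_inclusion` (fails the keyword/inefficiency
#'   conjunction), `language` (non-French), `animal` (animal vocabulary),
#'   `exclusion` (study exclusion word).
#' @param gender_marker_prob probability a post carries a gendered
#'   agreement marker.
#' @param age_marker_prob probability a post states the author's age
#'   explicitly ("j'ai N ans" or "nee en YYYY").
#' @param username_name_prob probability the username embeds a gendered
#'   first name.
#' @param source_weights named nonnegative weights of the categorical
#'   source draw.
#' @param seed integer seed; the generator is byte-reproducible given the
#'   configuration.
#' @return a validated list of class `abx_generation_config`.
#' @export
generation_config <- function(n_users = 2335,
                              posts_per_user_mean = 1.62,
                              female_rate = 0.8622,
                              age_mean = 35,
                              age_sd = 10,
                              date_range = c("2014-01", "2020-07"),
                              seasonal_amplitude = 2,
                              n_topics = 13,
                              vocab_size = 20 * n_topics,
                              topic_concentration = 1,
                              impact_rate = 0.63,
                              impact_category_probs = c(
                                physical = 0.78, psychic = 0.65,
                                activity = 0.31, relational = 0.25,
                                financial = 0.01
                              ),
                              distractor_rates = c(
                                no_inclusion = 0.05, language = 0.04,
                                animal = 0.04, exclusion = 0.03
                              ),
                              gender_marker_prob = 0.8,
                              age_marker_prob = 0.5,
                              username_name_prob = 0.5,
                              source_weights = c(
                                twitter = 888, doctissimo = 885, atoute = 396,
                                futura = 260, aufeminin = 171, meamedica = 125,
                                psychologies = 94, onmeda = 94, youtube = 71,
                                vinted = 53, andlil = 39, pediablog = 13,
                                miniforum = 6, microblog = 3
                              ),
                              seed = 20140101) {
  cfg <- list(
    n_users = as.integer(n_users),
    posts_per_user_mean = posts_per_user_mean,
    female_rate = female_rate,
    age_mean = age_mean, age_sd = age_sd,
    date_range = date_range,
    seasonal_amplitude = seasonal_amplitude,
    n_topics = as.integer(n_topics),
    vocab_size = as.integer(vocab_size),
    topic_concentration = topic_concentration,
    impact_rate = impact_rate,
    impact_category_probs = impact_category_probs,
    distractor_rates = distractor_rates,
    gender_marker_prob = gender_marker_prob,
    age_marker_prob = age_marker_prob,
    username_name_prob = username_name_prob,
    source_weights = source_weights,
    seed = as.integer(seed)
  )
  probs <- c(
    cfg$female_rate, cfg$impact_rate, cfg$impact_category_probs,
    cfg$distractor_rates, cfg$gender_marker_prob, cfg$age_marker_prob,
    cfg$username_name_prob
  )
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (cfg$n_users < 1) stop("n_users must be >= 1")
  if (cfg$posts_per_user_mean < 1) stop("posts_per_user_mean must be >= 1")
  if (cfg$n_topics < 1) stop("n_topics must be >= 1")
  if (cfg$vocab_size < 10 * cfg$n_topics) {
    stop("vocab_size must be >= 10 * n_topics")
  }
  if (sum(cfg$distractor_rates) >= 1) stop("distractor rates must sum to < 1")
  if (cfg$seasonal_amplitude < 0) stop("seasonal_amplitude must be >= 0")
  if (!setequal(names(cfg$impact_category_probs),
                c("physical", "psychic", "activity", "relational", "financial"))) {
    stop("impact_category_probs must be named by the five QoL domains")
  }
  if (!setequal(names(cfg$distractor_rates),
                c("no_inclusion", "language", "animal", "exclusion"))) {
    stop("distractor_rates must be named no_inclusion/language/animal/exclusion")
  }
  if (any(cfg$source_weights < 0) || sum(cfg$source_weights) == 0) {
    stop("source_weights must be nonnegative with positive sum")
  }
  structure(cfg, class = "abx_generation_config")
}

# month sequence and seasonal sampling weights for a date range
seasonal_month_table <- function(date_range, amplitude) {
  start <- as.Date(paste0(date_range[1], "-01"))
  end <- as.Date(paste0(date_range[2], "-01"))
  if (is.na(start) || is.na(end) || start > end) {
    stop("date_range must be c('YYYY-MM', 'YYYY-MM') with start <= end")
  }
  months <- seq(start, end, by = "month")
  m <- as.integer(format(months, "%m"))
  data.frame(
    month_start = months,
    label = format(months, "%Y-%m"),
    cold_season = m %in% c(11L, 12L, 1L, 2L, 3L),
    weight = ifelse(m %in% c(11L, 12L, 1L, 2L, 3L), amplitude, 1),
    stringsAsFactors = FALSE
  )
}

# accented display phrases used for injection; folded matching is exercised
# because the lexicons store folded forms
.inject <- list(
  female_agreement = c(
    "je suis allée chez le médecin", "je suis inquiète",
    "je suis désolée d'insister", "je ne suis pas contente",
    "je serais soulagée d'en finir", "pas encore guérie",
    "je me sens seule face à ça", "je voudrais être rassurée"
  ),
  male_agreement = c(
    "je suis allé chez le médecin", "je suis inquiet",
    "je suis désolé d'insister", "je ne suis pas content",
    "je serais soulagé d'en finir", "pas encore guéri",
    "je me sens seul face à ça", "je voudrais être rassuré"
  ),
  impact = list(
    physical = c(
      "j'ai des douleurs partout", "une fatigue terrible",
      "des nausées sans arrêt", "encore de la fièvre",
      "des vertiges toute la journée", "la diarrhée continue"
    ),
    psychic = c(
      "une angoisse permanente", "la peur ne me quitte plus",
      "un désespoir total", "une vraie déprime",
      "le stress monte", "la dépression me guette"
    ),
    activity = c(
      "impossible d'aller au travail", "en arrêt maladie",
      "fini le sport", "mon quotidien est chamboulé",
      "encore en congé", "le boulot devient impossible"
    ),
    relational = c(
      "ma famille ne comprend rien", "un isolement total",
      "des tensions dans le couple", "mon entourage s'éloigne",
      "la relation se dégrade", "mes amis me manquent"
    ),
    financial = c(
      "des dépenses en plus", "aucun remboursement",
      "la mutuelle ne suit plus", "ça coûte cher",
      "des frais partout", "trop d'argent dépensé"
    )
  ),
  inefficiency_fixed = c(
    "c'est totalement inefficace", "toujours malade après la cure",
    "aucun effet sur l'infection", "le traitement est sans effet",
    "pas efficace du tout", "aucune amélioration depuis une semaine"
  ),
  inefficiency_verbs = c("marche", "fonctionne", "agit"),
  keyword_templates = c(
    "je prends des %s depuis dix jours", "sous %s depuis la semaine dernière",
    "encore une cure de %s", "le médecin m'a prescrit des %s",
    "on m'a remis sous %s"
  ),
  fillers = c(
    "vraiment", "franchement", "bref", "voila", "en fait", "du coup",
    "sinon", "enfin", "bon", "d'ailleurs"
  ),
  emoticons = c(":)", ":(", ";)", ":/"),
  animal = c(
    "c'est pareil pour mon chien", "même mon chat y a eu droit",
    "le vétérinaire en donne aussi", "comme pour les poules de la ferme",
    "idem pour le lapin de ma voisine"
  ),
  exclusion = c(
    "voir la publicite en bas de page", "grosse promotion ce mois ci",
    "attention au spam dans ce fil", "un concours est organise"
  ),
  english = c(
    "my doctor said it is not working and i am still sick",
    "i do not know what to do because the infection is still there",
    "this is very hard for me and my family said i should rest",
    "it was not better after a week and i am tired of it"
  )
)

# assemble the text of one post; returns the string
compose_post_text <- function(kind, lexicons, phi, topic, n_topic_tokens,
                              vocab, gender, inject_gender, age, inject_age,
                              post_year, categories, n_filler, n_exclaim,
                              n_emoticon) {
  if (kind == "language") {
    # keyword + inefficiency term kept so the post passes inclusion, but the
    # running text is English and carries no French function words
    kw <- sample(lexicons$inclusion_keywords, 1)
    eng <- sample(.inject$english, 3, replace = FALSE)
    return(paste(kw, "inefficace,", paste(eng, collapse = ", ")))
  }
  parts <- character(0)
  if (kind == "no_inclusion") {
    # violate the conjunction: keep exactly one side of it
    add_inclusion <- stats::runif(1) < 0.5
    add_ineff <- !add_inclusion
  } else {
    add_inclusion <- TRUE
    add_ineff <- TRUE
  }
  if (add_inclusion) {
    kw <- sample(lexicons$inclusion_keywords, 1)
    parts <- c(parts, sprintf(sample(.inject$keyword_templates, 1), kw))
  }
  if (add_ineff) {
    if (stats::runif(1) < 0.5) {
      parts <- c(parts, sample(.inject$inefficiency_fixed, 1))
    } else {
      verb <- sample(.inject$inefficiency_verbs, 1)
      gap <- sample(c("", "vraiment ", "toujours "), 1)
      parts <- c(parts, paste0("ça ne ", gap, verb, " pas"))
    }
  }
  if (n_topic_tokens > 0) {
    ids <- sample.int(nrow(phi), n_topic_tokens, replace = TRUE,
                      prob = phi[, topic])
    parts <- c(parts, paste(vocab[ids], collapse = " "))
  }
  if (inject_gender) {
    pool <- if (gender == "female") .inject$female_agreement else .inject$male_agreement
    parts <- c(parts, sample(pool, 1))
  }
  if (inject_age) {
    if (stats::runif(1) < 0.7) {
      parts <- c(parts, paste0("j'ai ", age, " ans"))
    } else {
      birth <- post_year - age
      nee <- if (gender == "female") "née" else "né"
      parts <- c(parts, paste(nee, "en", birth))
    }
  }
  for (cat in categories) {
    parts <- c(parts, sample(.inject$impact[[cat]], 1))
  }
  if (kind == "animal") parts <- c(parts, sample(.inject$animal, 1))
  if (kind == "exclusion") parts <- c(parts, sample(.inject$exclusion, 1))
  if (n_filler > 0) {
    parts <- c(parts, paste(sample(.inject$fillers, n_filler, replace = TRUE),
                            collapse = " "))
  }
  text <- paste(parts, collapse = ", ")
  if (n_exclaim > 0) text <- paste0(text, " ", strrep("!", n_exclaim))
  if (n_emoticon > 0) {
    text <- paste(text, paste(sample(.inject$emoticons, n_emoticon,
                                     replace = TRUE), collapse = " "))
  }
  text
}

#' Generate a synthetic post corpus with latent ground truth
#'
#' Draws authors (gender, age, username, posting volume), assigns each post
#' a source, a seasonally weighted timestamp, one latent topic, an optional
#' impact-category set and an intended filter fate, then composes message
#' text that carries the corresponding lexical evidence: an antibiotic
#' keyword conjoined with an inefficiency phrase (unless the post is a
#' `no_inclusion` distractor), topic tokens drawn from the planted
#' distributions, gendered agreement markers, explicit age statements, one
#' lexical-field phrase per impact domain, and distractor triggers (English
#' text, animal vocabulary, exclusion words). Writing style varies with
#' author age (younger authors use more exclamation marks and emoticons and
#' write shorter messages), which is the learnable signal for the model
#' fallback of the age pipeline.
#'
#' @param config a [generation_config()].
#' @param lexicons lexicon set used for injection; defaults to
#'   [default_lexicons()].
#' @return list with elements `posts` (data frame: id, source, timestamp,
#'   author, text), `ground_truth` (one row per post: latent gender, age,
#'   topic, impact flags, filter fate and reason code, marker bookkeeping),
#'   `users` (per-user latent table), `topics` (planted `V x K` matrix) and
#'   `vocab`.
#' @export
generate_corpus <- function(config = generation_config(),
                            lexicons = default_lexicons()) {
  if (!inherits(config, "abx_generation_config")) {
    config <- do.call(generation_config, as.list(config))
  }
  set.seed(config$seed)
  K <- config$n_topics
  V <- config$vocab_size
  phi <- planted_topic_distributions(K, V, config$topic_concentration,
                                     seed = config$seed + 1L)
  vocab <- pseudo_vocab(V)
  months <- seasonal_month_table(config$date_range, config$seasonal_amplitude)
  p_adj <- conditional_category_probs(config$impact_category_probs)
  cat_names <- names(config$impact_category_probs)

  n_users <- config$n_users
  genders <- ifelse(stats::runif(n_users) < config$female_rate, "female", "male")
  ages <- vapply(seq_len(n_users), function(i) {
    repeat {
      a <- stats::rnorm(1, config$age_mean, config$age_sd)
      if (a >= 10 && a <= 100) return(round(a))
    }
  }, numeric(1))
  n_posts_user <- 1L + stats::rpois(n_users, config$posts_per_user_mean - 1)
  usernames <- character(n_users)
  name_flags <- stats::runif(n_users) < config$username_name_prob
  for (i in seq_len(n_users)) {
    if (name_flags[i]) {
      pool <- if (genders[i] == "female") lexicons$female_names else lexicons$male_names
      usernames[i] <- paste0(sample(pool, 1), sample(10:99, 1))
    } else {
      usernames[i] <- sprintf("user%05d", i)
    }
  }
  # handles are identities: disambiguate the rare name+digits collisions
  usernames <- make.unique(usernames, sep = "x")

  n_posts <- sum(n_posts_user)
  user_idx <- rep(seq_len(n_users), n_posts_user)
  src <- sample(names(config$source_weights), n_posts, replace = TRUE,
                prob = config$source_weights / sum(config$source_weights))
  month_i <- sample.int(nrow(months), n_posts, replace = TRUE,
                        prob = months$weight / sum(months$weight))
  day <- sample.int(28L, n_posts, replace = TRUE)
  hour <- sample.int(24L, n_posts, replace = TRUE) - 1L
  minute <- sample.int(60L, n_posts, replace = TRUE) - 1L
  timestamps <- sprintf("%sT%02d:%02d:00Z",
                        format(months$month_start[month_i] + (day - 1L), "%Y-%m-%d"),
                        hour, minute)

  dr <- config$distractor_rates
  kind <- sample(c(names(dr), "kept"), n_posts, replace = TRUE,
                 prob = c(dr, 1 - sum(dr)))
  topic <- sample.int(K, n_posts, replace = TRUE)
  has_imp <- stats::runif(n_posts) < config$impact_rate
  cat_mat <- matrix(FALSE, n_posts, length(cat_names),
                    dimnames = list(NULL, cat_names))
  for (j in which(has_imp)) cat_mat[j, ] <- draw_impact_categories(p_adj)

  inj_gender <- stats::runif(n_posts) < config$gender_marker_prob
  inj_age <- stats::runif(n_posts) < config$age_marker_prob
  age_u <- ages[user_idx]
  gender_u <- genders[user_idx]
  n_topic_tok <- 4L + stats::rpois(n_posts, 4)
  n_filler <- stats::rpois(n_posts, 1.5 + age_u / 8)
  n_exclaim <- stats::rpois(n_posts, pmax(0, (50 - age_u) / 15))
  n_emoticon <- stats::rpois(n_posts, pmax(0, (45 - age_u) / 12))
  post_year <- as.integer(substr(timestamps, 1, 4))

  text <- character(n_posts)
  for (j in seq_len(n_posts)) {
    cats <- cat_names[cat_mat[j, ]]
    text[j] <- compose_post_text(
      kind[j], lexicons, phi, topic[j], n_topic_tok[j], vocab,
      gender_u[j], inj_gender[j], age_u[j], inj_age[j], post_year[j],
      cats, n_filler[j], n_exclaim[j], n_emoticon[j]
    )
  }

  ids <- sprintf("p%06d", seq_len(n_posts))
  posts <- data.frame(
    id = ids, source = src, timestamp = timestamps,
    author = usernames[user_idx], text = text,
    stringsAsFactors = FALSE
  )
  reason <- c(
    kept = "kept", no_inclusion = "no_inclusion",
    language = "non_target_language", animal = "animal_vocabulary",
    exclusion = "exclusion_word"
  )[kind]
  ground_truth <- data.frame(
    id = ids, user_id = sprintf("u%05d", user_idx),
    true_gender = gender_u, true_age = age_u, true_topic = topic,
    has_impact = has_imp, stringsAsFactors = FALSE
  )
  for (cat in cat_names) ground_truth[[paste0("impact_", cat)]] <- cat_mat[, cat]
  ground_truth$true_impact_categories <-
    apply(cat_mat, 1, function(r) paste(cat_names[r], collapse = ";"))
  ground_truth$should_survive_filter <- kind == "kept"
  ground_truth$filter_reason <- unname(reason)
  ground_truth$has_gender_marker <- inj_gender | name_flags[user_idx]
  ground_truth$has_age_marker <- inj_age
  users <- data.frame(
    user_id = sprintf("u%05d", seq_len(n_users)), username = usernames,
    gender = genders, age = ages, n_posts = n_posts_user,
    has_name_username = name_flags, stringsAsFactors = FALSE
  )
  list(posts = posts, ground_truth = ground_truth, users = users,
       topics = phi, vocab = vocab)
}

#' Read and write post corpora as JSON-lines
#'
#' One JSON object per line with fields id, source, timestamp (ISO-8601),
#' author and text.
#'
#' @param posts data frame with those columns.
#' @param path file path.
#' @return `read_posts_jsonl` returns the posts data frame.
#' @export
write_posts_jsonl <- function(posts, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (j in seq_len(nrow(posts))) {
    writeLines(jsonlite::toJSON(as.list(posts[j, , drop = FALSE]),
                                auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_posts_jsonl
#' @export
read_posts_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(l) {
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Non-topical scaffold vocabulary of the generator
#'
#' Every token the generator can emit outside the planted topic
#' distributions: phrase templates, marker phrases, distractor triggers and
#' fillers. By construction these tokens carry author attributes or filter
#' fate, never the latent theme, so topic-structure evaluations on
#' synthetic corpora add them to the stopword list before fitting.
#'
#' @return character vector of folded tokens.
#' @export
generator_scaffold_tokens <- function() {
  src <- c(
    .inject$female_agreement, .inject$male_agreement,
    unlist(.inject$impact, use.names = FALSE),
    .inject$inefficiency_fixed, .inject$inefficiency_verbs,
    gsub("%s", " ", .inject$keyword_templates, fixed = TRUE),
    .inject$fillers, .inject$animal, .inject$exclusion, .inject$english,
    "nee ne ans"
  )
  # split exactly as preprocess_corpus does (apostrophes are separators)
  toks <- unlist(stringi::stri_split_regex(fold_text(src), "[^a-z]+"),
                 use.names = FALSE)
  sort(unique(toks[nzchar(toks)]))
}
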