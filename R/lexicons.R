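#' Lexicon sets driving every rule-based stage
#'
#' A lexicon set is a named list of word/phrase families: corpus inclusion
#' (antibiotic keywords + the inefficiency lexical field), the exclusion
#' cascade (non-target-language stopword profiles, animal vocabulary,
#' study-specific exclusion words), gender markers (first names,
#' username affixes, gendered lexical fields, adjective/participle
#' agreements), sentiment words, and one lexical field per quality-of-life
#' domain. All terms are stored accent-folded; matching is case- and
#' accent-insensitive on token boundaries.
#'
#' The study-specific exclusion-word list of the original analysis is not
#' public; `exclusion_words` ships as a small configurable placeholder and
#' must be replaced with the study list to replicate the original filtering.
#'
#' @return A list of class `abx_lexicons`.
#' @export
default_lexicons <- function() {
  lex <- list(
    inclusion_keywords = c(
      "antibiotique", "antibiotiques", "antibio", "antibios",
      "antibiotherapie", "amoxicilline", "augmentin", "penicilline",
      "azithromycine", "ciprofloxacine"
    ),
    # Fixed phrases of the inefficiency lexical field; the "ne ... pas"
    # negation family around efficacy verbs is handled by
    # inefficiency_negation_verbs with a bounded token gap.
    inefficiency_field = c(
      "inefficace", "inefficaces", "inefficacite", "sans effet",
      "aucun effet", "pas efficace", "pas efficaces", "ne fait rien",
      "n'a rien fait", "echec du traitement", "resistance", "resistant",
      "resistante", "toujours malade", "aucune amelioration"
    ),
    inefficiency_negation_verbs = c(
      "marche", "marchent", "fonctionne", "fonctionnent", "agit",
      "agissent", "guerit", "guerissent", "soulage", "soulagent",
      "repond", "repondent"
    ),
    exclusion_words = c(
      "publicite", "promotion", "spam", "concours"
    ),
    animal_vocabulary = c(
      "chien", "chiens", "chienne", "chiot", "chat", "chats", "chaton",
      "cheval", "chevaux", "lapin", "lapins", "hamster", "perroquet",
      "vache", "vaches", "mouton", "moutons", "poule", "poules",
      "veterinaire"
    ),
    language_profiles = list(
      fr = c(
        "le", "la", "les", "un", "une", "des", "de", "du", "et", "ou",
        "je", "tu", "il", "elle", "on", "nous", "vous", "ils", "elles",
        "ne", "pas", "plus", "que", "qui", "quoi", "dans", "pour",
        "avec", "sans", "mais", "mon", "ma", "mes", "est", "suis",
        "sont", "ai", "avoir", "etre", "fait", "tres", "bien", "ca",
        "cette", "ce", "se", "sa", "son", "aussi", "chez", "depuis"
      ),
      en = c(
        "the", "a", "an", "and", "or", "of", "to", "in", "on", "for",
        "with", "without", "i", "you", "he", "she", "we", "they", "it",
        "is", "are", "was", "were", "am", "be", "been", "have", "has",
        "had", "not", "no", "my", "your", "his", "her", "this", "that",
        "but", "very", "also", "since", "do", "does", "did", "me", "said"
      ),
      es = c(
        "el", "los", "las", "uno", "una", "unos", "y", "o", "en",
        "por", "para", "con", "sin", "yo", "ella", "nosotros",
        "ellos", "es", "son", "era", "estoy", "tengo", "hay",
        "pero", "muy", "tambien", "desde", "mi", "mis", "esta", "este"
      )
    ),
    female_names = c(
      "marie", "sophie", "julie", "emma", "claire", "lea", "chloe",
      "manon", "laura", "camille", "nathalie", "isabelle", "lucie",
      "celine", "aurelie", "charlotte", "pauline", "elodie", "sandrine",
      "valerie"
    ),
    male_names = c(
      "pierre", "jean", "paul", "nicolas", "thomas", "lucas", "hugo",
      "louis", "marc", "antoine", "julien", "kevin", "olivier", "romain",
      "david", "vincent", "sebastien", "guillaume", "maxime", "alexandre"
    ),
    female_affixes = c("mme", "madame", "mlle", "miss", "girl", "fille", "maman"),
    male_affixes = c("mr", "monsieur", "boy", "mec", "papa"),
    female_phrases = c(
      "mon mari", "mon copain", "enceinte", "ma grossesse",
      "mes regles", "gyneco"
    ),
    male_phrases = c(
      "ma femme", "ma copine", "ma cherie", "prostate", "ma barbe"
    ),
    # Unambiguous feminine/masculine agreement pairs of past participles and
    # adjectives. Forms whose spelling collides with a common noun or with a
    # symptom adjective used by the QoL lexicons (e.g. "fatigue", "angoisse",
    # "deprime", "epuise") are deliberately excluded so that a gender cue is
    # never also a health-domain cue.
    female_agreements = c(
      "allee", "inquiete", "desolee", "contente", "soulagee",
      "guerie", "seule", "rassuree"
    ),
    male_agreements = c(
      "alle", "inquiet", "desole", "content", "soulage",
      "gueri", "seul", "rassure"
    ),
    sentiment_negative = c(
      "peur", "angoisse", "angoissee", "desespoir", "anxieux", "anxieuse",
      "deprime", "deprimee", "depression", "marre", "horrible", "pire",
      "inquiet", "inquiete", "stress", "stresse", "stressee", "douleur",
      "douleurs", "epuise", "epuisee", "mal"
    ),
    sentiment_positive = c(
      "merci", "espoir", "mieux", "soulage", "soulagee", "content",
      "contente", "super", "gueri", "guerie", "courage", "rassure",
      "rassuree"
    ),
    qol_domains = list(
      physical = c(
        "douleur", "douleurs", "fatigue", "epuise", "epuisee",
        "epuisement", "symptomes", "diarrhee", "nausees", "vertiges",
        "fievre", "insomnie", "mal au ventre", "mal partout",
        "effets secondaires"
      ),
      psychic = c(
        "angoisse", "angoissee", "anxieuse", "anxieux", "peur",
        "desespoir", "deprime", "deprimee", "depression", "stress",
        "stressee", "moral a zero", "panique"
      ),
      activity = c(
        "travail", "boulot", "arret de travail", "arret maladie",
        "sport", "quotidien", "conge", "activites", "sortir"
      ),
      relational = c(
        "famille", "mari", "couple", "isolement", "isolee", "amis",
        "sexualite", "relation", "entourage"
      ),
      financial = c(
        "argent", "cout", "couteux", "cher", "rembourse",
        "remboursement", "mutuelle", "depenses", "frais"
      )
    ),
    target_language = "fr"
  )
  structure(lex, class = "abx_lexicons")
}

#' Validate a lexicon set
#'
#' Checks the structural invariants: mandatory non-empty families, language
#' profiles present for the target language, and that every term compiles to
#' a valid matching pattern.
#'
#' @param lexicons a lexicon list as returned by [default_lexicons()].
#' @return the validated lexicon set, invisibly.
#' @export
validate_lexicons <- function(lexicons) {
  required <- c(
    "inclusion_keywords", "inefficiency_field", "exclusion_words",
    "animal_vocabulary", "language_profiles", "qol_domains",
    "target_language"
  )
  missing <- setdiff(required, names(lexicons))
  if (length(missing) > 0) {
    stop("lexicon set is missing families: ", paste(missing, collapse = ", "))
  }
  if (length(lexicons$inclusion_keywords) == 0) {
    stop("inclusion_keywords must be non-empty")
  }
  if (length(lexicons$inefficiency_field) == 0) {
    stop("inefficiency_field must be non-empty")
  }
  if (!lexicons$target_language %in% names(lexicons$language_profiles)) {
    stop("no language profile for target language '", lexicons$target_language, "'")
  }
  flat <- unlist(lexicons[vapply(lexicons, is.character, logical(1))],
                 use.names = FALSE)
  for (term in flat) {
    ok <- tryCatch(
      { stringi::stri_detect_regex("x", term_regex(term)); TRUE },
      error = function(e) FALSE
    )
    if (!ok) stop("lexicon term does not compile: '", term, "'")
  }
  invisible(lexicons)
}

#' Read or write lexicons as JSON
#'
#' @param path file path.
#' @return `read_lexicons` returns a validated `abx_lexicons` list.
#' @export
read_lexicons <- function(path) {
  lex <- jsonlite::read_json(path, simplifyVector = TRUE)
  lex$language_profiles <- lapply(lex$language_profiles, as.character)
  lex$qol_domains <- lapply(lex$qol_domains, as.character)
  lex <- structure(lex, class = "abx_lexicons")
  validate_lexicons(lex)
  lex
}

#' @rdname read_lexicons
#' @param lexicons a lexicon set.
#' @export
write_lexicons <- function(lexicons, path) {
  jsonlite::write_json(unclass(lexicons), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' French stopwords plus analysis-lexicon terms for topic modelling
#'
#' The default topic-model stopword list joins a basic French function-word
#' list with the retrieval lexicons (antibiotic keywords and the
#' inefficiency field) and, optionally, all marker lexicons. Query terms
#' appear in essentially every retrieved message, so leaving them in the
#' vocabulary produces one high-probability token shared by all topics;
#' removing corpus-defining terms before topic modelling is standard
#' practice for keyword-retrieved corpora.
#'
#' @param lexicons lexicon set whose retrieval/marker terms are appended;
#'   `NULL` for the plain French function-word list.
#' @param include_markers also drop gender-agreement, sentiment and
#'   QoL-domain terms (they track author attributes, not discussion themes).
#' @return character vector of folded stopword tokens.
#' @export
default_stopwords <- function(lexicons = default_lexicons(),
                              include_markers = TRUE) {
  base <- c(
    "le", "la", "les", "un", "une", "des", "de", "du", "d", "l", "et",
    "ou", "je", "j", "tu", "il", "elle", "on", "nous", "vous", "ils",
    "elles", "ne", "n", "pas", "plus", "que", "qui", "quoi", "dont",
    "dans", "pour", "par", "avec", "sans", "mais", "donc", "car", "si",
    "mon", "ma", "mes", "ton", "ta", "tes", "son", "sa", "ses", "ce",
    "cet", "cette", "ces", "se", "me", "te", "moi", "toi", "lui", "leur",
    "est", "suis", "es", "sont", "etait", "ete", "etre", "ai", "as",
    "a", "avons", "avez", "ont", "avoir", "fait", "faire", "tres",
    "bien", "mal", "tout", "tous", "toute", "toutes", "rien", "ca",
    "cela", "y", "en", "au", "aux", "chez", "sur", "sous", "apres",
    "avant", "depuis", "pendant", "entre", "vers", "aussi", "encore",
    "deja", "toujours", "jamais", "ans", "an", "jour", "jours", "mois",
    "prends", "pris", "prendre", "hier", "aujourd", "hui", "quand",
    "comme", "meme", "alors", "puis", "peu", "trop", "aucun", "aucune",
    "vraiment", "franchement", "bref", "voila", "sinon", "ailleurs",
    "coup", "bon", "enfin", "surtout"
  )
  if (is.null(lexicons)) {
    return(unique(base))
  }
  extra <- c(
    lexicons$inclusion_keywords,
    lexicons$inefficiency_field,
    lexicons$inefficiency_negation_verbs
  )
  if (isTRUE(include_markers)) {
    extra <- c(
      extra,
      lexicons$female_agreements, lexicons$male_agreements,
      lexicons$female_phrases, lexicons$male_phrases,
      lexicons$sentiment_negative, lexicons$sentiment_positive,
      unlist(lexicons$qol_domains, use.names = FALSE)
    )
  }
  # multi-word phrases contribute their individual tokens
  extra_tokens <- unlist(fold_tokens(extra), use.names = FALSE)
  unique(c(base, fold_text(extra), extra_tokens))
}
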