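#' Default synthetic-note lexicon
#'
#' Term lists used by the corpus generator: per-class diagnostic keyword
#' phrases (Italian pediatric shorthand, including laterality abbreviations),
#' a background vocabulary of common visit words, negation and
#' other-doctor templates (the confounders that drive misclassification of
#' otitis mentions in real notes), atypical phrasings of tympanic-membrane
#' perforation, and drug names for the prescription field.
#'
#' The `no_otitis` keywords deliberately contain the stem `"oma"`
#' (`ematoma`, `angioma`, ...) so that true negatives still match an
#' otitis search pattern, as spurious matches do in real free-text
#' screening. Keyword sets are pairwise distinguishable: no class's set is
#' a subset of another's, and the longest matching phrase always
#' identifies the generating class on noise-free text (see
#' [keyword_oracle()]).
#'
#' @return A list of class `otitis_lexicon` with elements `keywords` (named
#'   list over [otitis_classes()]), `recurrent_history`, `background`,
#'   `negation_templates`, `other_doctor_templates`, `atypical_perforation`,
#'   and `drugs`.
#' @examples
#' lex <- default_lexicon()
#' names(lex$keywords)
#' @export
default_lexicon <- function() {
  lex <- list(
    keywords = list(
      no_otitis = c(
        "ematoma frontale", "angioma cutaneo", "fibroma palpebrale",
        "granuloma ombelicale", "papilloma plantare"
      ),
      otitis_not_media = c(
        "otite esterna", "otite del condotto uditivo",
        "otite esterna diffusa", "otite est"
      ),
      om_not_acute = c(
        "otite media sierosa", "otite media catarrale",
        "otite media cronica", "otite media effusiva"
      ),
      aom = c(
        "otite media acuta", "oma bilaterale", "oma dx", "oma sx",
        "otite media acuta bilaterale"
      ),
      aom_perforation = c(
        "otite media acuta perforata", "oma perforata",
        "otite media acuta con perforazione timpanica",
        "perforazione della membrana timpanica"
      ),
      aom_recurrent = c(
        "otite media acuta ricorrente", "oma ricorrente", "otite ricorrente"
      )
    ),
    recurrent_history = c(
      "terzo episodio di oma in sei mesi",
      "quarto episodio di otite media acuta in dodici mesi"
    ),
    background = c(
      "bambino", "febbre", "da", "giorni", "tosse", "rinite", "visita",
      "controllo", "orecchio", "dolore", "pianto", "notturno", "iperemia",
      "faringe", "condizioni", "generali", "buone", "terapia", "in", "atto",
      "madre", "riferisce", "da", "ieri", "persistente"
    ),
    negation_templates = c(
      "si esclude otite", "non otite", "negativo per otite",
      "niente otite timpani normali", "esclusa otite all esame"
    ),
    other_doctor_templates = c(
      "il collega otorino riferisce otite da rivalutare",
      "diagnosi di otite in pronto soccorso da confermare",
      "la guardia medica sospettava otite"
    ),
    atypical_perforation = c(
      "otorrea purulenta abbondante",
      "secrezione dal condotto con membrana timpanica lacerata",
      "timpano lacerato con essudato"
    ),
    drugs = c("amoxicillina", "paracetamolo", "ibuprofene", "cefixima",
              "amoxicillina clavulanato")
  )
  class(lex) <- c("otitis_lexicon", "list")
  validate_lexicon(lex)
  lex
}

#' Validate a lexicon
#'
#' Checks that all six classes have at least one keyword phrase and that
#' keyword sets are pairwise distinguishable (no class's set is a subset of
#' another's).
#'
#' @param lexicon A lexicon list as returned by [default_lexicon()] or
#'   [read_lexicon()].
#' @return The lexicon, invisibly, if valid; otherwise an error.
#' @export
validate_lexicon <- function(lexicon) {
  cls <- otitis_classes()
  missing <- setdiff(cls, names(lexicon$keywords))
  if (length(missing) > 0) {
    stop("lexicon is missing keyword lists for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  empty <- cls[vapply(lexicon$keywords[cls], length, 1L) == 0]
  if (length(empty) > 0) {
    stop("lexicon has empty keyword lists for: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  for (a in cls) {
    for (b in setdiff(cls, a)) {
      if (all(lexicon$keywords[[a]] %in% lexicon$keywords[[b]])) {
        stop("keyword set of '", a, "' is a subset of '", b,
             "': classes are not distinguishable", call. = FALSE)
      }
    }
  }
  invisible(lexicon)
}

#' Read / write a lexicon as YAML
#'
#' @param path File path.
#' @param lexicon A lexicon list.
#' @return `read_lexicon()` returns a validated `otitis_lexicon`;
#'   `write_lexicon()` returns `path` invisibly.
#' @export
read_lexicon <- function(path) {
  lex <- yaml::read_yaml(path)
  class(lex) <- c("otitis_lexicon", "list")
  validate_lexicon(lex)
  lex
}

#' @rdname read_lexicon
#' @export
write_lexicon <- function(lexicon, path) {
  yaml::write_yaml(unclass(lexicon), path)
  invisible(path)
}

#' Longest-keyword-match oracle classifier
#'
#' A transparent rule-based classifier used to establish that a synthetic
#' corpus is learnable: for each record it scans all text fields for every
#' lexicon keyword phrase (plus the recurrent history phrases) and returns
#' the class of the longest matching phrase. On a corpus generated with all
#' confounder and typo rates at zero this recovers the gold label exactly.
#'
#' @param corpus A visit-record tibble (see [generate_corpus()]).
#' @param lexicon A lexicon; defaults to [default_lexicon()].
#' @return The input with a `oracle_label` factor column appended.
#' @export
keyword_oracle <- function(corpus, lexicon = default_lexicon()) {
  cls <- otitis_classes()
  phrases <- purrr::map(cls, function(cl) {
    kw <- lexicon$keywords[[cl]]
    if (cl == "aom_recurrent") kw <- c(kw, lexicon$recurrent_history)
    kw
  })
  names(phrases) <- cls
  texts <- record_texts(corpus)
  lab <- vapply(texts, function(txt) {
    best_cls <- NA_character_
    best_len <- -1L
    for (cl in cls) {
      for (kw in phrases[[cl]]) {
        if (any(stringr::str_detect(txt, stringr::fixed(kw))) &&
            nchar(kw) > best_len) {
          best_len <- nchar(kw)
          best_cls <- cl
        }
      }
    }
    best_cls
  }, character(1))
  corpus$oracle_label <- otitis_factor(lab)
  corpus
}

# list of character vectors: the text fields of each record, in field order
record_texts <- function(corpus) {
  flds <- intersect(visit_text_fields(), names(corpus))
  purrr::pmap(corpus[flds], function(...) as.character(c(...)))
}
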