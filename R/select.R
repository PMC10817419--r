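#' Compile a free-text search pattern
#'
#' Builds the screening pattern used to pull otitis-relevant records out of
#' a large visit database. Terms may be literal substrings or regular
#' expressions; a text matches the pattern iff any term matches it.
#'
#' @param terms Character vector of terms (at least one).
#' @param regex Logical scalar or vector: is each term a regular
#'   expression? Literal terms are matched as fixed substrings.
#' @param case_insensitive Match case-insensitively (default `TRUE`).
#' @return An object of class `otitis_search_pattern`.
#' @examples
#' pat <- compile_search_pattern(c("otit", "oma"))
#' pattern_matches(pat, c("OTITE MEDIA", "controllo vaccinale"))
#' @export
compile_search_pattern <- function(terms, regex = FALSE,
                                   case_insensitive = TRUE) {
  if (length(terms) == 0) {
    stop("at least one search term is required", call. = FALSE)
  }
  regex <- rep_len(as.logical(regex), length(terms))
  for (i in which(regex)) {
    ok <- tryCatch({grepl(terms[i], ""); TRUE},
                   error = function(e) FALSE,
                   warning = function(w) FALSE)
    if (!ok) {
      stop("invalid regular expression in term: '", terms[i], "'",
           call. = FALSE)
    }
  }
  structure(
    list(terms = as.character(terms), regex = regex,
         case_insensitive = isTRUE(case_insensitive)),
    class = "otitis_search_pattern")
}

#' Does a pattern match each text?
#'
#' @param pattern An `otitis_search_pattern`.
#' @param texts Character vector.
#' @return Logical vector: does any term match each text?
#' @export
pattern_matches <- function(pattern, texts) {
  ci <- pattern$case_insensitive
  hit <- rep(FALSE, length(texts))
  for (i in seq_along(pattern$terms)) {
    matcher <- if (pattern$regex[i]) {
      stringr::regex(pattern$terms[i], ignore_case = ci)
    } else {
      stringr::fixed(pattern$terms[i], ignore_case = ci)
    }
    hit <- hit | stringr::str_detect(texts, matcher)
  }
  hit
}

#' Select otitis-relevant records by free-text search
#'
#' A record is retained iff the pattern matches at least one of its text
#' fields, each field scanned on its own (no cross-field concatenation, so
#' no spurious matches across field boundaries). Original record order is
#' preserved.
#'
#' @param corpus A visit-record tibble.
#' @param pattern An `otitis_search_pattern`; defaults to
#'   [default_search_pattern()].
#' @return The retained subset of `corpus`, same columns, original order.
#' @export
select_records <- function(corpus, pattern = default_search_pattern()) {
  if (nrow(corpus) == 0) return(corpus)
  texts <- record_texts(corpus)
  keep <- vapply(texts, function(txt) any(pattern_matches(pattern, txt)),
                 logical(1))
  corpus[keep, , drop = FALSE]
}

#' Default otitis screening pattern
#'
#' The original screening string is not public; this default captures its
#' intent: the stems `otit` (all otitis forms), `oma` (catches
#' `oma`-abbreviated acute otitis media — and, deliberately, `-oma` nouns
#' like `ematoma`, which is why a `no_otitis` class exists downstream),
#' `timpan`/`otorrea`/`perfor` (perforation descriptions that omit the
#' word otitis), plus one-edit misspellings of `otite`. Fully overridable: pass your own
#' [compile_search_pattern()] or a YAML term file via
#' [read_search_pattern()].
#'
#' @return An `otitis_search_pattern`.
#' @export
default_search_pattern <- function() {
  compile_search_pattern(
    terms = c("otit", "oma", "timpan", "otorrea", "perfor",
              "otie", "oite", "otte", "tite", "ot[i1l]te"),
    regex = c(rep(FALSE, 9), TRUE),
    case_insensitive = TRUE)
}

#' Read / write a search pattern as YAML
#'
#' The file is a list of entries with `term` and optional `regex` flag,
#' plus a top-level `case_insensitive` flag.
#'
#' @param path File path.
#' @param pattern An `otitis_search_pattern`.
#' @return `read_search_pattern()` returns an `otitis_search_pattern`.
#' @export
read_search_pattern <- function(path) {
  y <- yaml::read_yaml(path)
  terms <- vapply(y$terms, function(e) {
    if (is.list(e)) e$term else as.character(e)
  }, character(1))
  regex <- vapply(y$terms, function(e) {
    if (is.list(e)) isTRUE(e$regex) else FALSE
  }, logical(1))
  compile_search_pattern(terms, regex,
                         case_insensitive = y$case_insensitive %||% TRUE)
}

#' @rdname read_search_pattern
#' @export
write_search_pattern <- function(pattern, path) {
  yaml::write_yaml(list(
    case_insensitive = pattern$case_insensitive,
    terms = purrr::map2(pattern$terms, pattern$regex,
                        function(t, r) list(term = t, regex = r))
  ), path)
  invisible(path)
}
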