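#' Reserved vocabulary tokens
#'
#' `PAD` (index 0) fills sequences out to the fixed length and is embedded
#' as a zero vector; `OOV` stands in for tokens unseen when the vocabulary
#' was built; `SEP` marks boundaries between merged text fields; `NUM`
#' replaces numeric tokens.
#'
#' @return Character vector `c("PAD", "OOV", "SEP", "NUM")`, in index order.
#' @export
reserved_tokens <- function() c("PAD", "OOV", "SEP", "NUM")

#' Text preprocessing configuration
#'
#' @param max_length Fixed encoded sequence length `L`; longer token
#'   streams keep their first `L` tokens (the diagnosis field comes first
#'   in merged order, so the head carries the signal), shorter ones are
#'   padded with `PAD`.
#' @param lowercase Lowercase text before tokenizing.
#' @param number_pattern Regex a whole token must match to be replaced by
#'   `NUM`. The default covers integers and decimals with comma or point;
#'   mixed alphanumerics (`b12`) are left untouched.
#' @return A list of class `otitis_preprocess_config`.
#' @export
preprocess_config <- function(max_length = 1000L,
                              lowercase = TRUE,
                              number_pattern = "^[0-9]+([.,][0-9]+)?$") {
  if (max_length < 1) stop("max_length must be >= 1", call. = FALSE)
  structure(list(max_length = as.integer(max_length),
                 lowercase = isTRUE(lowercase),
                 number_pattern = number_pattern),
            class = c("otitis_preprocess_config", "list"))
}

#' Tokenize free text
#'
#' Lowercases (optionally), drops punctuation — except a decimal comma or
#' point between digits, which stays inside its numeric token — and splits
#' on whitespace.
#'
#' @param text Character vector of texts.
#' @param lowercase Lowercase first?
#' @return A list of character token vectors, one per input text.
#' @examples
#' tokenize_text("Otite media acuta, febbre 38,5.")
#' @export
tokenize_text <- function(text, lowercase = TRUE) {
  if (lowercase) text <- tolower(text)
  # protect decimal separators so "38,5" stays one token
  text <- gsub("(?<=[0-9])\\.(?=[0-9])", "", text, perl = TRUE)
  text <- gsub("(?<=[0-9]),(?=[0-9])", "", text, perl = TRUE)
  text <- gsub("[[:punct:]]+", " ", text)
  text <- gsub("", ".", text, fixed = TRUE)
  text <- gsub("", ",", text, fixed = TRUE)
  toks <- strsplit(trimws(text), "[[:space:]]+")
  lapply(toks, function(t) t[nzchar(t)])
}

#' Merge a record's text fields into one token stream
#'
#' Fields are tokenized in their stored order (`diagnosis`, `notes`,
#' `prescriptions`) and joined with a single `SEP` token between
#' consecutive non-empty fields; empty fields contribute no tokens and no
#' extra separator.
#'
#' @param record A one-row tibble or named list holding the text fields.
#' @param lowercase Passed to [tokenize_text()].
#' @return Character vector of tokens (possibly empty).
#' @examples
#' merge_fields(list(diagnosis = "otite media acuta",
#'                   notes = "", prescriptions = "amoxicillina 50 mg"))
#' @export
merge_fields <- function(record, lowercase = TRUE) {
  flds <- intersect(visit_text_fields(), names(record))
  if (length(flds) == 0) stop("record has no text fields", call. = FALSE)
  texts <- vapply(flds, function(f) as.character(record[[f]][[1]]),
                  character(1))
  toks <- tokenize_text(texts, lowercase = lowercase)
  toks <- toks[lengths(toks) > 0]
  if (length(toks) == 0) return(character(0))
  out <- toks[[1]]
  for (t in toks[-1]) out <- c(out, "SEP", t)
  out
}

#' Replace numeric tokens with NUM
#'
#' @param tokens Character vector of tokens.
#' @param config An [preprocess_config()]; its `number_pattern` decides
#'   what counts as a number.
#' @return Tokens with every number replaced by `"NUM"`.
#' @examples
#' normalize_numbers(c("amoxicillina", "50", "mg", "38,5", "b12"))
#' @export
normalize_numbers <- function(tokens, config = preprocess_config()) {
  tokens[grepl(config$number_pattern, tokens)] <- "NUM"
  tokens
}

#' Build a vocabulary from token streams
#'
#' Indices are assigned reserved-tokens-first (`PAD` = 0, `OOV` = 1,
#' `SEP` = 2, `NUM` = 3), then remaining tokens by descending corpus
#' frequency, ties broken lexicographically. Tokens rarer than `min_count`
#' are dropped (they will encode as `OOV`).
#'
#' @param streams A list of character token vectors (already normalized).
#' @param min_count Minimum corpus frequency to enter the vocabulary.
#' @return An object of class `otitis_vocabulary`: list with `tokens`
#'   (character vector in index order), `index` (named 0-based integer
#'   vector), and `size`.
#' @export
build_vocabulary <- function(streams, min_count = 1L) {
  res <- reserved_tokens()
  all_tokens <- unlist(streams, use.names = FALSE)
  all_tokens <- all_tokens[!all_tokens %in% res]
  freq <- table(all_tokens)
  freq <- freq[freq >= min_count]
  tokens <- if (length(freq) == 0) res else {
    ord <- order(-as.integer(freq), names(freq))
    c(res, names(freq)[ord])
  }
  index <- stats::setNames(seq_along(tokens) - 1L, tokens)
  structure(list(tokens = tokens, index = index,
                 size = length(tokens)),
            class = c("otitis_vocabulary", "list"))
}

#' @export
print.otitis_vocabulary <- function(x, ...) {
  cat("<otitis_vocabulary> ", x$size, " tokens (",
      paste(reserved_tokens(), collapse = ", "), " reserved)\n", sep = "")
  invisible(x)
}

# 0-based indices of tokens; unknown tokens map to OOV (index 1)
vocab_index <- function(vocab, tokens) {
  idx <- unname(vocab$index[tokens])
  idx[is.na(idx)] <- 1L
  idx
}

#' Encode one record to a fixed-length index sequence
#'
#' Merges the text fields, normalizes numbers, maps tokens to vocabulary
#' indices (unknown tokens to `OOV`), keeps the first `L` indices if the
#' stream is longer, and pads with `PAD` (0) up to `L` otherwise.
#'
#' @param record One-row tibble or named list with the text fields.
#' @param vocab An [build_vocabulary()] result.
#' @param config An [preprocess_config()].
#' @return Integer vector of length exactly `config$max_length`.
#' @export
encode_record <- function(record, vocab, config = preprocess_config()) {
  toks <- merge_fields(record, lowercase = config$lowercase)
  toks <- normalize_numbers(toks, config)
  idx <- vocab_index(vocab, toks)
  L <- config$max_length
  if (length(idx) >= L) idx[seq_len(L)] else c(idx, rep(0L, L - length(idx)))
}

#' Encode a whole corpus
#'
#' @param corpus Visit-record tibble.
#' @param vocab Vocabulary.
#' @param config Preprocess configuration.
#' @return An object of class `otitis_encoded`: list with `indices`
#'   (n x L integer matrix), `labels` (factor, `NA` where unlabeled),
#'   `visit_id`, `vocab_size`, and `max_length`.
#' @export
encode_corpus <- function(corpus, vocab, config = preprocess_config()) {
  n <- nrow(corpus)
  L <- config$max_length
  mat <- matrix(0L, nrow = n, ncol = L)
  for (i in seq_len(n)) {
    mat[i, ] <- encode_record(corpus[i, ], vocab, config)
  }
  labels <- if ("gold_label" %in% names(corpus)) {
    otitis_factor(corpus$gold_label)
  } else {
    otitis_factor(rep(NA_character_, n))
  }
  structure(list(indices = mat, labels = labels,
                 visit_id = corpus$visit_id %||% as.character(seq_len(n)),
                 vocab_size = vocab$size, max_length = L),
            class = c("otitis_encoded", "list"))
}

#' Decode an index sequence back to tokens
#'
#' Inverse of the index mapping, used for round-trip checks; `PAD`
#' positions are dropped.
#'
#' @param indices Integer vector of 0-based vocabulary indices.
#' @param vocab Vocabulary.
#' @return Character vector of tokens.
#' @export
decode_indices <- function(indices, vocab) {
  toks <- vocab$tokens[indices + 1L]
  toks[toks != "PAD"]
}
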