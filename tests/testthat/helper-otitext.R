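# shared fixtures and independent oracles used across the suite

# small zero-noise corpus: fully learnable by keyword match
zero_noise_config <- function(n, seed, n_peds = 8L,
                              note_tokens = c(8L, 25L)) {
  generator_config(n_visits = n, n_pediatricians = n_peds,
                   negation_rate = 0, other_doctor_rate = 0,
                   atypical_term_rate = 0, typo_rate = 0,
                   note_tokens = note_tokens, seed = seed)
}

# encode a corpus end to end with small embedding settings
encode_small <- function(corpus, max_length = 32L, dim = 8L, seed = 1L,
                         epochs = 1L) {
  pp <- preprocess_config(max_length = max_length)
  streams <- lapply(seq_len(nrow(corpus)), function(i)
    normalize_numbers(merge_fields(corpus[i, ]), pp))
  vocab <- build_vocabulary(streams)
  emb <- train_embeddings(streams, vocab,
                          embedding_config(dim = dim, epochs = epochs,
                                           seed = seed))
  list(pp = pp, vocab = vocab, emb = emb,
       enc = encode_corpus(corpus, vocab, pp))
}

encoded_subset <- function(enc, i) {
  structure(list(indices = enc$indices[i, , drop = FALSE],
                 labels = enc$labels[i], visit_id = enc$visit_id[i],
                 vocab_size = enc$vocab_size,
                 max_length = enc$max_length),
            class = c("otitis_encoded", "list"))
}

# independent largest-remainder oracle: checks the defining property of a
# Hamilton apportionment rather than re-running the allocation procedure
expect_hamilton <- function(counts, n, p) {
  expect_equal(sum(counts), n)
  exact <- n * p
  lo <- floor(exact + 1e-12)
  expect_true(all(counts >= lo))
  expect_true(all(counts <= lo + 1))
  rem <- exact - lo
  got_extra <- counts == lo + 1
  if (any(got_extra) && any(!got_extra)) {
    # every bumped class has remainder >= every non-bumped one, up to the
    # positional tie-break
    expect_true(min(rem[got_extra]) >= max(rem[!got_extra]) - 1e-9)
  }
}

# exhaustive recurrence oracle: slide each window over every candidate
# start day in the episode range
recurrence_window_oracle <- function(dates, rule = recurrence_rule()) {
  d <- sort(as.integer(as.Date(dates)))
  if (length(d) == 0) return(FALSE)
  hit <- function(win, thr) {
    if (length(d) < thr) return(FALSE)
    for (s in seq(min(d) - win + 1L, max(d))) {
      if (sum(d >= s & d <= s + win - 1L) >= thr) return(TRUE)
    }
    FALSE
  }
  hit(rule$short_window_days, rule$short_threshold) ||
    hit(rule$long_window_days, rule$long_threshold)
}

# random episode history generator for property tests
random_episodes <- function(max_n = 6L) {
  n <- sample(0:max_n, 1)
  as.Date("2010-01-01") + sample(0:500, n, replace = TRUE)
}
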