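#' Skip-gram embedding configuration
#'
#' @param dim Embedding dimension (the production default is 300; tests
#'   and small corpora use less).
#' @param window Symmetric context window size in tokens.
#' @param epochs Passes over the pair list.
#' @param negative Negative samples per positive pair.
#' @param learning_rate Initial SGD learning rate, decayed linearly.
#' @param min_count Tokens rarer than this are dropped from training
#'   streams (they are OOV anyway).
#' @param batch_size Pairs per vectorized SGD step.
#' @param seed Seed controlling initialization, pair shuffling, and
#'   negative sampling; training is deterministic given the seed.
#' @return A list of class `otitis_embedding_config`.
#' @export
embedding_config <- function(dim = 300L, window = 5L, epochs = 5L,
                             negative = 5L, learning_rate = 0.05,
                             min_count = 1L, batch_size = 512L, seed = 1L) {
  if (dim < 1) stop("embedding dimension must be >= 1", call. = FALSE)
  structure(list(dim = as.integer(dim), window = as.integer(window),
                 epochs = as.integer(epochs), negative = as.integer(negative),
                 learning_rate = learning_rate,
                 min_count = as.integer(min_count),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = c("otitis_embedding_config", "list"))
}

#' Train skip-gram word embeddings
#'
#' Plain skip-gram with negative sampling over the normalized token
#' streams: each (center, context) pair inside the window is a positive
#' example; `negative` tokens drawn from the unigram distribution raised
#' to 3/4 are the contrasting negatives. Vectorized minibatch SGD with a
#' linearly decaying learning rate. Reserved rows follow their
#' conventions: `PAD` is the zero vector; `OOV` is a small random vector
#' with components in \[-0.01, 0.01\].
#'
#' @param streams List of character token vectors (already SEP/NUM
#'   normalized, as fed to [build_vocabulary()]).
#' @param vocab The vocabulary built from the same streams.
#' @param config An [embedding_config()].
#' @return An object of class `otitis_embedding`: list with `vectors`
#'   (`vocab$size` x `dim` matrix, rownames = tokens) and `dim`.
#' @export
train_embeddings <- function(streams, vocab, config = embedding_config()) {
  d <- config$dim
  V <- vocab$size
  withr::with_seed(config$seed, {
    W_in <- matrix(stats::runif(V * d, -0.5 / d, 0.5 / d), nrow = V)
    W_out <- matrix(0, nrow = V, ncol = d)

    pairs <- skipgram_pairs(streams, vocab, config$window)
    if (nrow(pairs) > 0) {
      # unigram^(3/4) negative-sampling distribution over non-PAD tokens
      counts <- tabulate(unlist(lapply(streams, function(s)
        vocab_index(vocab, s))) + 1L, nbins = V)
      neg_prob <- counts^0.75
      neg_prob[1] <- 0  # never sample PAD
      if (sum(neg_prob) == 0) neg_prob[-1] <- 1
      neg_prob <- neg_prob / sum(neg_prob)

      n_pairs <- nrow(pairs)
      bs <- config$batch_size
      total_steps <- config$epochs * ceiling(n_pairs / bs)
      step <- 0
      for (ep in seq_len(config$epochs)) {
        ord <- sample.int(n_pairs)
        for (start in seq(1, n_pairs, by = bs)) {
          step <- step + 1
          lr <- config$learning_rate *
            max(1e-4, 1 - (step - 1) / total_steps)
          take <- ord[start:min(start + bs - 1, n_pairs)]
          ctr <- pairs[take, 1]
          ctx <- pairs[take, 2]
          B <- length(take)
          k <- config$negative
          neg <- sample.int(V, B * k, replace = TRUE, prob = neg_prob)

          vc <- W_in[ctr, , drop = FALSE]
          uo <- W_out[ctx, , drop = FALSE]
          un <- W_out[neg, , drop = FALSE]

          g_pos <- stats::plogis(rowSums(vc * uo)) - 1          # B
          vc_rep <- vc[rep(seq_len(B), each = k), , drop = FALSE]
          g_neg <- stats::plogis(rowSums(vc_rep * un))          # B*k

          d_vc <- g_pos * uo +
            rowsum_by(g_neg * un, rep(seq_len(B), each = k), B)
          d_uo <- g_pos * vc
          d_un <- g_neg * vc_rep

          W_in <- scatter_sub(W_in, ctr, lr * d_vc)
          W_out <- scatter_sub(W_out, ctx, lr * d_uo)
          W_out <- scatter_sub(W_out, neg, lr * d_un)
        }
      }
    }

    W_in[1, ] <- 0                                        # PAD
    W_in[2, ] <- stats::runif(d, -0.01, 0.01)             # OOV, small random
    rownames(W_in) <- vocab$tokens
    structure(list(vectors = W_in, dim = d),
              class = c("otitis_embedding", "list"))
  })
}

# all (center, context) index pairs within the window; 1-based row indices
skipgram_pairs <- function(streams, vocab, window) {
  out <- vector("list", length(streams))
  for (s in seq_along(streams)) {
    idx <- vocab_index(vocab, streams[[s]]) + 1L
    n <- length(idx)
    if (n < 2) next
    ctr <- integer(0); ctx <- integer(0)
    for (off in seq_len(window)) {
      if (off >= n) break
      a <- idx[seq_len(n - off)]
      b <- idx[seq_len(n - off) + off]
      ctr <- c(ctr, a, b)
      ctx <- c(ctx, b, a)
    }
    out[[s]] <- cbind(ctr, ctx)
  }
  pairs <- do.call(rbind, out)
  if (is.null(pairs)) matrix(integer(0), ncol = 2) else pairs
}

# accumulate rows of `x` by integer group (1..n): dense rowsum
rowsum_by <- function(x, group, n) {
  out <- matrix(0, nrow = n, ncol = ncol(x))
  agg <- rowsum(x, group)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

# W[idx,] <- W[idx,] - mean update per unique index. Averaging (rather
# than summing) duplicate contributions keeps the effective step size of
# very frequent tokens (SEP, NUM, common words) independent of the batch
# size, which is what keeps vectorized minibatch skip-gram stable.
scatter_sub <- function(W, idx, upd) {
  agg <- rowsum(upd, idx)
  cnt <- as.integer(table(idx))
  rows <- as.integer(rownames(agg))
  W[rows, ] <- W[rows, , drop = FALSE] - agg / cnt
  W
}

#' @export
print.otitis_embedding <- function(x, ...) {
  cat("<otitis_embedding> ", nrow(x$vectors), " tokens x ", x$dim,
      " dimensions\n", sep = "")
  invisible(x)
}

#' Cosine similarity between two token vectors
#'
#' @param embedding An `otitis_embedding`.
#' @param a,b Tokens.
#' @return Cosine similarity in \[-1, 1\] (0 if either vector is zero).
#' @export
embedding_similarity <- function(embedding, a, b) {
  va <- embedding$vectors[a, ]
  vb <- embedding$vectors[b, ]
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) return(0)
  sum(va * vb) / (na * nb)
}

#' Read / write an embedding table as text
#'
#' Standard whitespace-delimited embedding format: a `size dim` header
#' line, then one token and its components per line.
#'
#' @param embedding An `otitis_embedding`.
#' @param path File path.
#' @return `read_embeddings()` returns an `otitis_embedding`.
#' @export
write_embeddings <- function(embedding, path) {
  con <- file(path, "w")
  on.exit(close(con))
  m <- embedding$vectors
  writeLines(paste(nrow(m), ncol(m)), con)
  writeLines(paste(rownames(m),
                   apply(m, 1, function(r) paste(format(r, digits = 9),
                                                 collapse = " "))), con)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], " ")[[1]])
  parts <- strsplit(lines[-1], " +")
  tokens <- vapply(parts, `[[`, "", 1)
  m <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(hdr[2])))
  rownames(m) <- tokens
  structure(list(vectors = m, dim = hdr[2]),
            class = c("otitis_embedding", "list"))
}
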