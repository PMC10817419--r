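#' Specify one of the five network architectures
#'
#' All five share the same skeleton: an embedding layer initialized from
#' the skip-gram table (batch-normalized, dropout 0.2), zero or more
#' convolutional stages, a global pooling collapse of the sequence axis,
#' and a six-neuron output layer whose logits are softmaxed at prediction
#' time. The variants are:
#'
#' * **0** — simple embedding: no convolutions; global *average* pooling
#'   over embedded positions (the benchmark).
#' * **1** — single-kernel CNN: one convolutional layer (default width 5,
#'   128 filters).
#' * **2** — sequential single-kernel CNN: two convolutional layers in
#'   sequence (default widths 5 then 3).
#' * **3** — multiple parallel kernel CNN: one concatenation of parallel
#'   convolutions (default widths 3, 4, 5; 64 filters each).
#' * **4** — deep multiple parallel kernel CNN: two stacked parallel
#'   concatenations.
#'
#' Every convolutional layer uses ReLU activation and 'same' zero padding
#' (so parallel branches concatenate along the channel axis), followed by
#' batch normalization and dropout. Architectures 1-4 use global max
#' pooling.
#'
#' @param arch_id Integer 0-4.
#' @param kernel_widths Optional override: a list with one integer vector
#'   of widths per convolutional stage.
#' @param filters Optional override: integer vector, filters per stage.
#' @return A list of class `otitis_architecture`.
#' @examples
#' architecture_spec(3)
#' @export
architecture_spec <- function(arch_id, kernel_widths = NULL, filters = NULL) {
  arch_id <- as.integer(arch_id)
  if (!arch_id %in% 0:4) {
    stop("arch_id must be one of 0, 1, 2, 3, 4", call. = FALSE)
  }
  defaults <- list(
    list(widths = list(), filters = integer(0)),
    list(widths = list(5L), filters = 128L),
    list(widths = list(5L, 3L), filters = c(128L, 128L)),
    list(widths = list(c(3L, 4L, 5L)), filters = 64L),
    list(widths = list(c(3L, 4L, 5L), c(3L, 4L, 5L)), filters = c(64L, 64L))
  )[[arch_id + 1L]]
  widths <- if (is.null(kernel_widths)) defaults$widths else
    lapply(kernel_widths, as.integer)
  filt <- if (is.null(filters)) defaults$filters else as.integer(filters)
  n_stage <- length(widths)
  filt <- rep_len(filt, n_stage)
  expected_stages <- c(0L, 1L, 2L, 1L, 2L)[arch_id + 1L]
  if (n_stage != expected_stages) {
    stop("architecture ", arch_id, " requires ", expected_stages,
         " convolutional stage(s), got ", n_stage, call. = FALSE)
  }
  multi <- arch_id %in% c(3L, 4L)
  if (n_stage > 0) {
    per_stage <- lengths(widths)
    if (multi && any(per_stage < 2)) {
      stop("architecture ", arch_id, " requires parallel (multiple) kernel ",
           "widths per stage", call. = FALSE)
    }
    if (!multi && any(per_stage != 1)) {
      stop("architecture ", arch_id, " takes a single kernel width per stage",
           call. = FALSE)
    }
  }
  structure(list(arch_id = arch_id,
                 stages = purrr::map2(widths, filt, function(w, f)
                   list(widths = w, filters = f)),
                 pooling = if (arch_id == 0L) "avg" else "max"),
            class = c("otitis_architecture", "list"))
}

#' @export
print.otitis_architecture <- function(x, ...) {
  nm <- c("simple embedding", "single kernel CNN",
          "sequential single kernel CNN", "multiple parallel kernel CNN",
          "deep multiple parallel kernel CNN")[x$arch_id + 1]
  cat("<otitis_architecture ", x$arch_id, "> ", nm, "\n", sep = "")
  for (s in x$stages) {
    cat("  conv stage: widths ", paste(s$widths, collapse = "/"),
        ", ", s$filters, " filters each\n", sep = "")
  }
  cat("  pooling: global-", x$pooling, ", output: 6-unit softmax\n", sep = "")
  invisible(x)
}

#' Supervised training configuration
#'
#' @param batch_size Minibatch size `M`; the tuning protocol explores 8
#'   and 16.
#' @param embedding_dropout Dropout after the (batch-normalized) embedding
#'   layer; fixed at 0.2 in the tuning protocol.
#' @param hidden_dropout Dropout after each other hidden layer; the
#'   protocol explores 0.5 and 0.7.
#' @param learning_rate,beta1,beta2,epsilon Adam parameters.
#' @param max_epochs Upper bound on epochs.
#' @param patience Early-stopping patience (epochs without monitored-loss
#'   improvement) when a monitor set is supplied.
#' @param min_delta Smallest loss decrease that counts as improvement.
#' @param seed Controls initialization, shuffling, and dropout masks;
#'   training is deterministic given the seed (single-threaded).
#' @return A list of class `otitis_training_config`.
#' @export
training_config <- function(batch_size = 16L, embedding_dropout = 0.2,
                            hidden_dropout = 0.5, learning_rate = 1e-3,
                            beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                            max_epochs = 50L, patience = 5L,
                            min_delta = 1e-4, seed = 1L) {
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  drops <- c(embedding_dropout, hidden_dropout)
  if (any(drops < 0 | drops >= 1)) {
    stop("dropout rates must lie in [0, 1)", call. = FALSE)
  }
  if (max_epochs < 0) stop("max_epochs must be >= 0", call. = FALSE)
  structure(list(batch_size = as.integer(batch_size),
                 embedding_dropout = embedding_dropout,
                 hidden_dropout = hidden_dropout,
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), min_delta = min_delta,
                 seed = as.integer(seed)),
            class = c("otitis_training_config", "list"))
}

#' Default tuning grid
#'
#' The hyperparameter grid explored per architecture: batch size 8 or 16,
#' hidden dropout 0.5 or 0.7.
#'
#' @return Tibble with columns `batch_size`, `hidden_dropout`.
#' @export
default_grid <- function() {
  tidyr::expand_grid(batch_size = c(8L, 16L), hidden_dropout = c(0.5, 0.7))
}

#' Build an untrained model
#'
#' Assembles the parameter set of an architecture: the embedding matrix is
#' initialized from the skip-gram table (and fine-tuned during supervised
#' training; its `PAD` row stays zero and receives no updates), each
#' hidden layer is followed by batch normalization then dropout, and the
#' output layer has exactly six units.
#'
#' @param spec An [architecture_spec()].
#' @param embedding An [train_embeddings()] result (or compatible object
#'   with a `vectors` matrix).
#' @param training An [training_config()]; its seed drives weight
#'   initialization.
#' @return A list of class `otitis_model`.
#' @export
build_model <- function(spec, embedding, training = training_config()) {
  C0 <- ncol(embedding$vectors)
  withr::with_seed(training$seed, {
    params <- list(emb = unname(embedding$vectors))
    bn_run <- list()
    params$bn_emb_g <- rep(1, C0)
    params$bn_emb_b <- rep(0, C0)
    bn_run$bn_emb <- list(mean = rep(0, C0), var = rep(1, C0))
    C_in <- C0
    for (s in seq_along(spec$stages)) {
      st <- spec$stages[[s]]
      for (b in seq_along(st$widths)) {
        k <- st$widths[b]
        f <- st$filters
        key <- sprintf("conv_%d_%d", s, b)
        params[[paste0(key, "_W")]] <- glorot(k * C_in, f, k * C_in, f)
        params[[paste0(key, "_b")]] <- rep(0, f)
        params[[sprintf("bn_%d_%d_g", s, b)]] <- rep(1, f)
        params[[sprintf("bn_%d_%d_b", s, b)]] <- rep(0, f)
        bn_run[[sprintf("bn_%d_%d", s, b)]] <-
          list(mean = rep(0, f), var = rep(1, f))
      }
      C_in <- length(st$widths) * st$filters
    }
    params$dense_W <- glorot(C_in, 6, C_in, 6)
    params$dense_b <- rep(0, 6)
    structure(list(spec = spec, training = training, params = params,
                   bn_run = bn_run, vocab_size = nrow(embedding$vectors),
                   emb_dim = C0, L = NULL, trained = FALSE, history = NULL),
              class = c("otitis_model", "list"))
  })
}

#' @export
print.otitis_model <- function(x, ...) {
  cat("<otitis_model> architecture ", x$spec$arch_id,
      if (x$trained) " (trained)" else " (untrained)", "\n", sep = "")
  cat("  vocabulary ", x$vocab_size, ", embedding dim ", x$emb_dim,
      ", parameters ", format(sum(vapply(x$params, length, 1L)),
                              big.mark = ","), "\n", sep = "")
  if (!is.null(x$history) && nrow(x$history) > 0) {
    cat("  epochs ", nrow(x$history), ", final train loss ",
        signif(utils::tail(x$history$train_loss, 1), 4), "\n", sep = "")
  }
  invisible(x)
}

# forward pass over a token-index matrix (rows = records, 0-based indices).
# In training mode returns caches for backprop and updated BN running
# statistics; in eval mode uses the stored running statistics.
model_forward <- function(model, tokmat, training = FALSE) {
  spec <- model$spec
  p <- model$params
  cfg <- model$training
  M <- nrow(tokmat)
  L <- ncol(tokmat)
  N <- M * L
  tok <- as.integer(t(tokmat))
  X <- p$emb[tok + 1L, , drop = FALSE]

  bn_run <- model$bn_run
  caches <- list(tok = tok, M = M, L = L)

  bne <- bn_fwd(X, p$bn_emb_g, p$bn_emb_b, bn_run$bn_emb$mean,
                bn_run$bn_emb$var, training)
  bn_run$bn_emb <- list(mean = bne$run_mean, var = bne$run_var)
  dre <- dropout_fwd(bne$out, cfg$embedding_dropout, training)
  caches$bn_emb <- bne
  caches$drop_emb <- dre$mask
  X <- dre$out

  for (s in seq_along(spec$stages)) {
    st <- spec$stages[[s]]
    outs <- vector("list", length(st$widths))
    stage_cache <- vector("list", length(st$widths))
    for (b in seq_along(st$widths)) {
      k <- st$widths[b]
      key <- sprintf("conv_%d_%d", s, b)
      bkey <- sprintf("bn_%d_%d", s, b)
      idx <- patch_index(M, L, k)
      cv <- conv_fwd(X, p[[paste0(key, "_W")]], p[[paste0(key, "_b")]],
                     idx, k)
      bnc <- bn_fwd(cv$out, p[[paste0(bkey, "_g")]], p[[paste0(bkey, "_b")]],
                    bn_run[[bkey]]$mean, bn_run[[bkey]]$var, training)
      bn_run[[bkey]] <- list(mean = bnc$run_mean, var = bnc$run_var)
      drc <- dropout_fwd(bnc$out, cfg$hidden_dropout, training)
      outs[[b]] <- drc$out
      stage_cache[[b]] <- list(conv = cv, bn = bnc, drop = drc$mask,
                               idx = idx, k = k, C_in = ncol(X))
    }
    caches[[sprintf("stage_%d", s)]] <- stage_cache
    X <- do.call(cbind, outs)
  }

  C_last <- ncol(X)
  if (spec$pooling == "max") {
    pl <- max_pool_fwd(X, M, L)
    pooled <- pl$out
    caches$pool <- pl$arg
  } else {
    pooled <- avg_pool_fwd(X, M, L)
    caches$pool <- NULL
  }
  caches$pooled <- pooled
  caches$C_last <- C_last
  logits <- pooled %*% p$dense_W +
    matrix(p$dense_b, M, 6, byrow = TRUE)
  list(logits = logits, caches = caches, bn_run = bn_run)
}

# backward pass; returns gradients named like the parameters
model_backward <- function(model, dlogits, caches) {
  spec <- model$spec
  p <- model$params
  M <- caches$M
  L <- caches$L
  N <- M * L
  grads <- list()
  grads$dense_W <- crossprod(caches$pooled, dlogits)
  grads$dense_b <- colSums(dlogits)
  dpool <- dlogits %*% t(p$dense_W)
  dX <- if (spec$pooling == "max") {
    max_pool_bwd(dpool, caches$pool, M, L, caches$C_last)
  } else {
    avg_pool_bwd(dpool, M, L)
  }

  for (s in rev(seq_along(spec$stages))) {
    st <- spec$stages[[s]]
    stage_cache <- caches[[sprintf("stage_%d", s)]]
    col0 <- 0L
    dX_in <- NULL
    for (b in seq_along(st$widths)) {
      sc <- stage_cache[[b]]
      f <- st$filters
      dbranch <- dX[, col0 + seq_len(f), drop = FALSE]
      col0 <- col0 + f
      dbranch <- dropout_bwd(dbranch, sc$drop)
      bnb <- bn_bwd(dbranch, sc$bn,
                    p[[sprintf("bn_%d_%d_g", s, b)]])
      grads[[sprintf("bn_%d_%d_g", s, b)]] <- bnb$dgamma
      grads[[sprintf("bn_%d_%d_b", s, b)]] <- bnb$dbeta
      cvb <- conv_bwd(bnb$dX, sc$conv,
                      p[[sprintf("conv_%d_%d_W", s, b)]],
                      sc$idx, sc$k, N, sc$C_in)
      grads[[sprintf("conv_%d_%d_W", s, b)]] <- cvb$dW
      grads[[sprintf("conv_%d_%d_b", s, b)]] <- cvb$db
      dX_in <- if (is.null(dX_in)) cvb$dX else dX_in + cvb$dX
    }
    dX <- dX_in
  }

  dX <- dropout_bwd(dX, caches$drop_emb)
  bne <- bn_bwd(dX, caches$bn_emb, p$bn_emb_g)
  grads$bn_emb_g <- bne$dgamma
  grads$bn_emb_b <- bne$dbeta
  dEmb <- rowsum_by(bne$dX, caches$tok + 1L, model$vocab_size)
  dEmb[1L, ] <- 0  # PAD row stays fixed at zero
  grads$emb <- dEmb
  grads
}

#' Train a model
#'
#' Minibatch Adam on the average cross-entropy of each batch, with
#' optional early stopping on a monitor set's loss plateau. Deterministic
#' given the training seed and single-threaded execution. With
#' `max_epochs = 0` the returned model equals its initialization.
#'
#' @param model An untrained (or trained) `otitis_model`.
#' @param data An [encode_corpus()] result with labels for every record.
#' @param monitor Optional encoded set whose loss drives early stopping.
#' @return The trained model, with a `history` tibble (`epoch`,
#'   `train_loss`, `monitor_loss`). The parameters giving the best
#'   monitored (or training) loss are restored.
#' @export
train_model <- function(model, data, monitor = NULL) {
  if (!inherits(data, "otitis_encoded")) {
    stop("`data` must be an encode_corpus() result", call. = FALSE)
  }
  n <- nrow(data$indices)
  if (n == 0) stop("training set is empty", call. = FALSE)
  y <- as.integer(data$labels)
  if (length(y) != n || anyNA(y)) {
    stop("every training record needs a gold label (", sum(is.na(y)),
         " missing of ", n, ")", call. = FALSE)
  }
  cfg <- model$training
  model$L <- ncol(data$indices)

  withr::with_seed(cfg$seed + 1L, {
    state <- adam_init(model$params)
    best_loss <- Inf
    best <- list(params = model$params, bn_run = model$bn_run)
    wait <- 0L
    hist <- list()
    for (ep in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = cfg$batch_size)) {
        take <- ord[start:min(start + cfg$batch_size - 1, n)]
        fw <- model_forward(model, data$indices[take, , drop = FALSE],
                            training = TRUE)
        model$bn_run <- fw$bn_run
        sx <- softmax_xent(fw$logits, y[take])
        losses <- c(losses, sx$loss)
        grads <- model_backward(model, sx$dlogits, fw$caches)
        upd <- adam_step(model$params, grads, state, cfg$learning_rate,
                         cfg$beta1, cfg$beta2, cfg$epsilon)
        model$params <- upd$params
        state <- upd$state
      }
      train_loss <- mean(losses)
      mon_loss <- NA_real_
      if (!is.null(monitor)) {
        ml <- predict_logits(model, monitor)
        mon_loss <- softmax_xent(ml, as.integer(monitor$labels))$loss
      }
      hist[[ep]] <- tibble::tibble(epoch = ep, train_loss = train_loss,
                                   monitor_loss = mon_loss)
      track <- if (is.null(monitor)) train_loss else mon_loss
      if (is.finite(track) && track < best_loss - cfg$min_delta) {
        best_loss <- track
        best <- list(params = model$params, bn_run = model$bn_run)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
    if (cfg$max_epochs > 0 && is.finite(best_loss)) {
      model$params <- best$params
      model$bn_run <- best$bn_run
    }
    model$history <- if (length(hist) > 0) dplyr::bind_rows(hist) else
      tibble::tibble(epoch = integer(), train_loss = numeric(),
                     monitor_loss = numeric())
    model$trained <- TRUE
    model
  })
}

#' Pre-softmax logits for encoded records
#'
#' @param model A (trained) `otitis_model`.
#' @param data An [encode_corpus()] result, or a 0-based integer index
#'   matrix with one row per record.
#' @param batch_size Records per forward pass (memory bound only).
#' @return An n x 6 matrix of finite logits, in canonical class order.
#' @export
predict_logits <- function(model, data, batch_size = 256L) {
  mat <- if (inherits(data, "otitis_encoded")) data$indices else
    as.matrix(data)
  if (nrow(mat) == 0) {
    return(matrix(numeric(0), 0, 6,
                  dimnames = list(NULL, otitis_classes())))
  }
  if (!is.null(model$L) && ncol(mat) != model$L) {
    stop("records have length ", ncol(mat), " but the model was trained ",
         "on length ", model$L, call. = FALSE)
  }
  out <- matrix(NA_real_, nrow(mat), 6)
  for (start in seq(1, nrow(mat), by = batch_size)) {
    take <- start:min(start + batch_size - 1, nrow(mat))
    fw <- model_forward(model, mat[take, , drop = FALSE], training = FALSE)
    out[take, ] <- fw$logits
  }
  colnames(out) <- otitis_classes()
  out
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @method glance otitis_model
#' @export
glance.otitis_model <- function(x, ...) {
  tibble::tibble(
    arch_id = x$spec$arch_id,
    n_parameters = sum(vapply(x$params, length, 1L)),
    trained = x$trained,
    epochs = if (is.null(x$history)) 0L else nrow(x$history),
    final_train_loss = if (is.null(x$history) || nrow(x$history) == 0)
      NA_real_ else utils::tail(x$history$train_loss, 1),
    best_monitor_loss = if (is.null(x$history) || nrow(x$history) == 0)
      NA_real_ else suppressWarnings(min(x$history$monitor_loss, na.rm = TRUE))
  )
}

#' @method tidy otitis_model
#' @export
tidy.otitis_model <- function(x, ...) {
  x$history %||% tibble::tibble(epoch = integer(), train_loss = numeric(),
                                monitor_loss = numeric())
}

#' Training-history curve
#'
#' @param object A trained `otitis_model`.
#' @param ... Unused.
#' @return A ggplot of loss against epoch.
#' @method autoplot otitis_model
#' @export
autoplot.otitis_model <- function(object, ...) {
  h <- tidy(object) |>
    tidyr::pivot_longer(dplyr::ends_with("loss"),
                        names_to = "series", values_to = "loss") |>
    dplyr::filter(!is.na(.data$loss))
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$loss,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Write a trained model's metadata sidecar
#'
#' JSON description of a fitted model: architecture, training
#' configuration (including the seed), and per-epoch history. The fitted
#' weights themselves are reproducible from the seed and inputs, so the
#' sidecar is the durable record of a run.
#'
#' @param model A trained `otitis_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_metadata <- function(model, path) {
  jsonlite::write_json(list(
    architecture = list(arch_id = model$spec$arch_id,
                        stages = model$spec$stages,
                        pooling = model$spec$pooling),
    training = unclass(model$training),
    vocab_size = model$vocab_size,
    embedding_dim = model$emb_dim,
    sequence_length = model$L,
    trained = model$trained,
    history = model$history), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
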