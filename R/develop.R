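#' Two-stage model development
#'
#' The tuning protocol applied to each architecture:
#'
#' 1. **Stage 1 — grid search.** Every grid point (batch size x hidden
#'    dropout, plus any architecture hyperparameters baked into the spec)
#'    is trained on the training set and scored by validation accuracy;
#'    the best point per architecture wins (ties: first grid row).
#' 2. **Stage 2 — retraining with transfer records.** The winning
#'    configuration is retrained from scratch on the training set plus a
#'    seeded, without-replacement sample of `n_transfer` validation
#'    records. The validation set then arbitrates the final choice: the
#'    retrained model replaces the stage-1 model only if its validation
#'    accuracy is at least as good.
#'
#' @param arch_ids Integer vector of architectures to develop (subset of
#'   0-4), or a list of [architecture_spec()] objects.
#' @param train,validation [encode_corpus()] results with gold labels.
#' @param embedding An [train_embeddings()] table; initializes every
#'   model's embedding layer.
#' @param grid Tibble of hyperparameter combinations with columns
#'   `batch_size` and `hidden_dropout`; defaults to [default_grid()].
#' @param n_transfer Number of validation records folded into stage-2
#'   retraining (default 300).
#' @param base_training An [training_config()] supplying everything the
#'   grid does not vary (epochs, learning rate, ...).
#' @param seed Seed for the transfer-record sample and per-fit seeds.
#' @return A list of class `otitis_development`: one element per
#'   architecture, each holding `model` (the final `otitis_model`) and
#'   `trace` (a tibble of every fit's grid point, stage, and validation
#'   accuracy).
#' @export
two_stage_develop <- function(arch_ids, train, validation, embedding,
                              grid = default_grid(), n_transfer = 300L,
                              base_training = training_config(),
                              seed = 1L) {
  if (is.null(grid) || nrow(grid) == 0) {
    stop("hyperparameter grid is empty", call. = FALSE)
  }
  n_val <- nrow(validation$indices)
  if (n_val < n_transfer) {
    stop("validation set has ", n_val, " records but n_transfer is ",
         n_transfer, call. = FALSE)
  }
  specs <- if (is.list(arch_ids) && inherits(arch_ids[[1]],
                                             "otitis_architecture")) {
    arch_ids
  } else {
    lapply(arch_ids, architecture_spec)
  }

  # the stage-2 transfer subset is one seeded draw, shared by all
  # architectures and identical across reruns
  transfer_idx <- withr::with_seed(seed,
    sample.int(n_val, n_transfer))
  aug <- structure(list(
    indices = rbind(train$indices,
                    validation$indices[transfer_idx, , drop = FALSE]),
    labels = otitis_factor(c(as.character(train$labels),
                             as.character(validation$labels[transfer_idx]))),
    visit_id = c(train$visit_id, validation$visit_id[transfer_idx]),
    vocab_size = train$vocab_size, max_length = train$max_length),
    class = c("otitis_encoded", "list"))

  val_y <- validation$labels
  out <- vector("list", length(specs))
  for (a in seq_along(specs)) {
    spec <- specs[[a]]
    trace <- list()
    best_acc <- -Inf
    best_fit <- NULL
    best_row <- NULL
    for (g in seq_len(nrow(grid))) {
      cfg <- base_training
      cfg$batch_size <- as.integer(grid$batch_size[g])
      cfg$hidden_dropout <- grid$hidden_dropout[g]
      cfg$seed <- as.integer(seed + 1000L * a + g)
      fit <- train_model(build_model(spec, embedding, cfg),
                         train, monitor = validation)
      acc <- prediction_accuracy(
        ensemble_predict(list(predict_logits(fit, validation))), val_y)
      trace[[length(trace) + 1L]] <- tibble::tibble(
        arch_id = spec$arch_id, stage = 1L,
        batch_size = cfg$batch_size, hidden_dropout = cfg$hidden_dropout,
        validation_accuracy = acc)
      if (acc > best_acc) {
        best_acc <- acc
        best_fit <- fit
        best_row <- g
      }
    }
    cfg <- base_training
    cfg$batch_size <- as.integer(grid$batch_size[best_row])
    cfg$hidden_dropout <- grid$hidden_dropout[best_row]
    cfg$seed <- as.integer(seed + 1000L * a)
    refit <- train_model(build_model(spec, embedding, cfg),
                         aug, monitor = validation)
    acc2 <- prediction_accuracy(
      ensemble_predict(list(predict_logits(refit, validation))), val_y)
    trace[[length(trace) + 1L]] <- tibble::tibble(
      arch_id = spec$arch_id, stage = 2L,
      batch_size = cfg$batch_size, hidden_dropout = cfg$hidden_dropout,
      validation_accuracy = acc2)
    final <- if (acc2 >= best_acc) refit else best_fit
    out[[a]] <- list(model = final, trace = dplyr::bind_rows(trace))
  }
  names(out) <- vapply(specs, function(s) paste0("arch_", s$arch_id), "")
  structure(out, class = c("otitis_development", "list"))
}
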