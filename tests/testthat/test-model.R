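# tiny random embedding shared by the structural tests
toy_embedding <- function(V = 12, d = 6, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(V * d, sd = 0.3), V, d)
    m[1, ] <- 0
    rownames(m) <- c("PAD", "OOV", "SEP", "NUM",
                     paste0("w", seq_len(V - 4)))
    structure(list(vectors = m, dim = d),
              class = c("otitis_embedding", "list"))
  })
}

test_that("architecture specifications enforce their structure", {
  expect_equal(length(architecture_spec(0)$stages), 0)
  expect_equal(architecture_spec(0)$pooling, "avg")
  expect_equal(length(architecture_spec(1)$stages), 1)
  expect_equal(length(architecture_spec(2)$stages), 2)
  a3 <- architecture_spec(3)
  expect_equal(length(a3$stages), 1)
  expect_equal(a3$stages[[1]]$widths, c(3L, 4L, 5L))
  expect_equal(length(architecture_spec(4)$stages), 2)
  expect_error(architecture_spec(7), "arch_id")
  expect_error(architecture_spec(1, kernel_widths = list(5L, 3L)),
               "1 convolutional stage")
  expect_error(architecture_spec(3, kernel_widths = list(5L)), "parallel")
})

test_that("built models have six output units and the right layer stack", {
  emb <- toy_embedding()
  tc <- training_config(seed = 2)
  for (aid in 0:4) {
    m <- build_model(architecture_spec(aid), emb, tc)
    expect_equal(ncol(m$params$dense_W), 6)
    expect_equal(length(m$params$dense_b), 6)
    n_conv <- sum(grepl("^conv_.*_W$", names(m$params)))
    expect_equal(n_conv, c(0, 1, 2, 3, 6)[aid + 1])
    # one batch-norm per hidden layer (embedding + each conv)
    n_bn <- sum(grepl("^bn_.*_g$", names(m$params)))
    expect_equal(n_bn, n_conv + 1)
    expect_equal(m$params$emb, unname(emb$vectors))
  }
})

test_that("analytic gradients match numerical differentiation", {
  emb <- toy_embedding()
  tc <- training_config(batch_size = 4, embedding_dropout = 0,
                        hidden_dropout = 0, seed = 3)
  withr::with_seed(11, {
    tok <- matrix(sample(0:11, 4 * 7, replace = TRUE), 4, 7)
    y <- sample(1:6, 4, replace = TRUE)
    for (aid in c(0, 2, 4)) {
      spec <- architecture_spec(aid, filters = if (aid > 0)
        rep(3L, c(0, 1, 2, 1, 2)[aid + 1]) else NULL)
      m <- build_model(spec, emb, tc)
      fw <- otitext:::model_forward(m, tok, training = TRUE)
      sx <- otitext:::softmax_xent(fw$logits, y)
      gr <- otitext:::model_backward(m, sx$dlogits, fw$caches)
      for (nm in names(gr)) {
        p <- m$params[[nm]]
        picks <- sample(length(p), min(3, length(p)))
        for (ii in picks) {
          if (nm == "emb" && (ii - 1) %% nrow(p) == 0) next  # frozen PAD row
          eps <- 1e-5
          m2 <- m
          m2$params[[nm]][ii] <- p[ii] + eps
          l1 <- otitext:::softmax_xent(
            otitext:::model_forward(m2, tok, training = TRUE)$logits, y)$loss
          m2$params[[nm]][ii] <- p[ii] - eps
          l0 <- otitext:::softmax_xent(
            otitext:::model_forward(m2, tok, training = TRUE)$logits, y)$loss
          num <- (l1 - l0) / (2 * eps)
          expect_equal(gr[[nm]][ii], num, tolerance = 1e-4,
                       info = paste("arch", aid, nm))
        }
      }
    }
  })
})

test_that("zero-epoch training returns the initialized model", {
  emb <- toy_embedding()
  tc <- training_config(max_epochs = 0, seed = 4)
  m0 <- build_model(architecture_spec(1, filters = 4L), emb, tc)
  corpus <- generate_corpus(zero_noise_config(12, seed = 6))
  fx <- encode_small(corpus, max_length = 16, dim = 6, seed = 4)
  m0 <- build_model(architecture_spec(1, filters = 4L), fx$emb, tc)
  m <- train_model(m0, fx$enc)
  expect_identical(m$params, m0$params)
  lg <- predict_logits(m, fx$enc)
  expect_true(all(is.finite(lg)))
  expect_equal(dim(lg), c(12, 6))
})

test_that("training fits a separable synthetic set to perfect accuracy", {
  corpus <- generate_corpus(zero_noise_config(60, seed = 15,
                                              note_tokens = c(6L, 12L)))
  fx <- encode_small(corpus, max_length = 16, dim = 8, seed = 15,
                     epochs = 2)
  tc <- training_config(batch_size = 8, max_epochs = 30, patience = 30,
                        learning_rate = 3e-3, seed = 15)
  m <- train_model(build_model(architecture_spec(1, filters = 16L),
                               fx$emb, tc), fx$enc)
  pred <- ensemble_predict(list(predict_logits(m, fx$enc)))
  expect_equal(prediction_accuracy(pred, fx$enc$labels), 1.0)
  # best-so-far training loss is non-increasing
  best <- cummin(m$history$train_loss)
  expect_true(all(diff(best) <= 1e-12))
})

test_that("prediction is deterministic and validates input shape", {
  corpus <- generate_corpus(zero_noise_config(20, seed = 5))
  fx <- encode_small(corpus, max_length = 16, dim = 6, seed = 5)
  tc <- training_config(batch_size = 8, max_epochs = 2, seed = 5)
  m <- train_model(build_model(architecture_spec(3, filters = 4L),
                               fx$emb, tc), fx$enc)
  a <- predict_logits(m, fx$enc)
  b <- predict_logits(m, fx$enc)
  expect_identical(a, b)
  # two identical records give identical rows
  two <- fx$enc$indices[c(1, 1), ]
  lg <- predict_logits(m, two)
  expect_equal(lg[1, ], lg[2, ])
  # empty input, wrong length
  expect_equal(dim(predict_logits(m, fx$enc$indices[0, , drop = FALSE])),
               c(0, 6))
  expect_error(predict_logits(m, fx$enc$indices[, 1:8]), "length")
})

test_that("training validates labels and emptiness", {
  corpus <- generate_corpus(zero_noise_config(10, seed = 2))
  fx <- encode_small(corpus, max_length = 16, dim = 6, seed = 2)
  m <- build_model(architecture_spec(0), fx$emb, training_config(seed = 2))
  unlabeled <- fx$enc
  unlabeled$labels[3] <- NA
  expect_error(train_model(m, unlabeled), "gold label")
  empty <- encoded_subset(fx$enc, integer(0))
  expect_error(train_model(m, empty), "empty")
})

test_that("identical seeds reproduce identical trained models", {
  corpus <- generate_corpus(zero_noise_config(30, seed = 7))
  fx <- encode_small(corpus, max_length = 16, dim = 6, seed = 7)
  tc <- training_config(batch_size = 8, max_epochs = 3, seed = 7)
  m1 <- train_model(build_model(architecture_spec(1, filters = 6L),
                                fx$emb, tc), fx$enc)
  m2 <- train_model(build_model(architecture_spec(1, filters = 6L),
                                fx$emb, tc), fx$enc)
  expect_identical(predict_logits(m1, fx$enc), predict_logits(m2, fx$enc))
})

test_that("tidy and glance expose the training history", {
  corpus <- generate_corpus(zero_noise_config(16, seed = 3))
  fx <- encode_small(corpus, max_length = 16, dim = 6, seed = 3)
  tc <- training_config(batch_size = 8, max_epochs = 2, seed = 3)
  m <- train_model(build_model(architecture_spec(0), fx$emb, tc), fx$enc)
  expect_equal(nrow(tidy(m)), 2)
  g <- glance(m)
  expect_equal(g$arch_id, 0L)
  expect_true(g$trained)
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
})
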