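test_that("confusion matrices tally prediction/gold pairs exactly", {
  p <- rep("aom", 10)
  cm <- confusion_matrix(p, p)
  expect_equal(sum(cm), 10)
  expect_equal(cm["aom", "aom"], 10L, ignore_attr = TRUE)
  expect_equal(sum(diag(cm)), 10)

  withr::with_seed(61, {
    pred <- sample(otitis_classes(), 100, replace = TRUE)
    gold <- sample(otitis_classes(), 100, replace = TRUE)
    cm2 <- confusion_matrix(pred, gold)
    # brute-force pairwise tally
    for (i in seq_along(otitis_classes())) {
      for (j in seq_along(otitis_classes())) {
        expect_equal(cm2[i, j],
                     sum(pred == otitis_classes()[i] &
                           gold == otitis_classes()[j]),
                     ignore_attr = TRUE)
      }
    }
  })

  expect_error(confusion_matrix(character(0), character(0)), "empty")
  expect_error(confusion_matrix(c("aom"), c("aom", "aom")), "length")
})

test_that("the reference matrix reproduces the published metrics", {
  cm <- reference_confusion()
  expect_equal(sum(cm), 880)
  expect_equal(otitext:::round_half_up(accuracy(cm), 2), 96.59)
  expect_equal(otitext:::round_half_up(balanced_precision(cm), 2), 97.03)
  expect_equal(otitext:::round_half_up(balanced_recall(cm), 2), 93.97)
  expect_equal(otitext:::round_half_up(balanced_f1(cm), 2), 95.48)
  rep <- metrics_report(cm, digits = 2)
  expect_equal(rep$summary$n_misclassified, 30)
  expect_equal(rep$summary$accuracy, 96.59)
  expect_equal(rep$summary$balanced_f1, 95.48)
})

test_that("macro-averaged per-class F1 differs from the harmonic form", {
  # the documented discrepancy that pins down the balanced-F1 definition:
  # on the reference matrix the macro mean of per-class F1 is 95.32,
  # not the published 95.48
  rep <- metrics_report(reference_confusion(), digits = 2)
  expect_equal(rep$summary$macro_f1, 95.32)
  expect_equal(rep$summary$balanced_f1, 95.48)
})

test_that("degenerate matrices follow the documented conventions", {
  d <- diag(c(5L, 4L, 3L, 2L, 1L, 1L))
  expect_equal(accuracy(d), 100)
  expect_equal(balanced_precision(d), 100)
  expect_equal(balanced_recall(d), 100)
  expect_equal(balanced_f1(100, 100), 100)

  z <- matrix(0L, 6, 6)
  z[1, 2] <- 10L
  expect_equal(accuracy(z), 0)
  expect_warning(bp <- balanced_precision(z), "contribute 0")
  expect_lt(bp, 100 / 6 + 1e-9)
  expect_warning(f0 <- balanced_f1(0, 0), "defined as 0")
  expect_equal(f0, 0)
  expect_error(accuracy(matrix(0L, 6, 6)), "empty")
  expect_error(as_otitis_confusion(matrix(1, 5, 5)), "6 x 6")
  expect_error(as_otitis_confusion(matrix(-1, 6, 6)), "nonnegative")
})

test_that("balanced metrics sit between the per-class extremes", {
  withr::with_seed(67, {
    for (i in 1:20) {
      cm <- matrix(rpois(36, 4), 6, 6)
      diag(cm) <- diag(cm) + rpois(6, 10)
      rep <- metrics_report(cm)
      pc <- rep$per_class
      expect_lte(rep$summary$accuracy, 100)
      expect_gte(min(pc$recall), 0)
      expect_gte(rep$summary$balanced_recall, min(pc$recall) - 1e-9)
      expect_lte(rep$summary$balanced_recall, max(pc$recall) + 1e-9)
      expect_gte(rep$summary$balanced_precision, min(pc$precision) - 1e-9)
      expect_lte(rep$summary$balanced_precision, max(pc$precision) + 1e-9)
    }
    # harmonic-mean identity on the diagonal
    for (x in c(0.5, 37.21, 95.48, 100)) {
      expect_equal(balanced_f1(x, x), x)
    }
  })
})

test_that("half-up rounding matches the printed-table convention", {
  expect_equal(otitext:::round_half_up(95.485, 2), 95.49)
  expect_equal(otitext:::round_half_up(95.484, 2), 95.48)
  expect_equal(otitext:::round_half_up(2.5, 0), 3)
})

test_that("error reports list misclassified records with their texts", {
  corpus <- generate_corpus(generator_config(n_visits = 150,
                                             negation_rate = 0.5,
                                             other_doctor_rate = 0,
                                             atypical_term_rate = 0,
                                             typo_rate = 0, seed = 71))
  # a naive mention-based classifier: any otitis mention -> aom;
  # genuinely fooled by negated mentions in no_otitis records
  naive <- vapply(seq_len(nrow(corpus)), function(i) {
    txt <- tolower(paste(corpus$diagnosis[i], corpus$notes[i]))
    if (grepl("otite media acuta", txt)) "aom"
    else if (grepl("otite", txt)) "aom"
    else "no_otitis"
  }, "")
  rep <- error_report(corpus, naive)
  negated <- corpus$visit_id[grepl("negation", corpus$confounder)]
  expect_gt(length(negated), 0)
  expect_true(any(negated %in% rep$errors$visit_id))
  expect_equal(nrow(rep$errors),
               sum(naive != as.character(corpus$gold_label)))
  expect_equal(sum(rep$counts$n), nrow(rep$errors))
  expect_true(all(c("diagnosis", "notes", "predicted", "gold") %in%
                    names(rep$errors)))

  perfect <- error_report(corpus, corpus$gold_label)
  expect_equal(nrow(perfect$errors), 0)
})

test_that("confusion matrices round-trip through delimited text", {
  cm <- reference_confusion()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_confusion(cm, path)
  expect_identical(unclass(read_confusion(path)), unclass(cm))
})

test_that("tidy, glance and autoplot work on evaluation objects", {
  cm <- reference_confusion()
  td <- tidy(cm)
  expect_equal(nrow(td), 36)
  expect_equal(sum(td$n), 880)
  g <- glance(cm)
  expect_equal(g$n_misclassified, 30)
  expect_s3_class(autoplot(cm), "ggplot")
  rep <- metrics_report(cm)
  expect_equal(nrow(tidy(rep)), 6)
  expect_equal(glance(rep)$n, 880)
})

test_that("metrics and misclassification reports export to JSON", {
  cm <- reference_confusion()
  rep <- metrics_report(cm, digits = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_metrics(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$summary[[1]]$accuracy, 96.59)
  expect_equal(length(back$per_class), 6)

  corpus <- generate_corpus(zero_noise_config(30, seed = 19))
  pred <- as.character(corpus$gold_label)
  pred[1:3] <- "no_otitis"
  er <- error_report(corpus, pred)
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  write_error_report(er, p2)
  lines <- readLines(p2)
  expect_equal(length(lines), nrow(er$errors))
  first <- jsonlite::fromJSON(lines[1])
  expect_true(all(c("visit_id", "predicted", "gold") %in% names(first)))
})
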