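test_that("recurrence rule fires on the defining examples", {
  d0 <- as.Date("2010-01-01")
  expect_true(classify_recurrent(d0 + c(0, 60, 120)))
  expect_false(classify_recurrent(d0 + c(0, 100, 200)))
  expect_true(classify_recurrent(as.Date(character(0)),
                                 explicit_statement = TRUE))
  expect_false(classify_recurrent(as.Date(character(0))))
  # four episodes spread beyond six months but inside a year
  expect_true(classify_recurrent(d0 + c(0, 100, 200, 300)))
  # order must not matter
  expect_true(classify_recurrent(d0 + c(120, 0, 60)))
})

test_that("recurrence rule parameters validate and are honored", {
  expect_error(recurrence_rule(short_threshold = 0), ">= 1")
  strict <- recurrence_rule(short_window_days = 30, short_threshold = 2,
                            long_window_days = 60, long_threshold = 3)
  d0 <- as.Date("2010-01-01")
  expect_true(classify_recurrent(d0 + c(0, 20), rule = strict))
  expect_false(classify_recurrent(d0 + c(0, 40), rule = strict))
})

test_that("classify_recurrent agrees with the all-windows oracle", {
  withr::with_seed(17, {
    for (i in 1:200) {
      d <- random_episodes()
      expect_equal(classify_recurrent(d), recurrence_window_oracle(d),
                   info = paste(format(d), collapse = ","))
    }
  })
})

test_that("adjudication resolves disagreements via the third reviewer", {
  agree <- tibble::tibble(record_id = c("a", "b"),
                          label_a = c("aom", "no_otitis"),
                          label_b = c("aom", "no_otitis"))
  res <- adjudicate(agree)
  expect_equal(as.character(res$labels$final_label), c("aom", "no_otitis"))
  expect_equal(res$report$n_disagreements, 0)

  mixed <- tibble::tibble(record_id = c("a", "b"),
                          label_a = c("aom", "om_not_acute"),
                          label_b = c("aom", "aom"),
                          adjudicated = c(NA, "aom"))
  res2 <- adjudicate(mixed)
  expect_equal(as.character(res2$labels$final_label), c("aom", "aom"))
  expect_equal(res2$report$n_disagreements, 1)
  expect_equal(res2$report$disagreement_rate, 0.5)

  bad <- tibble::tibble(record_id = "zz9", label_a = "aom",
                        label_b = "no_otitis")
  expect_error(adjudicate(bad), "zz9")
})

test_that("kappa matches hand-derived and library values", {
  # perfect agreement
  expect_equal(weighted_cohens_kappa(c("aom", "aom", "no_otitis"),
                                     c("aom", "aom", "no_otitis"),
                                     "unweighted"), 1)
  # observed agreement 0.5 equals chance agreement 0.5 -> kappa 0
  a <- c("no_otitis", "no_otitis", "otitis_not_media", "otitis_not_media")
  b <- c("no_otitis", "otitis_not_media", "no_otitis", "otitis_not_media")
  expect_equal(weighted_cohens_kappa(a, b, "unweighted"), 0)

  # independent route: e1071's chance-corrected agreement (unweighted)
  skip_if_not_installed("e1071")
  withr::with_seed(23, {
    for (i in 1:5) {
      x <- sample(otitis_classes(), 60, replace = TRUE)
      y <- x
      flip <- sample(60, 15)
      y[flip] <- sample(otitis_classes(), 15, replace = TRUE)
      tab <- table(factor(x, otitis_classes()), factor(y, otitis_classes()))
      expect_equal(weighted_cohens_kappa(x, y, "unweighted"),
                   e1071::classAgreement(tab)$kappa, tolerance = 1e-10)
    }
  })
})

test_that("kappa weighting penalizes distant disagreements more", {
  a <- rep(c("no_otitis", "aom_recurrent"), each = 10)
  near <- c(rep("otitis_not_media", 10), rep("aom_perforation", 10))
  lin_near <- weighted_cohens_kappa(a, near, "linear")
  far <- c(rep("aom_recurrent", 10), rep("no_otitis", 10))
  lin_far <- weighted_cohens_kappa(a, far, "linear")
  expect_gt(lin_near, lin_far)
  # quadratic discounts near-misses less than linear does
  expect_gt(weighted_cohens_kappa(a, near, "quadratic"), lin_near)
})

test_that("kappa is symmetric and permutation-invariant when unweighted", {
  withr::with_seed(29, {
    x <- sample(otitis_classes(), 80, replace = TRUE)
    y <- sample(otitis_classes(), 80, replace = TRUE)
    expect_equal(weighted_cohens_kappa(x, y, "linear"),
                 weighted_cohens_kappa(y, x, "linear"))
    perm <- sample(otitis_classes())
    px <- perm[match(x, otitis_classes())]
    py <- perm[match(y, otitis_classes())]
    expect_equal(weighted_cohens_kappa(x, y, "unweighted"),
                 weighted_cohens_kappa(px, py, "unweighted"))
  })
})

test_that("degenerate and invalid kappa inputs are handled", {
  # zero chance disagreement: both raters constant and equal
  expect_warning(k <- weighted_cohens_kappa(rep("aom", 5), rep("aom", 5)),
                 "degenerate")
  expect_equal(k, 0)
  # constant vs varying rater: chance disagreement is nonzero and the
  # ordinary formula evaluates to exactly 0
  expect_equal(
    weighted_cohens_kappa(rep("aom", 5),
                          c("aom", "aom", "aom", "aom", "no_otitis")),
    0)
  expect_error(weighted_cohens_kappa(c("aom"), c("aom", "aom")), "length")
  expect_error(weighted_cohens_kappa(character(0), character(0)),
               "non-empty")
})

test_that("annotations round-trip through the delimited file", {
  pairs <- tibble::tibble(record_id = c("a", "b"),
                          label_a = c("aom", "om_not_acute"),
                          label_b = c("aom", "aom"),
                          adjudicated = c(NA, "aom"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(pairs, path)
  back <- read_annotations(path)
  expect_equal(back$record_id, pairs$record_id)
  expect_equal(back$adjudicated, pairs$adjudicated)
  expect_equal(adjudicate(back)$report$n_disagreements, 1)
})
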