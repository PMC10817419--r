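# hand-built corpora give exact control over pediatrician shares and dates
flat_corpus <- function(n_per_ped, peds, seed = 1) {
  withr::with_seed(seed, {
    n <- sum(n_per_ped)
    pre <- as.Date("2004-01-01") + sample(0:1400, n, replace = TRUE)
    post <- as.Date("2009-01-01") + sample(0:1400, n, replace = TRUE)
    tibble::tibble(
      visit_id = sprintf("v%05d", seq_len(n)),
      pediatrician_id = rep(peds, times = n_per_ped),
      # alternate historical/later so both periods mirror the shares
      visit_date = ifelse(seq_len(n) %% 2 == 0, pre, post) |>
        as.Date(origin = "1970-01-01"))
  })
}

test_that("equal pediatrician shares give equal per-set quotas", {
  corpus <- flat_corpus(rep(100, 10), sprintf("p%02d", 1:10))
  cfg <- split_config(train_size = 300, validation_size = 100,
                      test_size = 100, min_records_per_set = 100, seed = 2)
  asg <- stratified_split(corpus, cfg)
  joined <- merge(asg, corpus, by = "visit_id")
  counts <- table(joined$set, joined$pediatrician_id)
  expect_true(all(counts["train", ] == 30))
  expect_true(all(counts["validation", ] == 10))
  expect_true(all(counts["test", ] == 10))
})

test_that("skewed shares follow the largest-remainder quota", {
  corpus <- flat_corpus(c(400, 300, 200, 100), paste0("p", 1:4))
  cfg <- split_config(train_size = 100, validation_size = 100,
                      test_size = 100, min_records_per_set = 100, seed = 3)
  asg <- stratified_split(corpus, cfg)
  joined <- merge(asg, corpus, by = "visit_id")
  counts <- table(joined$set, joined$pediatrician_id)
  for (s in c("train", "validation", "test")) {
    expect_equal(unname(counts[s, paste0("p", 1:4)]), c(40, 30, 20, 10))
  }
})

test_that("infeasible splits fail with the binding constraint named", {
  expect_error(split_config(train_size = 400, min_records_per_set = 500),
               "min_records_per_set")

  corpus <- flat_corpus(rep(50, 4), paste0("p", 1:4))  # 100 pre-cutoff
  cfg <- split_config(train_size = 150, validation_size = 20,
                      test_size = 20, min_records_per_set = 10, seed = 1)
  expect_error(stratified_split(corpus, cfg), "predate the cutoff")

  cfg2 <- split_config(train_size = 50, validation_size = 80,
                       test_size = 80, min_records_per_set = 10, seed = 1)
  expect_error(stratified_split(corpus, cfg2), "on/after the cutoff")
})

test_that("cutoff outside the corpus date range is rejected", {
  corpus <- flat_corpus(rep(30, 3), paste0("p", 1:3))
  cfg <- split_config(train_size = 10, validation_size = 10, test_size = 10,
                      min_records_per_set = 10,
                      historical_cutoff = as.Date("2030-01-01"))
  expect_error(stratified_split(corpus, cfg), "date range")
})

test_that("split invariants hold across random corpora", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      k <- sample(3:8, 1)
      sizes <- sample(40:120, k, replace = TRUE)
    })
    corpus <- flat_corpus(sizes, paste0("p", seq_along(sizes)), seed = seed)
    n <- nrow(corpus)
    cfg <- split_config(train_size = floor(n * 0.3),
                        validation_size = floor(n * 0.15),
                        test_size = floor(n * 0.15),
                        min_records_per_set = 10, seed = seed)
    asg <- stratified_split(corpus, cfg)
    # disjoint
    expect_equal(anyDuplicated(asg$visit_id), 0)
    # sizes
    expect_equal(sum(asg$set == "train"), cfg$train_size)
    expect_equal(sum(asg$set == "validation"), cfg$validation_size)
    expect_equal(sum(asg$set == "test"), cfg$test_size)
    # temporal separation
    joined <- merge(asg, corpus, by = "visit_id")
    expect_true(all(joined$visit_date[joined$set == "train"] <
                      cfg$historical_cutoff))
    expect_true(all(joined$visit_date[joined$set != "train"] >=
                      cfg$historical_cutoff))
    # per-pediatrician counts deviate from the exact share by < 1 record
    shares <- table(corpus$pediatrician_id) / n
    for (s in c("train", "validation", "test")) {
      cnt <- table(factor(joined$pediatrician_id[joined$set == s],
                          levels = names(shares)))
      target <- sum(joined$set == s) * as.numeric(shares)
      expect_true(all(abs(as.numeric(cnt) - target) < 1 + 1e-9))
    }
  }
})

test_that("splitting is deterministic and coverage is honored", {
  corpus <- flat_corpus(c(200, 150, 100, 6), paste0("p", 1:4), seed = 9)
  cfg <- split_config(train_size = 120, validation_size = 60,
                      test_size = 60, min_records_per_set = 60, seed = 5)
  a <- stratified_split(corpus, cfg)
  b <- stratified_split(corpus, cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))

  joined <- merge(a, corpus, by = "visit_id")
  # p4 has few records; wherever it has an eligible record in a period,
  # it must appear in that period's sets
  for (s in c("train", "validation", "test")) {
    period_pre <- s == "train"
    eligible <- corpus$pediatrician_id == "p4" &
      ((corpus$visit_date < cfg$historical_cutoff) == period_pre)
    if (sum(eligible) > 0) {
      expect_true(any(joined$pediatrician_id[joined$set == s] == "p4"))
    }
  }
})

test_that("assignments round-trip through the two-column file", {
  corpus <- flat_corpus(rep(40, 4), paste0("p", 1:4))
  cfg <- split_config(train_size = 30, validation_size = 20, test_size = 20,
                      min_records_per_set = 20, seed = 2)
  asg <- stratified_split(corpus, cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_split(asg, path)
  back <- read_split(path)
  expect_equal(back$visit_id, asg$visit_id)
  expect_equal(back$set, asg$set)
})
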