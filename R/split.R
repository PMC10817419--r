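#' Train/validation/test split configuration
#'
#' The training set is drawn from historical records (strictly before
#' `historical_cutoff`); validation and test sets are drawn disjointly
#' from the later period. Within each set the per-pediatrician record
#' shares of the full corpus are preserved by largest-remainder quota.
#'
#' @param train_size,validation_size,test_size Target set sizes.
#' @param min_records_per_set Every set must contain at least this many
#'   records (default 500, relaxed in small test corpora).
#' @param historical_cutoff Training records must predate this;
#'   validation/test records must not.
#' @param ensure_pediatrician_coverage If `TRUE`, every pediatrician with
#'   at least one eligible record in a set's period contributes at least
#'   one record to that set.
#' @param seed Sampling seed.
#' @return A list of class `otitis_split_config`.
#' @export
split_config <- function(train_size = 4926L, validation_size = 723L,
                         test_size = 880L, min_records_per_set = 500L,
                         historical_cutoff = as.Date("2008-01-01"),
                         ensure_pediatrician_coverage = TRUE,
                         seed = 1L) {
  cfg <- structure(list(
    train_size = as.integer(train_size),
    validation_size = as.integer(validation_size),
    test_size = as.integer(test_size),
    min_records_per_set = as.integer(min_records_per_set),
    historical_cutoff = as.Date(historical_cutoff),
    ensure_pediatrician_coverage = isTRUE(ensure_pediatrician_coverage),
    seed = as.integer(seed)),
    class = c("otitis_split_config", "list"))
  if (cfg$min_records_per_set < 1) {
    stop("min_records_per_set must be >= 1", call. = FALSE)
  }
  sizes <- c(train = cfg$train_size, validation = cfg$validation_size,
             test = cfg$test_size)
  small <- sizes < cfg$min_records_per_set
  if (any(small)) {
    stop("infeasible split: requested ", names(sizes)[small][1],
         " size ", sizes[small][1], " is below min_records_per_set (",
         cfg$min_records_per_set, ")", call. = FALSE)
  }
  cfg
}

#' Stratified temporal train/validation/test split
#'
#' Samples the three sets so that each set's per-pediatrician record
#' counts equal the largest-remainder quota of the pediatricians' shares
#' in the full corpus, the training set lies strictly before the
#' historical cutoff, validation and test lie on/after it and are drawn
#' disjointly from one seeded permutation of the later pool. When a
#' pediatrician has fewer eligible records in a period than their quota,
#' the shortfall is redistributed to pediatricians with spare eligible
#' records, largest corpus share first.
#'
#' @param corpus Visit-record tibble with `visit_id`, `pediatrician_id`,
#'   `visit_date`.
#' @param config An [split_config()].
#' @return A tibble of class `otitis_split` with columns `visit_id`, `set`
#'   (`"train"`, `"validation"`, `"test"`); unsampled records are absent.
#' @export
stratified_split <- function(corpus, config = split_config()) {
  cutoff <- config$historical_cutoff
  if (nrow(corpus) > 0 &&
      (cutoff <= min(corpus$visit_date) || cutoff > max(corpus$visit_date))) {
    stop("infeasible split: historical_cutoff ", format(cutoff),
         " lies outside the corpus date range", call. = FALSE)
  }
  peds <- sort(unique(corpus$pediatrician_id))
  shares <- as.numeric(table(factor(corpus$pediatrician_id, levels = peds)))
  shares <- shares / sum(shares)

  pre <- corpus$visit_date < cutoff
  if (sum(pre) < config$train_size) {
    stop("infeasible split: training set needs ", config$train_size,
         " records but only ", sum(pre), " predate the cutoff",
         call. = FALSE)
  }
  n_post_needed <- config$validation_size + config$test_size
  if (sum(!pre) < n_post_needed) {
    stop("infeasible split: validation+test need ", n_post_needed,
         " records but only ", sum(!pre), " are on/after the cutoff",
         call. = FALSE)
  }

  withr::with_seed(config$seed, {
    cover <- config$ensure_pediatrician_coverage

    avail_pre <- as.numeric(table(factor(corpus$pediatrician_id[pre],
                                         levels = peds)))
    q_train <- allocate_quota(config$train_size, shares, avail_pre, cover,
                              "train")
    train_ids <- sample_by_quota(corpus[pre, ], peds, q_train)

    # one permutation of the post-cutoff pool; validation takes its quota
    # first, test takes its quota from what remains
    post <- corpus[!pre, ]
    post <- post[sample.int(nrow(post)), ]
    avail_post <- as.numeric(table(factor(post$pediatrician_id,
                                          levels = peds)))
    q_val <- allocate_quota(config$validation_size, shares, avail_post,
                            cover, "validation")
    q_test <- allocate_quota(config$test_size, shares, avail_post - q_val,
                             cover, "test")
    val_ids <- character(0); test_ids <- character(0)
    for (i in seq_along(peds)) {
      rows <- which(post$pediatrician_id == peds[i])
      val_ids <- c(val_ids, post$visit_id[rows[seq_len(q_val[i])]])
      test_ids <- c(test_ids,
                    post$visit_id[rows[q_val[i] + seq_len(q_test[i])]])
    }

    out <- tibble::tibble(
      visit_id = c(train_ids, val_ids, test_ids),
      set = c(rep("train", length(train_ids)),
              rep("validation", length(val_ids)),
              rep("test", length(test_ids))))
    class(out) <- c("otitis_split", class(out))
    attr(out, "config") <- config
    out
  })
}

# per-pediatrician counts: largest-remainder quota of `shares`, capped by
# availability, optional >=1 coverage where eligible, total forced to `size`
allocate_quota <- function(size, shares, avail, coverage, set_name) {
  k <- length(shares)
  q <- largest_remainder(size, shares)
  floor_q <- if (coverage) pmin(1L, as.integer(avail)) else rep(0L, k)
  if (coverage) q <- pmax(q, floor_q)
  q <- pmin(q, as.integer(avail))
  ord_share <- order(-shares, seq_len(k))
  diff <- size - sum(q)
  while (diff != 0) {
    if (diff > 0) {
      cand <- ord_share[avail[ord_share] > q[ord_share]]
      if (length(cand) == 0) {
        stop("infeasible split: not enough eligible records to fill the ",
             set_name, " set quota", call. = FALSE)
      }
      take <- cand[seq_len(min(diff, length(cand)))]
      q[take] <- q[take] + 1L
      diff <- diff - length(take)
    } else {
      cand <- order(-q, seq_len(k))
      cand <- cand[q[cand] > floor_q[cand]]
      if (length(cand) == 0) {
        stop("infeasible split: ", set_name, " size ", size,
             " cannot honor one-record-per-pediatrician coverage",
             call. = FALSE)
      }
      take <- cand[seq_len(min(-diff, length(cand)))]
      q[take] <- q[take] - 1L
      diff <- diff + length(take)
    }
  }
  q
}

# uniform within-pediatrician sampling of `quota` records each
sample_by_quota <- function(pool, peds, quota) {
  ids <- character(0)
  for (i in seq_along(peds)) {
    rows <- which(pool$pediatrician_id == peds[i])
    if (quota[i] > 0) {
      ids <- c(ids, pool$visit_id[rows[sample.int(length(rows), quota[i])]])
    }
  }
  ids
}

#' Materialize split subsets
#'
#' @param corpus Visit-record tibble.
#' @param assignment An [stratified_split()] result.
#' @return Named list of tibbles: `train`, `validation`, `test`.
#' @export
split_corpus <- function(corpus, assignment) {
  lapply(stats::setNames(nm = c("train", "validation", "test")), function(s) {
    corpus[corpus$visit_id %in% assignment$visit_id[assignment$set == s], ,
           drop = FALSE]
  })
}

#' Read / write a split assignment as TSV
#'
#' @param assignment An `otitis_split` tibble.
#' @param path File path.
#' @return `read_split()` returns the assignment tibble.
#' @export
write_split <- function(assignment, path) {
  utils::write.table(assignment[, c("visit_id", "set")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  out <- tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                             colClasses = "character"))
  class(out) <- c("otitis_split", class(out))
  out
}
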