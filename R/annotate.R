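#' Recurrence rule parameters
#'
#' Recurrent acute otitis media is defined as at least `short_threshold`
#' episodes within any `short_window_days`-day window (default 3 in 183
#' days, i.e. six months) or at least `long_threshold` episodes within any
#' `long_window_days`-day window (default 4 in 365 days), or an explicit
#' statement by the pediatrician marking the case as recurrent. Windows
#' are fixed day counts, not calendar months, so the rule is exactly
#' testable.
#'
#' @param short_window_days,short_threshold The six-month branch.
#' @param long_window_days,long_threshold The twelve-month branch.
#' @return A list of class `otitis_recurrence_rule`.
#' @export
recurrence_rule <- function(short_window_days = 183L, short_threshold = 3L,
                            long_window_days = 365L, long_threshold = 4L) {
  if (short_threshold < 1 || long_threshold < 1 ||
      short_window_days < 1 || long_window_days < 1) {
    stop("recurrence windows and thresholds must be >= 1", call. = FALSE)
  }
  structure(list(short_window_days = as.integer(short_window_days),
                 short_threshold = as.integer(short_threshold),
                 long_window_days = as.integer(long_window_days),
                 long_threshold = as.integer(long_threshold)),
            class = c("otitis_recurrence_rule", "list"))
}

#' Classify an episode history as recurrent AOM
#'
#' `TRUE` iff the pediatrician explicitly marked the case recurrent, or
#' some window of `short_window_days` (anchored at an episode date, closed
#' interval `[t, t + window - 1]`) contains at least `short_threshold`
#' episodes, or some `long_window_days` window contains at least
#' `long_threshold`.
#'
#' @param episode_dates Vector of episode `Date`s (any order, duplicates
#'   allowed — same-day episodes count once each).
#' @param explicit_statement Did the clinician explicitly state recurrence?
#' @param rule An [recurrence_rule()].
#' @return Logical scalar.
#' @examples
#' d <- as.Date("2010-01-01") + c(0, 60, 120)
#' classify_recurrent(d)
#' @export
classify_recurrent <- function(episode_dates,
                               explicit_statement = FALSE,
                               rule = recurrence_rule()) {
  if (isTRUE(explicit_statement)) return(TRUE)
  d <- sort(as.integer(as.Date(episode_dates)))
  n <- length(d)
  window_hit <- function(win, thr) {
    if (n < thr) return(FALSE)
    for (i in seq_len(n)) {
      if (sum(d >= d[i] & d <= d[i] + win - 1L) >= thr) return(TRUE)
    }
    FALSE
  }
  window_hit(rule$short_window_days, rule$short_threshold) ||
    window_hit(rule$long_window_days, rule$long_threshold)
}

#' Resolve dual-review annotations
#'
#' Two independent reviewers label every record; on agreement the shared
#' label is final, on disagreement the third reviewer's adjudicated label
#' is. A disagreement without an adjudicated label is an error.
#'
#' @param pairs Tibble with columns `record_id`, `label_a`, `label_b`, and
#'   optionally `adjudicated` (required wherever `label_a != label_b`).
#' @return A list with `labels` (tibble `record_id`, `final_label`,
#'   `disagreement`) and `report` (one-row tibble: `n`, `n_disagreements`,
#'   `disagreement_rate`).
#' @export
adjudicate <- function(pairs) {
  a <- otitis_factor(pairs$label_a)
  b <- otitis_factor(pairs$label_b)
  disagree <- as.character(a) != as.character(b)
  adj <- if ("adjudicated" %in% names(pairs)) {
    as.character(pairs$adjudicated)
  } else {
    rep(NA_character_, nrow(pairs))
  }
  missing <- disagree & (is.na(adj) | adj == "")
  if (any(missing)) {
    stop("disagreement without adjudicated label for record(s): ",
         paste(utils::head(pairs$record_id[missing], 5), collapse = ", "),
         call. = FALSE)
  }
  final <- ifelse(disagree, adj, as.character(a))
  list(
    labels = tibble::tibble(record_id = pairs$record_id,
                            final_label = otitis_factor(final),
                            disagreement = disagree),
    report = tibble::tibble(n = nrow(pairs),
                            n_disagreements = sum(disagree),
                            disagreement_rate =
                              if (nrow(pairs) > 0) mean(disagree) else NA_real_)
  )
}

#' Weighted Cohen's kappa
#'
#' Chance-corrected agreement between two raters over the six ordered
#' classes, with linear (default), quadratic, or unweighted (0/1)
#' disagreement weights over the canonical class order:
#' `kappa = 1 - sum(w * observed) / sum(w * expected)`. If chance
#' disagreement is zero (e.g. a constant rater meeting a constant rater),
#' the statistic is undefined; the function returns 0 with a warning.
#'
#' @param labels_a,labels_b Equal-length, non-empty label vectors.
#' @param weighting `"linear"`, `"quadratic"`, or `"unweighted"`.
#' @return Kappa in \[-1, 1\].
#' @examples
#' weighted_cohens_kappa(c("aom", "aom", "no_otitis"),
#'                       c("aom", "aom", "no_otitis"))
#' @export
weighted_cohens_kappa <- function(labels_a, labels_b,
                                  weighting = c("linear", "quadratic",
                                                "unweighted")) {
  weighting <- match.arg(weighting)
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  if (length(labels_a) == 0) {
    stop("label vectors must be non-empty", call. = FALSE)
  }
  a <- otitis_factor(labels_a)
  b <- otitis_factor(labels_b)
  k <- length(otitis_classes())
  O <- table(a, b) / length(a)
  pa <- rowSums(O); pb <- colSums(O)
  E <- outer(pa, pb)
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  W <- switch(weighting,
              linear = d / (k - 1),
              quadratic = (d / (k - 1))^2,
              unweighted = (d > 0) * 1)
  chance <- sum(W * E)
  if (chance < .Machine$double.eps) {
    warning("degenerate kappa: zero chance disagreement; returning 0",
            call. = FALSE)
    return(0)
  }
  1 - sum(W * O) / chance
}

#' Read / write annotation pairs as TSV
#'
#' Columns: `record_id`, `label_a`, `label_b`, `adjudicated` (empty where
#' the reviewers agreed).
#'
#' @param pairs Annotation tibble.
#' @param path File path.
#' @return `read_annotations()` returns the tibble.
#' @export
write_annotations <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      colClasses = "character",
                                      na.strings = ""))
}
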