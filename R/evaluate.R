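#' Confusion matrix of predicted versus gold classes
#'
#' Rows are predicted classes, columns gold classes, both in the canonical
#' order of [otitis_classes()]; cell (i, j) counts records predicted as
#' class i whose gold label is class j.
#'
#' @param predicted,gold Equal-length, non-empty label vectors (factors,
#'   characters, or 0-based indices), or for `predicted` an
#'   [ensemble_predict()] tibble.
#' @return A 6 x 6 integer matrix of class `otitis_confusion`.
#' @examples
#' confusion_matrix(c("aom", "aom", "no_otitis"),
#'                  c("aom", "om_not_acute", "no_otitis"))
#' @export
confusion_matrix <- function(predicted, gold) {
  if (is.data.frame(predicted)) predicted <- predicted$.pred
  if (length(predicted) != length(gold)) {
    stop("predicted and gold label vectors differ in length", call. = FALSE)
  }
  if (length(predicted) == 0) {
    stop("cannot build a confusion matrix from empty inputs", call. = FALSE)
  }
  p <- otitis_factor(predicted)
  g <- otitis_factor(gold)
  cm <- unclass(table(p, g))
  dimnames(cm) <- list(predicted = otitis_classes(),
                       gold = otitis_classes())
  as_otitis_confusion(cm)
}

#' Coerce a 6 x 6 count matrix to an `otitis_confusion`
#'
#' @param x A 6 x 6 nonnegative count matrix, rows = predicted, columns =
#'   gold, in canonical class order.
#' @return An `otitis_confusion` matrix.
#' @export
as_otitis_confusion <- function(x) {
  x <- as.matrix(x)
  if (!all(dim(x) == c(6, 6))) {
    stop("a confusion matrix must be 6 x 6", call. = FALSE)
  }
  if (any(x < 0) || any(x != round(x))) {
    stop("confusion matrix entries must be nonnegative counts",
         call. = FALSE)
  }
  storage.mode(x) <- "integer"
  dimnames(x) <- list(predicted = otitis_classes(), gold = otitis_classes())
  class(x) <- c("otitis_confusion", class(x))
  x
}

#' Accuracy, balanced precision, balanced recall (percent)
#'
#' `accuracy()` is 100 x diagonal sum / total. `balanced_precision()` and
#' `balanced_recall()` are the unweighted means over the six classes of
#' per-class precision (diagonal / row sum) and recall
#' (diagonal / column sum); a class never predicted (empty row) or absent
#' from the gold standard (empty column) contributes 0 to the mean, with a
#' warning — the conservative convention.
#'
#' @param cm An `otitis_confusion` (or coercible 6 x 6 count matrix).
#' @return A percentage in \[0, 100\].
#' @export
accuracy <- function(cm) {
  cm <- as_otitis_confusion(cm)
  total <- sum(cm)
  if (total == 0) stop("confusion matrix is empty", call. = FALSE)
  100 * sum(diag(cm)) / total
}

#' @rdname accuracy
#' @export
balanced_precision <- function(cm) {
  cm <- as_otitis_confusion(cm)
  if (sum(cm) == 0) stop("confusion matrix is empty", call. = FALSE)
  100 * mean(per_class_frac(diag(cm), rowSums(cm), "predicted"))
}

#' @rdname accuracy
#' @export
balanced_recall <- function(cm) {
  cm <- as_otitis_confusion(cm)
  if (sum(cm) == 0) stop("confusion matrix is empty", call. = FALSE)
  100 * mean(per_class_frac(diag(cm), colSums(cm), "gold"))
}

per_class_frac <- function(num, den, axis) {
  out <- ifelse(den > 0, num / den, 0)
  if (any(den == 0)) {
    warning("class(es) with empty ", axis, " margin contribute 0: ",
            paste(otitis_classes()[den == 0], collapse = ", "),
            call. = FALSE)
  }
  out
}

#' Balanced F1: harmonic mean of balanced precision and recall (percent)
#'
#' The harmonic mean `2 * BP * BR / (BP + BR)` of the two balanced
#' metrics. This is the definition consistent with the published result
#' tables of this evaluation style; the macro-average of per-class F1
#' scores is a different quantity (see [metrics_report()]'s `macro_f1`).
#'
#' @param bp,br Balanced precision and recall, as percentages in
#'   \[0, 100\]. If `br` is missing and `bp` is a matrix, both are
#'   computed from it.
#' @return A percentage; 0 (with a warning) when both inputs are 0.
#' @examples
#' balanced_f1(97.03, 93.97)
#' @export
balanced_f1 <- function(bp, br) {
  if (missing(br)) {
    cm <- as_otitis_confusion(bp)
    bp <- balanced_precision(cm)
    br <- balanced_recall(cm)
  }
  if (any(c(bp, br) < 0) || any(c(bp, br) > 100)) {
    stop("balanced precision/recall must be percentages in [0, 100]",
         call. = FALSE)
  }
  if (bp + br == 0) {
    warning("balanced precision and recall are both 0; F1 defined as 0",
            call. = FALSE)
    return(0)
  }
  2 * bp * br / (bp + br)
}

#' Full metrics report from a confusion matrix
#'
#' The balanced-metric summary derived from a 6 x 6 confusion matrix:
#' overall accuracy, balanced (macro) precision and recall, their harmonic
#' mean as balanced F1, the macro-average of per-class F1 scores as a
#' secondary output, per-class precision/recall/F1, and the misclassified
#' count (total minus diagonal).
#'
#' @param cm An `otitis_confusion` (or coercible matrix).
#' @param digits Rounding (half-up) applied to the percentage columns;
#'   `NULL` leaves full precision.
#' @return A list of class `otitis_metrics` with `summary` (one-row
#'   tibble) and `per_class` (six-row tibble).
#' @examples
#' cm <- confusion_matrix(c("aom", "aom"), c("aom", "no_otitis"))
#' metrics_report(cm)$summary
#' @export
metrics_report <- function(cm, digits = NULL) {
  cm <- as_otitis_confusion(cm)
  total <- sum(cm)
  if (total == 0) stop("confusion matrix is empty", call. = FALSE)
  prec <- suppressWarnings(per_class_frac(diag(cm), rowSums(cm), "predicted"))
  rec <- suppressWarnings(per_class_frac(diag(cm), colSums(cm), "gold"))
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  bp <- 100 * mean(prec)
  br <- 100 * mean(rec)
  summary <- tibble::tibble(
    n = total,
    accuracy = 100 * sum(diag(cm)) / total,
    balanced_precision = bp,
    balanced_recall = br,
    balanced_f1 = balanced_f1(bp, br),
    macro_f1 = 100 * mean(f1),
    n_misclassified = total - sum(diag(cm)))
  per_class <- tibble::tibble(
    class = otitis_classes(),
    n_gold = as.integer(colSums(cm)),
    n_predicted = as.integer(rowSums(cm)),
    precision = 100 * prec,
    recall = 100 * rec,
    f1 = 100 * f1)
  if (!is.null(digits)) {
    pct <- c("accuracy", "balanced_precision", "balanced_recall",
             "balanced_f1", "macro_f1")
    summary[pct] <- lapply(summary[pct], round_half_up, digits)
    num <- c("precision", "recall", "f1")
    per_class[num] <- lapply(per_class[num], round_half_up, digits)
  }
  structure(list(summary = summary, per_class = per_class,
                 confusion = cm),
            class = c("otitis_metrics", "list"))
}

#' @export
print.otitis_metrics <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<otitis_metrics> n = %d | accuracy %.2f | balanced ",
                     "precision %.2f | balanced recall %.2f | balanced F1 ",
                     "%.2f | misclassified %d\n"),
              s$n, s$accuracy, s$balanced_precision, s$balanced_recall,
              s$balanced_f1, s$n_misclassified))
  invisible(x)
}

#' @method glance otitis_metrics
#' @export
glance.otitis_metrics <- function(x, ...) x$summary

#' @method tidy otitis_metrics
#' @export
tidy.otitis_metrics <- function(x, ...) x$per_class

#' @method tidy otitis_confusion
#' @export
tidy.otitis_confusion <- function(x, ...) {
  long <- as.data.frame(as.table(unclass(x)), responseName = "n",
                        stringsAsFactors = FALSE)
  tibble::as_tibble(stats::setNames(long, c("predicted", "gold", "n")))
}

#' @method glance otitis_confusion
#' @export
glance.otitis_confusion <- function(x, ...) metrics_report(x)$summary

#' Confusion-matrix heat map
#'
#' @param object An `otitis_confusion`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot otitis_confusion
#' @export
autoplot.otitis_confusion <- function(object, ...) {
  d <- tidy.otitis_confusion(object)
  d$predicted <- factor(d$predicted, levels = rev(otitis_classes()))
  d$gold <- factor(d$gold, levels = otitis_classes())
  ggplot2::ggplot(d, ggplot2::aes(.data$gold, .data$predicted,
                                  fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "gold class", y = "predicted class", fill = "count") +
    ggplot2::theme_minimal()
}

#' Misclassification report
#'
#' Lists every off-diagonal record with its texts and (predicted, gold)
#' label pair, for manual review of error causes (negations, other
#' doctors' diagnoses, atypical perforation phrasing, ...).
#'
#' @param corpus The evaluated records (tibble with `visit_id` and text
#'   fields; a `confounder` column, if present, is carried through).
#' @param predictions Predicted labels (vector or [ensemble_predict()]
#'   tibble), aligned with `corpus` rows.
#' @param gold Gold labels; defaults to `corpus$gold_label`.
#' @return A list with `errors` (tibble of misclassified records) and
#'   `counts` (tibble of off-diagonal (predicted, gold) pair counts).
#' @export
error_report <- function(corpus, predictions, gold = corpus$gold_label) {
  if (is.data.frame(predictions)) predictions <- predictions$.pred
  p <- otitis_factor(predictions)
  g <- otitis_factor(gold)
  if (length(p) != nrow(corpus) || length(g) != nrow(corpus)) {
    stop("predictions and gold labels must align with the corpus rows",
         call. = FALSE)
  }
  bad <- which(as.character(p) != as.character(g))
  keep <- intersect(c("visit_id", visit_text_fields(), "confounder"),
                    names(corpus))
  errors <- corpus[bad, keep, drop = FALSE]
  errors$predicted <- p[bad]
  errors$gold <- g[bad]
  counts <- if (length(bad) > 0) {
    dplyr::count(tibble::tibble(predicted = p[bad], gold = g[bad]),
                 .data$predicted, .data$gold, name = "n")
  } else {
    tibble::tibble(predicted = otitis_factor(character()),
                   gold = otitis_factor(character()), n = integer())
  }
  list(errors = tibble::as_tibble(errors), counts = counts)
}

#' Read / write a confusion matrix as delimited text
#'
#' Tab-separated 6 x 6 count matrix with class names as header and first
#' column.
#'
#' @param cm An `otitis_confusion`.
#' @param path File path.
#' @return `read_confusion()` returns an `otitis_confusion`.
#' @export
write_confusion <- function(cm, path) {
  utils::write.table(as.data.frame(unclass(as_otitis_confusion(cm))), path,
                     sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_confusion
#' @export
read_confusion <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  as_otitis_confusion(m)
}

#' Reference test-set results of the published otitis ensemble
#'
#' The package ships, as plain text, the published 6 x 6 test-set
#' confusion matrix of the ensemble free-text otitis classifier this
#' pipeline re-implements (880 records, Italian pediatric primary-care
#' notes), together with the published per-architecture balanced metrics.
#' They serve as fixed ground truth for validating the metric arithmetic:
#' feeding the matrix to [metrics_report()] must reproduce the published
#' accuracy, balanced precision/recall, and balanced F1.
#'
#' @return `reference_confusion()`: an `otitis_confusion`.
#'   `reference_model_metrics()`: a tibble with one row per selected
#'   network (`model`, `balanced_precision`, `balanced_recall`,
#'   `accuracy`, `balanced_f1`).
#' @examples
#' metrics_report(reference_confusion(), digits = 2)$summary
#' @export
reference_confusion <- function() {
  read_confusion(system.file("extdata", "reference_confusion.tsv",
                             package = "otitext", mustWork = TRUE))
}

#' @rdname reference_confusion
#' @export
reference_model_metrics <- function() {
  tibble::as_tibble(utils::read.table(
    system.file("extdata", "reference_model_metrics.tsv",
                package = "otitext", mustWork = TRUE),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE))
}

#' Export a metrics report as JSON
#'
#' Writes the summary row, the per-class table, and the confusion matrix
#' counts into one JSON document.
#'
#' @param report An [metrics_report()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  jsonlite::write_json(list(
    summary = report$summary,
    per_class = report$per_class,
    confusion = unclass(report$confusion)), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export a misclassification report as JSON Lines
#'
#' One misclassified record per line, with its identifier, text fields,
#' and (predicted, gold) label pair.
#'
#' @param report An [error_report()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_error_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  errs <- report$errors
  for (i in seq_len(nrow(errs))) {
    row <- lapply(errs[i, ], function(col) {
      v <- col[[1]]
      if (is.factor(v)) as.character(v) else v
    })
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE), con)
  }
  invisible(path)
}
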