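#' Logit-averaging ensemble prediction
#'
#' Combines member models by element-wise averaging of their pre-softmax
#' logit matrices, then applies softmax once and takes the arg-max
#' (lowest class index on exact ties). Because softmax is monotone, the
#' predicted class equals the arg-max of the mean logits.
#'
#' @param logit_matrices A list of n x 6 logit matrices (one per member
#'   model), all of identical shape. A single matrix reproduces that
#'   model's own predictions.
#' @return A tibble with `.pred` (factor over [otitis_classes()]) and six
#'   probability columns `p_<class>`.
#' @examples
#' m <- rbind(c(2, 0, 0, 0, 0, 0))
#' ensemble_predict(list(m))
#' @export
ensemble_predict <- function(logit_matrices) {
  if (!is.list(logit_matrices) || length(logit_matrices) == 0) {
    stop("at least one logit matrix is required", call. = FALSE)
  }
  dims <- lapply(logit_matrices, dim)
  if (any(vapply(dims, is.null, TRUE))) {
    stop("logit matrices must be matrices", call. = FALSE)
  }
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1) {
    stop("logit matrices have mismatched shapes", call. = FALSE)
  }
  if (ncol(logit_matrices[[1]]) != 6) {
    stop("logit matrices must have 6 columns", call. = FALSE)
  }
  if (any(!vapply(logit_matrices, function(m) all(is.finite(m)), TRUE)) &&
      nrow(logit_matrices[[1]]) > 0) {
    stop("logit matrices must be finite", call. = FALSE)
  }
  mean_logits <- Reduce(`+`, logit_matrices) / length(logit_matrices)
  if (nrow(mean_logits) == 0) {
    probs <- matrix(numeric(0), 0, 6)
    pred <- integer(0)
  } else {
    probs <- softmax(mean_logits)
    pred <- max.col(probs, ties.method = "first")
  }
  out <- tibble::as_tibble(stats::setNames(
    as.data.frame(probs), paste0("p_", otitis_classes())))
  dplyr::bind_cols(tibble::tibble(.pred = otitis_factor(pred - 1L)), out)
}

#' Accuracy of predictions against gold labels
#'
#' @param predictions Factor/character vector or an [ensemble_predict()]
#'   tibble.
#' @param gold Gold labels.
#' @return Fraction correct in \[0, 1\].
#' @export
prediction_accuracy <- function(predictions, gold) {
  if (is.data.frame(predictions)) predictions <- predictions$.pred
  mean(as.character(otitis_factor(predictions)) ==
         as.character(otitis_factor(gold)))
}

#' Export predictions as a delimited file
#'
#' Tab-separated: record id, predicted class, and the six class
#' probabilities.
#'
#' @param predictions An [ensemble_predict()] tibble.
#' @param visit_id Record identifiers aligned with the rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, visit_id, path) {
  out <- dplyr::bind_cols(tibble::tibble(visit_id = visit_id),
                          predictions)
  out$.pred <- as.character(out$.pred)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
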