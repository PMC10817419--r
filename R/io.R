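#' Read / write a visit corpus as JSON Lines
#'
#' One visit record per line. Text fields are nested under `"fields"` in
#' their stored order; dates are ISO-8601 strings; the optional gold label
#' and episode dates round-trip.
#'
#' @param corpus Visit-record tibble (see [generate_corpus()]).
#' @param path File path.
#' @return `read_corpus()` returns the corpus tibble; `write_corpus()`
#'   returns `path` invisibly.
#' @export
write_corpus <- function(corpus, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    r <- corpus[i, ]
    obj <- list(
      visit_id = r$visit_id,
      patient_id = r$patient_id,
      pediatrician_id = r$pediatrician_id,
      visit_date = format(r$visit_date),
      sex = r$sex,
      fields = stats::setNames(
        lapply(visit_text_fields(), function(f) r[[f]]),
        visit_text_fields())
    )
    if (!is.na(r$gold_label)) obj$gold_label <- as.character(r$gold_label)
    if ("confounder" %in% names(r)) obj$confounder <- r$confounder
    if ("explicit_recurrent" %in% names(r) && !is.na(r$explicit_recurrent)) {
      obj$explicit_recurrent <- r$explicit_recurrent
    }
    if ("episode_dates" %in% names(r) && length(r$episode_dates[[1]]) > 0) {
      obj$episode_dates <- format(r$episode_dates[[1]])
    }
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, function(l) jsonlite::fromJSON(l,
                                                       simplifyVector = TRUE))
  if (length(rows) == 0) return(empty_corpus())
  tibble::tibble(
    visit_id = vapply(rows, `[[`, "", "visit_id"),
    patient_id = vapply(rows, `[[`, "", "patient_id"),
    pediatrician_id = vapply(rows, `[[`, "", "pediatrician_id"),
    visit_date = as.Date(vapply(rows, `[[`, "", "visit_date")),
    sex = vapply(rows, `[[`, "", "sex"),
    diagnosis = vapply(rows, function(r) r$fields$diagnosis %||% "", ""),
    notes = vapply(rows, function(r) r$fields$notes %||% "", ""),
    prescriptions = vapply(rows, function(r) r$fields$prescriptions %||% "",
                           ""),
    gold_label = otitis_factor(vapply(rows, function(r)
      r$gold_label %||% NA_character_, "")),
    confounder = vapply(rows, function(r) r$confounder %||% "none", ""),
    explicit_recurrent = vapply(rows, function(r)
      r$explicit_recurrent %||% NA, NA),
    episode_dates = lapply(rows, function(r)
      as.Date(r$episode_dates %||% character(0)))
  )
}
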