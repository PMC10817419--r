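#' The six diagnostic classes, in canonical order
#'
#' Every component of the pipeline (generator labels, network output neurons,
#' confusion-matrix axes) shares this fixed ordering: `no_otitis`,
#' `otitis_not_media`, `om_not_acute`, `aom`, `aom_perforation`,
#' `aom_recurrent`. The classes are mutually exclusive; `aom` denotes acute
#' otitis media without perforation or recurrence, the modal class in
#' pediatric primary-care extracts.
#'
#' @return Character vector of the six class labels, in canonical order.
#' @examples
#' otitis_classes()
#' @export
otitis_classes <- function() {
  c("no_otitis", "otitis_not_media", "om_not_acute",
    "aom", "aom_perforation", "aom_recurrent")
}

#' Coerce labels to the canonical otitis class factor
#'
#' @param x Character vector, factor, or 0-based integer indices.
#' @return Factor with levels `otitis_classes()`.
#' @examples
#' otitis_factor(c("aom", "no_otitis"))
#' otitis_factor(c(0L, 5L))
#' @export
otitis_factor <- function(x) {
  cls <- otitis_classes()
  if (is.numeric(x)) {
    if (any(x < 0 | x > 5, na.rm = TRUE)) {
      stop("class indices must be in 0..5", call. = FALSE)
    }
    return(factor(cls[x + 1L], levels = cls))
  }
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), cls)
  if (length(bad) > 0) {
    stop("unknown otitis class label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  factor(x, levels = cls)
}

#' @rdname otitis_factor
#' @return `otitis_index()` returns 0-based integer indices.
#' @export
otitis_index <- function(x) {
  as.integer(otitis_factor(x)) - 1L
}

# Names of the free-text fields of a visit record, in their stored order.
# Order matters: fields are merged in this order with SEP boundaries.
visit_text_fields <- function() {
  c("diagnosis", "notes", "prescriptions")
}

# round half up at `digits` (the tables' convention; R's round() is half-even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# largest-remainder (Hamilton) apportionment of n into quotas ~ proportions.
# Ties in the fractional remainder are broken by position (earlier wins).
largest_remainder <- function(n, proportions) {
  stopifnot(n >= 0, all(proportions >= 0))
  s <- sum(proportions)
  if (abs(s - 1) > 1e-9) {
    stop("proportions must sum to 1 (got ", format(s), ")", call. = FALSE)
  }
  exact <- n * proportions
  base <- floor(exact + 1e-12)
  left <- n - sum(base)
  if (left > 0) {
    rem <- exact - base
    take <- order(-rem, seq_along(rem))[seq_len(left)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
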