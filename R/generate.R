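#' Configuration for the synthetic visit generator
#'
#' Defaults emulate the structure of an Italian pediatric primary-care
#' extract screened for otitis: acute otitis media without perforation is
#' the modal class (~45% of screened records), patients are slightly more
#' often male (52.2%), records cluster unevenly across pediatricians, and
#' notes span 2004 through mid-2017 so a historical/later split is
#' possible.
#'
#' @param n_visits Number of visit records to generate.
#' @param n_pediatricians Number of pediatricians records cluster under.
#' @param class_proportions Six nonnegative reals summing to 1, in the
#'   canonical class order of [otitis_classes()]. Class counts are fixed by
#'   largest-remainder apportionment of these proportions, so they are
#'   exact, not sampled.
#' @param male_fraction Probability a newly created patient is male.
#' @param negation_rate,other_doctor_rate Probability a `no_otitis` record
#'   additionally carries a negated otitis mention / a reference to another
#'   doctor's otitis diagnosis — the confounders that make screening text
#'   hard.
#' @param atypical_term_rate Probability an `aom_perforation` record
#'   describes the perforation with atypical terminology instead of a
#'   canonical keyword.
#' @param typo_rate Probability the diagnostic keyword is mutated by a
#'   single-character deletion, substitution, or transposition.
#' @param date_range Length-2 `Date` vector; visit dates are uniform over it.
#' @param note_tokens Length-2 integer vector: range of the target token
#'   count of the notes field (uniform).
#' @param patient_reuse Probability a visit reuses an existing patient of
#'   its pediatrician instead of creating a new one (real extracts have
#'   slightly more visits than children).
#' @param dirichlet_concentration Concentration of the symmetric Dirichlet
#'   from which per-pediatrician visit shares are drawn; small values give
#'   strong clustering.
#' @param seed Integer seed; the corpus is a deterministic function of
#'   (config, lexicon, seed).
#' @return A list of class `otitis_generator_config`.
#' @export
generator_config <- function(n_visits = 2000,
                             n_pediatricians = 142,
                             class_proportions = c(
                               no_otitis = 0.19, otitis_not_media = 0.19,
                               om_not_acute = 0.125, aom = 0.45,
                               aom_perforation = 0.035, aom_recurrent = 0.01),
                             male_fraction = 0.522,
                             negation_rate = 0.05,
                             other_doctor_rate = 0.05,
                             atypical_term_rate = 0.2,
                             typo_rate = 0.05,
                             date_range = as.Date(c("2004-01-01", "2017-08-23")),
                             note_tokens = c(10L, 120L),
                             patient_reuse = 0.1,
                             dirichlet_concentration = 5,
                             seed = 1L) {
  cfg <- list(
    n_visits = as.integer(n_visits),
    n_pediatricians = as.integer(n_pediatricians),
    class_proportions = class_proportions,
    male_fraction = male_fraction,
    negation_rate = negation_rate,
    other_doctor_rate = other_doctor_rate,
    atypical_term_rate = atypical_term_rate,
    typo_rate = typo_rate,
    date_range = as.Date(date_range),
    note_tokens = as.integer(note_tokens),
    patient_reuse = patient_reuse,
    dirichlet_concentration = dirichlet_concentration,
    seed = as.integer(seed)
  )
  class(cfg) <- c("otitis_generator_config", "list")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (cfg$n_visits < 0) stop("n_visits must be nonnegative", call. = FALSE)
  if (cfg$n_pediatricians < 1) {
    stop("n_pediatricians must be positive", call. = FALSE)
  }
  p <- cfg$class_proportions
  if (length(p) != 6 || any(p < 0)) {
    stop("class_proportions must be six nonnegative values", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop("class_proportions must sum to 1 (got ", format(sum(p)), ")",
         call. = FALSE)
  }
  rates <- c(cfg$male_fraction, cfg$negation_rate, cfg$other_doctor_rate,
             cfg$atypical_term_rate, cfg$typo_rate, cfg$patient_reuse)
  if (any(rates < 0 | rates > 1)) {
    stop("fractions and rates must lie in [0, 1]", call. = FALSE)
  }
  if (length(cfg$date_range) != 2 || cfg$date_range[1] > cfg$date_range[2]) {
    stop("date_range must be two ordered dates", call. = FALSE)
  }
  if (length(cfg$note_tokens) != 2 || cfg$note_tokens[1] < 1 ||
      cfg$note_tokens[1] > cfg$note_tokens[2]) {
    stop("note_tokens must be an ordered positive range", call. = FALSE)
  }
  invisible(cfg)
}

#' Generate a labeled synthetic visit corpus
#'
#' Produces exactly `n_visits` records whose per-class counts equal the
#' largest-remainder apportionment of `class_proportions` (deterministic
#' given the seed). Each record carries its generating class as
#' `gold_label`, three free-text fields (`diagnosis`, `notes`,
#' `prescriptions`) seeded with class keywords, background vocabulary,
#' numerals (dosages, temperatures), and — at the configured rates —
#' negated otitis mentions, other-doctor references, atypical perforation
#' phrasing, and single-edit typos. Recurrent-AOM records carry either an
#' explicit "otite ricorrente" statement or an episode history (dates in
#' the `episode_dates` list-column) satisfying the recurrence rule, with
#' equal probability.
#'
#' @param config An [generator_config()] object.
#' @param lexicon A lexicon, by default [default_lexicon()].
#' @return A tibble with one row per visit: `visit_id`, `patient_id`,
#'   `pediatrician_id`, `visit_date`, `sex`, `diagnosis`, `notes`,
#'   `prescriptions`, `gold_label`, `confounder`, `explicit_recurrent`,
#'   `episode_dates`.
#' @examples
#' corpus <- generate_corpus(generator_config(n_visits = 20, seed = 1))
#' dplyr::count(corpus, gold_label)
#' @export
generate_corpus <- function(config = generator_config(),
                            lexicon = default_lexicon()) {
  validate_generator_config(config)
  validate_lexicon(lexicon)
  n <- config$n_visits
  if (n == 0) return(empty_corpus())

  withr::with_seed(config$seed, {
    cls <- otitis_classes()
    quota <- largest_remainder(n, config$class_proportions)
    labels <- sample(rep(cls, times = quota))

    # per-pediatrician clustering: shares drawn from a symmetric Dirichlet
    k <- config$n_pediatricians
    w <- stats::rgamma(k, shape = config$dirichlet_concentration, rate = 1)
    w <- w / sum(w)
    ped <- sample.int(k, n, replace = TRUE, prob = w)

    # patients: reuse an existing patient of the same pediatrician sometimes
    patient_of <- vector("list", k)
    sex_of <- list()
    patient_id <- character(n)
    next_patient <- 0L
    reuse_draw <- stats::runif(n)
    for (i in seq_len(n)) {
      p <- ped[i]
      pool <- patient_of[[p]]
      if (length(pool) > 0 && reuse_draw[i] < config$patient_reuse) {
        patient_id[i] <- pool[sample.int(length(pool), 1)]
      } else {
        next_patient <- next_patient + 1L
        pid <- sprintf("pat%06d", next_patient)
        patient_of[[p]] <- c(pool, pid)
        sex_of[[pid]] <- if (stats::runif(1) < config$male_fraction) {
          "male"
        } else {
          "female"
        }
        patient_id[i] <- pid
      }
    }
    sex <- vapply(patient_id, function(pid) sex_of[[pid]], character(1),
                  USE.NAMES = FALSE)

    span <- as.integer(config$date_range[2] - config$date_range[1])
    visit_date <- config$date_range[1] +
      sample.int(span + 1L, n, replace = TRUE) - 1L

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      rows[[i]] <- generate_visit(labels[i], lexicon, config, visit_date[i])
    }

    tibble::tibble(
      visit_id = sprintf("v%06d", seq_len(n)),
      patient_id = patient_id,
      pediatrician_id = sprintf("ped%03d", ped),
      visit_date = visit_date,
      sex = sex,
      diagnosis = vapply(rows, `[[`, "", "diagnosis"),
      notes = vapply(rows, `[[`, "", "notes"),
      prescriptions = vapply(rows, `[[`, "", "prescriptions"),
      gold_label = otitis_factor(labels),
      confounder = vapply(rows, `[[`, "", "confounder"),
      explicit_recurrent = vapply(rows, `[[`, NA, "explicit_recurrent"),
      episode_dates = lapply(rows, `[[`, "episode_dates")
    )
  })
}

empty_corpus <- function() {
  tibble::tibble(
    visit_id = character(), patient_id = character(),
    pediatrician_id = character(), visit_date = as.Date(character()),
    sex = character(), diagnosis = character(), notes = character(),
    prescriptions = character(), gold_label = otitis_factor(character()),
    confounder = character(), explicit_recurrent = logical(),
    episode_dates = list()
  )
}

#' Generate the text fields of a single visit
#'
#' Draws from the ambient RNG stream; [generate_corpus()] wraps it in a
#' seeded context. Exposed mainly for testing individual confounder
#' branches at forced rates.
#'
#' @param class A single class label from [otitis_classes()].
#' @param lexicon,config As in [generate_corpus()].
#' @param visit_date The visit date (anchors any episode history).
#' @return A list with `diagnosis`, `notes`, `prescriptions`, `confounder`,
#'   `explicit_recurrent`, `episode_dates`.
#' @export
generate_visit <- function(class, lexicon, config,
                           visit_date = as.Date("2010-06-01")) {
  if (!class %in% otitis_classes()) {
    stop("unknown class: ", class, call. = FALSE)
  }
  if (is.null(lexicon$keywords[[class]])) {
    stop("lexicon has no keywords for class: ", class, call. = FALSE)
  }
  confounder <- character(0)
  explicit_recurrent <- NA
  episode_dates <- as.Date(character())

  if (class == "aom_recurrent") {
    explicit_recurrent <- stats::runif(1) < 0.5
    if (explicit_recurrent) {
      kw <- sample(lexicon$keywords[[class]], 1)
    } else {
      kw <- sample(lexicon$recurrent_history, 1)
      episode_dates <- recurrent_history_dates(visit_date)
    }
  } else {
    kw <- sample(lexicon$keywords[[class]], 1)
  }

  if (class == "aom_perforation" &&
      stats::runif(1) < config$atypical_term_rate) {
    kw <- sample(lexicon$atypical_perforation, 1)
    confounder <- c(confounder, "atypical")
  }
  if (stats::runif(1) < config$typo_rate) {
    kw <- mutate_typo(kw)
    confounder <- c(confounder, "typo")
  }

  extras <- character(0)
  if (class == "no_otitis") {
    if (stats::runif(1) < config$negation_rate) {
      extras <- c(extras, sample(lexicon$negation_templates, 1))
      confounder <- c(confounder, "negation")
    }
    if (stats::runif(1) < config$other_doctor_rate) {
      extras <- c(extras, sample(lexicon$other_doctor_templates, 1))
      confounder <- c(confounder, "other_doctor")
    }
  }

  target <- sample(seq(config$note_tokens[1], config$note_tokens[2]), 1)
  n_bg <- max(3L, target - 2L - sum(lengths(strsplit(extras, " "))))
  bg <- sample(lexicon$background, n_bg, replace = TRUE)
  temp <- sprintf("febbre %d,%d", sample(37:40, 1), sample(0:9, 1))
  notes <- paste(c(bg[1:2], temp, bg[-(1:2)], extras), collapse = " ")

  dose <- sample(c(250L, 500L, 50L, 100L), 1)
  days <- sample(5:10, 1)
  prescriptions <- paste(sample(lexicon$drugs, 1), dose, "mg per", days,
                         "giorni")

  list(
    diagnosis = kw,
    notes = notes,
    prescriptions = prescriptions,
    confounder = if (length(confounder) == 0) {
      "none"
    } else {
      paste(confounder, collapse = "+")
    },
    explicit_recurrent = explicit_recurrent,
    episode_dates = episode_dates
  )
}

# episode dates before `visit_date` satisfying the recurrence rule:
# either 3 episodes inside 183 days or 4 inside 365 days, equal odds
recurrent_history_dates <- function(visit_date) {
  if (stats::runif(1) < 0.5) {
    gaps <- sample(20:60, 2, replace = TRUE)
  } else {
    gaps <- sample(60:110, 3, replace = TRUE)
  }
  offsets <- rev(cumsum(c(sample(5:30, 1), gaps)))
  visit_date - offsets
}

# one random single-character edit: deletion, substitution, or transposition
mutate_typo <- function(word) {
  chars <- strsplit(word, "")[[1]]
  n <- length(chars)
  if (n < 2) return(word)
  op <- sample(c("del", "sub", "swap"), 1)
  i <- sample.int(n - 1L, 1)
  if (op == "del") {
    chars <- chars[-i]
  } else if (op == "sub") {
    chars[i] <- sample(letters, 1)
  } else {
    tmp <- chars[i]
    chars[i] <- chars[i + 1]
    chars[i + 1] <- tmp
  }
  paste(chars, collapse = "")
}

#' Summarize a corpus
#'
#' Class counts, per-pediatrician record counts, and sex proportions — the
#' descriptive table one would report for each dataset.
#'
#' @param corpus A visit-record tibble.
#' @return A list of three tibbles: `classes` (`gold_label`, `n`),
#'   `pediatricians` (`pediatrician_id`, `n_records`, `n_patients`), and
#'   `sex` (`sex`, `n`, `prop`).
#' @export
corpus_summary <- function(corpus) {
  classes <- tibble::tibble(gold_label = otitis_classes()) |>
    dplyr::left_join(
      dplyr::count(corpus, gold_label = as.character(.data$gold_label)),
      by = "gold_label") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  pediatricians <- corpus |>
    dplyr::group_by(.data$pediatrician_id) |>
    dplyr::summarise(n_records = dplyr::n(),
                     n_patients = dplyr::n_distinct(.data$patient_id),
                     .groups = "drop")
  sex <- dplyr::count(corpus, .data$sex) |>
    dplyr::mutate(prop = if (nrow(corpus) > 0) .data$n / sum(.data$n) else
      numeric(0))
  list(classes = classes, pediatricians = pediatricians, sex = sex)
}
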