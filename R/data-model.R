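# Domain types, CSV readers/writers, validation, and exclusion accounting.

#' Canonical label sets
#'
#' The two societies, experimental conditions, genders and the four
#' society.condition curve keys used throughout the package. Labels are
#' normalized once, at the data boundary; everything downstream assumes the
#' canonical forms.
#'
#' @name labels
#' @keywords internal
NULL

SOCIETIES <- c("BaYaka", "Bandongo")
CONDITIONS <- c("intra", "inter")
GENDERS <- c("F", "M")
CURVE_KEYS <- c("BaYaka.intra", "BaYaka.inter", "Bandongo.intra", "Bandongo.inter")
EXCLUSION_RULES <- c("incomplete", "shy_or_anxious", "failed_comprehension",
                     "experimenter_error")
TRIAL_COLUMNS <- c("participant_id", "society", "gender", "age_years",
                   "condition", "choice", "presentation_order")

curve_key <- function(society, condition) paste(society, condition, sep = ".")

#' Normalize a society, condition or gender label
#'
#' Case-insensitive mapping of common synonyms onto the canonical labels:
#' societies `BaYaka`/`Bandongo`, conditions `intra`/`inter`, genders `F`/`M`
#' (woman/girl/female map to `F`; man/boy/male map to `M`).
#'
#' @param x character vector of raw labels.
#' @return character vector of canonical labels; unknown labels raise an error.
#' @keywords internal
normalize_society <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- c(bayaka = "BaYaka", bandongo = "Bandongo")[key]
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown society label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(out)
}

normalize_condition <- function(x) {
  key <- gsub("[ _-]?ethnic$", "", tolower(trimws(as.character(x))))
  out <- c(intra = "intra", inter = "inter")[key]
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown condition label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(out)
}

normalize_gender <- function(x) {
  key <- tolower(trimws(as.character(x)))
  map <- c(f = "F", female = "F", woman = "F", girl = "F",
           m = "M", male = "M", man = "M", boy = "M")
  out <- map[key]
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown gender label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(out)
}

#' Construct a validated trial dataset
#'
#' A trial dataset holds one row per participant x condition binary sharing
#' choice: `participant_id`, `society`, `gender`, `age_years` (positive,
#' real-valued -- ages may be estimates), `condition`, `choice` (1 = GIVE,
#' 0 = KEEP) and an optional `presentation_order` in \{1, 2\}.
#'
#' @param trials data frame with the canonical trial columns (labels already
#'   canonical or normalizable synonyms).
#' @param provenance free-text note on where the data came from.
#' @param normalize normalize label synonyms before validating.
#' @return the validated data frame with class `trial_dataset` and a
#'   `provenance` attribute.
#' @examples
#' d <- trial_dataset(data.frame(
#'   participant_id = c("p1", "p1"), society = "BaYaka", gender = "F",
#'   age_years = 9.5, condition = c("intra", "inter"), choice = c(1L, 0L)))
#' nrow(d)
#' @export
trial_dataset <- function(trials, provenance = "", normalize = TRUE) {
  trials <- as.data.frame(trials)
  required <- setdiff(TRIAL_COLUMNS, "presentation_order")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"presentation_order" %in% names(trials)) {
    trials[["presentation_order"]] <- rep(NA_integer_, nrow(trials))
  }
  trials <- trials[, TRIAL_COLUMNS]
  trials$participant_id <- as.character(trials$participant_id)
  if (normalize) {
    trials$society <- normalize_society(trials$society)
    trials$condition <- normalize_condition(trials$condition)
    trials$gender <- normalize_gender(trials$gender)
  }
  age <- suppressWarnings(as.numeric(trials$age_years))
  bad <- which(is.na(age) | age <= 0)
  if (length(bad) > 0) {
    stop("invalid age_years (non-numeric or non-positive) at row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  trials$age_years <- age
  choice <- suppressWarnings(as.integer(trials$choice))
  bad <- which(is.na(choice) | !choice %in% c(0L, 1L))
  if (length(bad) > 0) {
    stop("choice must be 0 (KEEP) or 1 (GIVE); bad row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  trials$choice <- choice
  po <- trials$presentation_order
  if (!all(is.na(po) | po %in% c(1L, 2L))) {
    stop("presentation_order must be 1, 2 or missing", call. = FALSE)
  }
  dup <- duplicated(trials[, c("participant_id", "condition")])
  if (any(dup)) {
    stop("more than one record per (participant_id, condition): ",
         paste(unique(trials$participant_id[dup]), collapse = ", "),
         call. = FALSE)
  }
  rownames(trials) <- NULL
  structure(trials, provenance = as.character(provenance),
            class = c("trial_dataset", "data.frame"))
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("<trial_dataset> %d records, %d participants\n",
              nrow(x), length(unique(x$participant_id))))
  prov <- attr(x, "provenance")
  if (nzchar(prov)) cat("provenance:", prov, "\n")
  print(head(as.data.frame(x), 6))
  invisible(x)
}

#' Read a trial dataset from CSV
#'
#' Expects a header with the canonical columns `participant_id, society,
#' gender, age_years, condition, choice` (plus optional
#' `presentation_order`). Labels are normalized case-insensitively.
#'
#' @param path CSV file path.
#' @return a [trial_dataset()].
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  trial_dataset(raw, provenance = paste0("read from ", path))
}

#' Write a trial dataset to CSV
#'
#' Canonical header and stable column order; round-trips exactly through
#' [read_trials()].
#'
#' @param dataset a [trial_dataset()].
#' @param path output CSV path.
#' @export
write_trials <- function(dataset, path) {
  stopifnot(inherits(dataset, "trial_dataset"))
  write.csv(as.data.frame(dataset)[, TRIAL_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Construct exclusion flags
#'
#' One row per participant with four boolean exclusion rules, in the order in
#' which they are attributed: `incomplete` (opted out before testing),
#' `shy_or_anxious`, `failed_comprehension`, `experimenter_error`.
#'
#' @param participant_id character vector of ids.
#' @param incomplete,shy_or_anxious,failed_comprehension,experimenter_error
#'   logical (or 0/1) vectors, recycled if scalar.
#' @return data frame of class `exclusion_flags`.
#' @export
exclusion_flags <- function(participant_id, incomplete = FALSE,
                            shy_or_anxious = FALSE,
                            failed_comprehension = FALSE,
                            experimenter_error = FALSE) {
  out <- data.frame(participant_id = as.character(participant_id),
                    incomplete = as.logical(incomplete),
                    shy_or_anxious = as.logical(shy_or_anxious),
                    failed_comprehension = as.logical(failed_comprehension),
                    experimenter_error = as.logical(experimenter_error),
                    stringsAsFactors = FALSE)
  if (anyNA(out[EXCLUSION_RULES])) stop("exclusion flags must be TRUE/FALSE", call. = FALSE)
  class(out) <- c("exclusion_flags", "data.frame")
  out
}

#' Apply the participant-exclusion rules
#'
#' A participant is retained iff all four exclusion flags are false.
#' Participants with several true flags are attributed to the first true flag
#' in rule order, so per-rule counts plus the retained total always sum to
#' the number of participants. Flags absent for a participant are treated as
#' all-false.
#'
#' @param participants character vector of participant ids.
#' @param flags an [exclusion_flags()] data frame (duplicated ids are an
#'   error).
#' @return a list with `retained` (character vector of retained ids) and
#'   `report`: a list holding per-rule exclusion counts (`rule_counts`),
#'   `n_total`, and `n_retained`.
#' @examples
#' fx <- exclusion_fixture(seed = 1)
#' apply_exclusions(fx$participants, fx$flags)$report$n_retained  # 179
#' @export
apply_exclusions <- function(participants, flags) {
  participants <- as.character(participants)
  flags <- as.data.frame(flags)
  if (anyDuplicated(flags$participant_id) > 0) {
    stop("duplicate participant id in exclusion flags", call. = FALSE)
  }
  idx <- match(participants, flags$participant_id)
  mat <- matrix(FALSE, nrow = length(participants), ncol = length(EXCLUSION_RULES),
                dimnames = list(NULL, EXCLUSION_RULES))
  present <- !is.na(idx)
  for (rule in EXCLUSION_RULES) {
    mat[present, rule] <- as.logical(flags[[rule]][idx[present]])
  }
  any_true <- rowSums(mat) > 0
  # first true flag in the listed rule order
  first_rule <- apply(mat, 1L, function(r) if (any(r)) which(r)[1L] else NA_integer_)
  rule_counts <- vapply(seq_along(EXCLUSION_RULES),
                        function(k) sum(first_rule == k, na.rm = TRUE), integer(1))
  names(rule_counts) <- EXCLUSION_RULES
  retained <- participants[!any_true]
  list(retained = retained,
       report = list(rule_counts = rule_counts,
                     n_total = length(participants),
                     n_retained = length(retained)))
}

#' Read/write exclusion flags CSV
#'
#' Columns: `participant_id` plus the four rules coded 0/1.
#'
#' @param path CSV file path.
#' @return [exclusion_flags()] data frame.
#' @export
read_exclusion_flags <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("participant_id", EXCLUSION_RULES), names(raw))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  exclusion_flags(raw$participant_id,
                  incomplete = raw$incomplete == 1,
                  shy_or_anxious = raw$shy_or_anxious == 1,
                  failed_comprehension = raw$failed_comprehension == 1,
                  experimenter_error = raw$experimenter_error == 1)
}

#' @rdname read_exclusion_flags
#' @param flags an [exclusion_flags()] data frame.
#' @export
write_exclusion_flags <- function(flags, path) {
  out <- as.data.frame(flags)
  for (rule in EXCLUSION_RULES) out[[rule]] <- as.integer(out[[rule]])
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
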