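# Free-list recoding, frequency tables, Smith's salience, and the
# first-coded learning-mechanism tables.

MECHANISMS <- c("Demonstration", "Task assignment", "Instruction",
                "Observation/Imitation", "Play", "Self", "No Answer")

# round half-up for display (base round() is round-half-even)
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Recode raw free-list category labels
#'
#' Maps raw labels onto canonical categories (e.g. "older peer",
#' "younger peer", "friend" onto "peer"). Labels absent from the mapping
#' pass through unchanged with a logged notice: the category universe of
#' free responses is open.
#'
#' @param raw character vector of raw labels.
#' @param mapping named character vector, `names(mapping)` = raw labels,
#'   values = canonical labels.
#' @param quiet suppress the notice about unmapped labels.
#' @return character vector of canonical labels.
#' @export
recode_categories <- function(raw, mapping = character(0), quiet = FALSE) {
  raw <- as.character(raw)
  hit <- raw %in% names(mapping)
  out <- raw
  out[hit] <- unname(mapping[raw[hit]])
  if (!quiet && any(!hit)) {
    unmapped <- setdiff(unique(raw[!hit]), unname(mapping))
    if (length(unmapped) > 0) {
      message("passing through unmapped categor", if (length(unmapped) > 1) "ies: " else "y: ",
              paste(unmapped, collapse = ", "))
    }
  }
  out
}

#' Recode and de-duplicate free lists
#'
#' Applies [recode_categories()] to the long-format lists, then collapses
#' duplicates created by the recoding within each list, keeping the best
#' (earliest) rank for each canonical category and re-ranking 1..L.
#'
#' @param lists long-format free-list data frame (`participant_id`,
#'   `society`, `domain`, `rank`, `category`).
#' @param mapping named character vector of recodings.
#' @param quiet suppress unmapped-label notices.
#' @return the recoded long-format data frame.
#' @export
recode_freelists <- function(lists, mapping = character(0), quiet = FALSE) {
  lists <- as.data.frame(lists)
  lists$category <- recode_categories(lists$category, mapping, quiet = quiet)
  lists <- lists[order(lists$participant_id, lists$society, lists$domain, lists$rank), ]
  key <- paste(lists$participant_id, lists$society, lists$domain, sep = "\r")
  keep <- !duplicated(paste(key, lists$category, sep = "\r"))
  lists <- lists[keep, ]
  key <- key[keep]
  lists$rank <- stats::ave(seq_len(nrow(lists)), key,
                           FUN = function(i) seq_along(i))
  rownames(lists) <- NULL
  lists
}

validate_freelists <- function(lists) {
  lists <- as.data.frame(lists)
  needed <- c("participant_id", "rank", "category")
  missing_cols <- setdiff(needed, names(lists))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(lists) == 0L) stop("no free lists supplied", call. = FALSE)
  key <- lists$participant_id
  dup <- duplicated(paste(key, lists$category, sep = "\r"))
  if (any(dup)) stop("categories must be distinct within a list", call. = FALSE)
  ok_rank <- tapply(lists$rank, key, function(r) setequal(r, seq_along(r)))
  if (!all(ok_rank)) stop("ranks must be 1..L within each list", call. = FALSE)
  lists
}

#' Smith's salience table
#'
#' For each category `c`, Smith's S is the average inverse percentile rank
#' over all N lists: `S_c = (1/N) * sum over lists p containing c of
#' (L_p - r_pc + 1) / L_p`, with `r` the 1-based rank and `L_p` the list
#' length; lists not containing `c` contribute 0. `S = 1` means every list
#' named the category first; `S = 0` means no list named it.
#'
#' @param lists long-format free lists for one society/domain (each
#'   `participant_id` is one list).
#' @return data frame of class `salience_table` with `category`, `frequency`
#'   (count of lists containing it) and `smiths_s`, sorted by decreasing
#'   salience; the number of lists N is attached as attribute `n_lists`.
#' @examples
#' smiths_salience(data.frame(participant_id = "p1", rank = 1:2,
#'                            category = c("A", "B")))
#' @export
smiths_salience <- function(lists) {
  lists <- validate_freelists(lists)
  n_lists <- length(unique(lists$participant_id))
  len <- stats::ave(lists$rank, lists$participant_id, FUN = length)
  w <- (len - lists$rank + 1) / len
  s <- tapply(w, lists$category, sum) / n_lists
  freq <- tapply(lists$participant_id, lists$category,
                 function(p) length(unique(p)))
  out <- data.frame(category = names(s), frequency = as.integer(freq[names(s)]),
                    smiths_s = as.numeric(s), stringsAsFactors = FALSE)
  out <- out[order(-out$smiths_s, out$category), ]
  rownames(out) <- NULL
  structure(out, n_lists = n_lists, class = c("salience_table", "data.frame"))
}

#' Per-category listing frequencies
#'
#' The number of lists containing each category; consistent with the
#' `frequency` column of [smiths_salience()].
#'
#' @param lists long-format free lists.
#' @return data frame with `category`, `frequency`.
#' @export
frequency_table <- function(lists) {
  lists <- validate_freelists(lists)
  freq <- tapply(lists$participant_id, lists$category,
                 function(p) length(unique(p)))
  out <- data.frame(category = names(freq), frequency = as.integer(freq),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$category), ]
  rownames(out) <- NULL
  out
}

#' Salience tables per society and domain
#'
#' Convenience wrapper applying [smiths_salience()] within each society x
#' domain stratum of a combined long-format table.
#'
#' @param lists long-format free lists with `society` and `domain` columns.
#' @return data frame with `society`, `domain`, `category`, `frequency`,
#'   `smiths_s`.
#' @export
salience_by_group <- function(lists) {
  lists <- as.data.frame(lists)
  groups <- unique(lists[c("society", "domain")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    sub <- lists[lists$society == groups$society[i] &
                 lists$domain == groups$domain[i], ]
    tab <- smiths_salience(sub)
    cbind(society = groups$society[i], domain = groups$domain[i],
          as.data.frame(tab), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Learning-mechanism frequency table
#'
#' Tabulates first-coded learning mechanisms per society and domain. Each
#' participant contributes at most one mechanism per domain (only the first
#' reported mechanism is coded). Percentages use the number of the society's
#' respondents as denominator and are rounded half-up to 2 decimals for
#' display; the raw fractions are retained.
#'
#' @param reports data frame with `participant_id`, `society`, `domain`
#'   (`intra`/`inter`) and `mechanism` (one of Demonstration, Task
#'   assignment, Instruction, Observation/Imitation, Play, Self, No Answer).
#' @return data frame with `society`, `domain`, `mechanism`, `count`,
#'   `percent` (display-rounded) and `fraction` (exact); all mechanism
#'   levels appear, including zero counts.
#' @export
mechanism_table <- function(reports) {
  reports <- as.data.frame(reports)
  needed <- c("participant_id", "society", "domain", "mechanism")
  missing_cols <- setdiff(needed, names(reports))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(reports$mechanism), MECHANISMS)
  if (length(bad) > 0) {
    stop("unknown mechanism(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(reports[c("participant_id", "domain")])
  if (any(dup)) {
    stop("more than one mechanism per (participant, domain)", call. = FALSE)
  }
  n_soc <- tapply(reports$participant_id, reports$society,
                  function(p) length(unique(p)))
  grid <- expand.grid(society = names(n_soc), domain = unique(reports$domain),
                      mechanism = MECHANISMS, stringsAsFactors = FALSE)
  grid$count <- mapply(function(s, d, m) {
    sum(reports$society == s & reports$domain == d & reports$mechanism == m)
  }, grid$society, grid$domain, grid$mechanism)
  grid$fraction <- grid$count / as.numeric(n_soc[grid$society])
  grid$percent <- round_half_up(100 * grid$fraction, 2)
  grid <- grid[order(grid$society, grid$domain,
                     match(grid$mechanism, MECHANISMS)), ]
  rownames(grid) <- NULL
  attr(grid, "n_respondents") <- n_soc
  grid
}

#' Read free-list / mechanism CSV files
#'
#' Free-list CSV columns: `participant_id, society, domain, rank, category`
#' (long format). Mechanism CSV columns: `participant_id, society, domain,
#' mechanism`.
#'
#' @param path CSV file path.
#' @return data frame.
#' @export
read_freelists <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  out <- read.csv(path, stringsAsFactors = FALSE)
  validate_freelists(out)
}

#' @rdname read_freelists
#' @export
read_mechanisms <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.csv(path, stringsAsFactors = FALSE)
}
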