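# Synthetic study generator: trial datasets, exclusion fixtures and
# free-lists with the statistical structure the analysis assumes.

#' Study design for the synthetic cohort
#'
#' Counts of children (5-16 years) and adults (17+ years) per society, the
#' age sampling rule (uniform on the stratum range, or explicit age lists),
#' and the gender balance. Every simulated participant completes both
#' conditions in counterbalanced order.
#'
#' @param n_children,n_adults named integer vectors (one entry per society).
#' @param child_age_range,adult_age_range length-2 ranges in years for
#'   uniform age sampling.
#' @param child_ages,adult_ages optional explicit age vectors (recycled to
#'   the stratum count within each society); override the uniform rule.
#' @param gender_balance proportion of female participants in \[0, 1\].
#' @return list of class `study_design`.
#' @export
study_design <- function(n_children = c(BaYaka = 61, Bandongo = 61),
                         n_adults = c(BaYaka = 41, Bandongo = 42),
                         child_age_range = c(5, 16),
                         adult_age_range = c(17, 70),
                         child_ages = NULL, adult_ages = NULL,
                         gender_balance = 0.5) {
  stopifnot(all(n_children >= 0), all(n_adults >= 0),
            gender_balance >= 0, gender_balance <= 1)
  if (sum(n_children) + sum(n_adults) < 1) {
    stop("design must include at least one participant", call. = FALSE)
  }
  if (!setequal(names(n_children), SOCIETIES) || !setequal(names(n_adults), SOCIETIES)) {
    stop("counts must be named by society: ", paste(SOCIETIES, collapse = ", "),
         call. = FALSE)
  }
  structure(list(n_children = n_children[SOCIETIES], n_adults = n_adults[SOCIETIES],
                 child_age_range = child_age_range, adult_age_range = adult_age_range,
                 child_ages = child_ages, adult_ages = adult_ages,
                 gender_balance = gender_balance),
            class = "study_design")
}

#' The default (study-sized) design
#'
#' 122 children and 83 adults across the two societies, 205 participants in
#' total, ages uniform on \[5, 16\] and \[17, 70\], gender balance 0.5, both
#' conditions per participant with counterbalanced presentation order.
#'
#' @return a [study_design()].
#' @export
default_design <- function() study_design()

#' A design scaled to a target cohort size
#'
#' Keeps the default child/adult proportions (122:83) while setting the
#' number of participants per society, for recovery and power simulations.
#'
#' @param n_per_society participants per society.
#' @return a [study_design()].
#' @export
scaled_design <- function(n_per_society) {
  n_child <- round(n_per_society * 122 / 205)
  n_adult <- n_per_society - n_child
  study_design(n_children = c(BaYaka = n_child, Bandongo = n_child),
               n_adults = c(BaYaka = n_adult, Bandongo = n_adult))
}

#' Generative truth mirroring the fitted study
#'
#' Default true parameters for simulation: the infant probability and the
#' four adult sharing probabilities are set to the study's posterior means
#' (0.42; Bandongo intra 0.45, Bandongo inter 0.36, BaYaka intra 0.40,
#' BaYaka inter 0.40). Midpoint ages are fixed at `a = 8` years (middle
#' childhood) for all curves and each rate `b` is chosen so the curve's
#' completion age `a + 3/b` equals the study's posterior-mean completion age
#' (BaYaka 11.51/12.46, Bandongo 13.31/12.15 for intra/inter). Gender
#' offsets are zero.
#'
#' @return a [model_parameters()].
#' @export
default_truth <- function() {
  completion <- c(BaYaka.intra = 11.51, BaYaka.inter = 12.46,
                  Bandongo.intra = 13.31, Bandongo.inter = 12.15)
  p_adult <- c(BaYaka.intra = 0.40, BaYaka.inter = 0.40,
               Bandongo.intra = 0.45, Bandongo.inter = 0.36)
  curves <- lapply(CURVE_KEYS, function(key) {
    a <- 8
    curve_parameters(a = a, b = 3 / (completion[[key]] - a), p_adult = p_adult[[key]])
  })
  names(curves) <- CURVE_KEYS
  model_parameters(p_infant = 0.42, curves = curves)
}

#' A fixed, identifiable generative truth
#'
#' A truth whose trajectories are clearly visible in data of a few hundred
#' participants: infant rate 0.15, adult rate 0.85 in all four cells,
#' midpoint 8 years, rate 0.8/year (completion age 11.75), no gender
#' offsets. Used as the base for the power study, whose premise is that the
#' infant-to-adult shift in sharing rates is distinct enough for completion
#' ages to be estimable at all; with near-flat curves the completion age of
#' a curve is unidentified and no difference of any size is detectable.
#'
#' @return a [model_parameters()].
#' @export
identifiable_truth <- function() {
  curves <- lapply(CURVE_KEYS, function(key) curve_parameters(8, 0.8, 0.85))
  names(curves) <- CURVE_KEYS
  model_parameters(0.15, curves)
}

#' Draw a random identifiable truth for recovery studies
#'
#' Samples generative parameters uniformly over the scientifically plausible
#' identifiable range: rising trajectories with the midpoint inside the
#' sampled age span (`a` in \[7, 13\] years), visible transitions (`b` in
#' \[0.3, 0.8\] per year), infant rates in \[0.15, 0.45\], adult rates in
#' \[0.55, 0.9\], and modest gender offsets. Truths vary across replicates
#' so prior-shrinkage pulls average out over a recovery study instead of
#' accumulating on one side, and degenerate flat-curve posteriors (where
#' curve parameters revert to the prior and interval coverage of a fixed
#' point is meaningless) are avoided.
#'
#' @param seed integer RNG seed.
#' @return a [model_parameters()].
#' @export
draw_plausible_truth <- function(seed) {
  set.seed(seed)
  curves <- lapply(CURVE_KEYS, function(key) {
    curve_parameters(a = runif(1, 7, 13), b = runif(1, 0.3, 0.8),
                     p_adult = runif(1, 0.55, 0.9),
                     a_g = rnorm(1, 0, 0.3), b_g = rnorm(1, 0, 0.1),
                     p_g = rnorm(1, 0, 0.3))
  })
  names(curves) <- CURVE_KEYS
  model_parameters(runif(1, 0.15, 0.45), curves)
}

# hash (seed, participant index) into a per-participant substream seed so a
# participant's choice draws do not depend on cohort insertion order
participant_seed <- function(seed, index) {
  (as.numeric(seed) %% 65536 * 31013 + index * 7919) %% 2147483647
}

stratum_ages <- function(n, range, explicit) {
  if (n == 0L) return(numeric(0))
  if (!is.null(explicit)) return(rep_len(as.numeric(explicit), n))
  runif(n, range[1], range[2])
}

#' Simulate a trial dataset from known parameters
#'
#' Builds a cohort from the design (ages, genders, counterbalanced
#' presentation order) and draws each choice from
#' `Bernoulli(sharing_probability(age, society, condition, gender))` under
#' the generative truth. Each participant's two choices use a seed substream
#' keyed by (seed, participant index), so draws are reproducible and
#' independent of cohort assembly order.
#'
#' @param truth a [model_parameters()] used as generative truth.
#' @param design a [study_design()].
#' @param seed integer RNG seed.
#' @return a [trial_dataset()] with one record per participant per condition.
#' @examples
#' d <- simulate_trials(default_truth(), scaled_design(20), seed = 1)
#' table(d$condition)
#' @export
simulate_trials <- function(truth, design = default_design(), seed = 1L) {
  stopifnot(inherits(truth, "model_parameters"), inherits(design, "study_design"))
  # generative truth may sit on the closed probability boundary [0, 1]
  # (degenerate all-GIVE / all-KEEP curves), unlike fitted parameters
  probs <- c(truth$p_infant,
             vapply(truth$curves, function(cv) cv$p_adult, numeric(1)))
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("invalid truth: probabilities outside [0, 1]", call. = FALSE)
  }
  ab <- unlist(lapply(truth$curves, function(cv) c(cv$a, cv$b)))
  if (any(!is.finite(ab)) || any(ab <= 0)) {
    stop("invalid truth: non-positive a or b", call. = FALSE)
  }
  set.seed(seed)
  cohort <- do.call(rbind, lapply(SOCIETIES, function(soc) {
    n_c <- design$n_children[[soc]]
    n_a <- design$n_adults[[soc]]
    ages <- c(stratum_ages(n_c, design$child_age_range, design$child_ages),
              stratum_ages(n_a, design$adult_age_range, design$adult_ages))
    n <- n_c + n_a
    if (n == 0L) return(NULL)
    data.frame(participant_id = sprintf("%s-%03d", soc, seq_len(n)),
               society = soc, age_years = ages,
               gender = ifelse(runif(n) < design$gender_balance, "F", "M"),
               stringsAsFactors = FALSE)
  }))
  n_total <- nrow(cohort)
  # counterbalancing: alternate which condition is presented first
  first <- ifelse(seq_len(n_total) %% 2L == 1L, "intra", "inter")
  u <- matrix(NA_real_, n_total, 2)  # substream uniforms, presentation order
  for (i in seq_len(n_total)) {
    set.seed(participant_seed(seed, i))
    u[i, ] <- runif(2)
  }
  long <- data.frame(
    participant_id = rep(cohort$participant_id, each = 2L),
    society = rep(cohort$society, each = 2L),
    gender = rep(cohort$gender, each = 2L),
    age_years = rep(cohort$age_years, each = 2L),
    condition = as.vector(vapply(first, function(f) {
      if (f == "intra") c("intra", "inter") else c("inter", "intra")
    }, character(2))),
    presentation_order = rep(c(1L, 2L), n_total),
    stringsAsFactors = FALSE)
  long$u <- as.vector(t(u))
  z <- gender_code(long$gender)
  keys <- curve_key(long$society, long$condition)
  p <- numeric(nrow(long))
  for (key in CURVE_KEYS) {
    sel <- keys == key
    if (any(sel)) {
      p[sel] <- sharing_probability(long$age_years[sel], truth$p_infant,
                                    truth$curves[[key]], z[sel])
    }
  }
  long$choice <- as.integer(long$u < p)
  long$u <- NULL
  trial_dataset(long, provenance = sprintf("simulated (seed %d)", as.integer(seed)))
}

#' Exclusion fixture reproducing the study's accounting
#'
#' 205 participants with disjoint true exclusion flags in counts 5
#' (incomplete), 5 (shy/anxious), 11 (failed comprehension) and 5
#' (experimenter error), so that [apply_exclusions()] retains 179.
#'
#' @param seed integer seed deciding which participants carry which flag.
#' @return list with `participants` (ids) and `flags`
#'   ([exclusion_flags()]).
#' @export
exclusion_fixture <- function(seed = 1L) {
  set.seed(seed)
  n <- 205L
  ids <- sprintf("P%03d", seq_len(n))
  counts <- c(incomplete = 5L, shy_or_anxious = 5L,
              failed_comprehension = 11L, experimenter_error = 5L)
  flagged <- sample(ids, sum(counts))
  groups <- rep(names(counts), counts)
  flags <- exclusion_flags(ids,
                           incomplete = ids %in% flagged[groups == "incomplete"],
                           shy_or_anxious = ids %in% flagged[groups == "shy_or_anxious"],
                           failed_comprehension = ids %in% flagged[groups == "failed_comprehension"],
                           experimenter_error = ids %in% flagged[groups == "experimenter_error"])
  list(participants = ids, flags = flags)
}

#' Simulate free-list interview data
#'
#' For each list, every category in the profile is named independently with
#' its listing probability; named categories are ordered by their rank
#' tendency perturbed with standard Gumbel noise (smaller tendency = earlier
#' in the list), then truncated to `max_length`. A list that would come out
#' empty names the most probable category, keeping list lengths >= 1.
#'
#' @param salience_profile data frame with columns `category`, `p_listed`
#'   (probability in \[0, 1\] of being named) and `rank_tendency` (mean
#'   position tendency; any real scale).
#' @param n_lists number of lists to generate.
#' @param max_length maximum list length (>= 1).
#' @param seed integer RNG seed.
#' @param society,domain labels attached to every generated list.
#' @return long-format data frame: `participant_id`, `society`, `domain`,
#'   `rank`, `category`.
#' @export
simulate_freelists <- function(salience_profile, n_lists, max_length = 10L,
                               seed = 1L, society = "BaYaka", domain = "intra") {
  prof <- as.data.frame(salience_profile)
  if (nrow(prof) == 0L) stop("empty category universe", call. = FALSE)
  stopifnot(all(c("category", "p_listed", "rank_tendency") %in% names(prof)),
            all(prof$p_listed >= 0 & prof$p_listed <= 1), max_length >= 1)
  set.seed(seed)
  if (n_lists == 0L) {
    return(data.frame(participant_id = character(0), society = character(0),
                      domain = character(0), rank = integer(0),
                      category = character(0), stringsAsFactors = FALSE))
  }
  out <- lapply(seq_len(n_lists), function(i) {
    named <- runif(nrow(prof)) < prof$p_listed
    if (!any(named)) named[which.max(prof$p_listed)] <- TRUE
    cats <- prof$category[named]
    # Gumbel-perturbed tendencies give a random but tendency-respecting order
    noise <- -log(-log(runif(length(cats))))
    ord <- order(prof$rank_tendency[named] - noise)
    cats <- cats[ord][seq_len(min(length(cats), max_length))]
    data.frame(participant_id = sprintf("L%04d", i), society = society,
               domain = domain, rank = seq_along(cats), category = cats,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
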