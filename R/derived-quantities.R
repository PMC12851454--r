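# Completion ages, inter-vs-intra contrasts, the hypothesis-support rule,
# marginal sharing rates, and the simulation-based power study.

#' Norm-acquisition completion age
#'
#' The age at which 95% of the change between the infant and adult sharing
#' probabilities has taken place, i.e. where `exp(-b (x - a)) = 0.05`. The
#' default `approx` mode uses the `a + 3/b` rule; `exact`
#' mode uses `a + log(20)/b`.
#'
#' @param a midpoint age (years); vectorized.
#' @param b transition rate (per year, > 0); vectorized.
#' @param mode `"approx"` (a + 3/b, default) or `"exact"` (a + log(20)/b).
#' @return completion age in years.
#' @examples
#' completion_age(10, 0.2)            # 25
#' completion_age(10, 0.2, "exact")   # 24.979
#' @export
completion_age <- function(a, b, mode = c("approx", "exact")) {
  mode <- match.arg(mode)
  if (any(!is.finite(b)) || any(b <= 0)) {
    stop("completion age undefined for b <= 0", call. = FALSE)
  }
  a + (if (mode == "approx") 3 else log(20)) / b
}

#' Posterior summary of a curve's completion age
#'
#' Applies [completion_age()] to each draw's base (a, b) for the requested
#' society and condition. The base parameters are used directly: averaging
#' the two gender adjustments `a + 0.5 a_g` and `a - 0.5 a_g` returns `a`,
#' so the base curve is the gender-marginal one.
#'
#' @param draws a `posterior_draws` object.
#' @param society,condition canonical labels.
#' @param mode completion-age mode, see [completion_age()].
#' @param mass HPDI probability mass.
#' @return one-row data frame of class `completion_summary`: `society`,
#'   `condition`, `mean`, `hpdi_low`, `hpdi_high`, `mass`.
#' @export
completion_posterior <- function(draws, society, condition,
                                 mode = c("approx", "exact"), mass = 0.89) {
  mode <- match.arg(mode)
  key <- curve_key(society, condition)
  if (!key %in% CURVE_KEYS) {
    stop("unknown society/condition: ", key, call. = FALSE)
  }
  df <- draws_frame(draws)
  if (nrow(df) == 0L) stop("draws must be non-empty", call. = FALSE)
  x <- completion_age(df[[paste0("a.", key)]], df[[paste0("b.", key)]], mode)
  hp <- hpdi(x, mass)
  structure(data.frame(society = society, condition = condition,
                       mean = mean(x), hpdi_low = hp[["low"]],
                       hpdi_high = hp[["high"]], mass = mass,
                       stringsAsFactors = FALSE),
            class = c("completion_summary", "data.frame"))
}

#' Posterior contrast of completion ages (inter minus intra)
#'
#' Per draw, the difference between the inter- and intra-ethnic completion
#' ages for one society; reports the posterior mean, HPDI and the posterior
#' probability that the difference is strictly positive (the hypothesized
#' direction: inter-ethnic norms completed later).
#'
#' @param draws a `posterior_draws` object.
#' @param society canonical society label.
#' @param mode completion-age mode.
#' @param mass HPDI probability mass.
#' @return one-row data frame of class `contrast_result`: `society`, `mean`,
#'   `hpdi_low`, `hpdi_high`, `prob_positive`, `mass`.
#' @export
completion_contrast <- function(draws, society, mode = c("approx", "exact"),
                                mass = 0.89) {
  mode <- match.arg(mode)
  df <- draws_frame(draws)
  if (nrow(df) == 0L) stop("draws must be non-empty", call. = FALSE)
  d <- completion_age(df[[paste0("a.", curve_key(society, "inter"))]],
                      df[[paste0("b.", curve_key(society, "inter"))]], mode) -
       completion_age(df[[paste0("a.", curve_key(society, "intra"))]],
                      df[[paste0("b.", curve_key(society, "intra"))]], mode)
  hp <- hpdi(d, mass)
  structure(data.frame(society = society, mean = mean(d),
                       hpdi_low = hp[["low"]], hpdi_high = hp[["high"]],
                       prob_positive = mean(d > 0), mass = mass,
                       stringsAsFactors = FALSE),
            class = c("contrast_result", "data.frame"))
}

#' Hypothesis-support rule
#'
#' Support is declared when the posterior probability of a positive
#' completion-age difference strictly exceeds the threshold (default 0.75).
#'
#' @param result a [completion_contrast()] result, or a bare posterior
#'   probability.
#' @param threshold support threshold in (0, 1).
#' @return logical.
#' @examples
#' hypothesis_support(0.43)  # FALSE
#' hypothesis_support(0.76)  # TRUE
#' @export
hypothesis_support <- function(result, threshold = 0.75) {
  stopifnot(threshold > 0, threshold < 1)
  p <- if (is.numeric(result)) result else result$prob_positive
  p > threshold
}

#' Posterior marginal sharing rates
#'
#' The infant rate is shared across societies and conditions; adult rates
#' are per society x condition, marginalizing over gender by averaging the
#' two gender-specific adult probabilities
#' `invlogit(logit(p_adult) +/- 0.5 p_g)` within each draw.
#'
#' @param draws a `posterior_draws` object.
#' @param which `"infant"` or `"adult"`.
#' @param society,condition required iff `which = "adult"`.
#' @param mass HPDI probability mass.
#' @return one-row data frame of class `rate_summary`: `which`, `society`,
#'   `condition`, `mean`, `hpdi_low`, `hpdi_high`, `mass`.
#' @export
marginal_rate <- function(draws, which = c("infant", "adult"), society = NULL,
                          condition = NULL, mass = 0.89) {
  which <- match.arg(which)
  df <- draws_frame(draws)
  if (nrow(df) == 0L) stop("draws must be non-empty", call. = FALSE)
  if (which == "infant") {
    x <- df$p_infant
    society <- NA_character_; condition <- NA_character_
  } else {
    if (is.null(society) || is.null(condition)) {
      stop("society and condition are required for adult rates", call. = FALSE)
    }
    key <- curve_key(society, condition)
    if (!key %in% CURVE_KEYS) stop("unknown society/condition: ", key, call. = FALSE)
    lp <- qlogis(df[[paste0("p_adult.", key)]])
    pg <- df[[paste0("p_g.", key)]]
    x <- (plogis(lp + 0.5 * pg) + plogis(lp - 0.5 * pg)) / 2
  }
  hp <- hpdi(x, mass)
  structure(data.frame(which = which, society = society, condition = condition,
                       mean = mean(x), hpdi_low = hp[["low"]],
                       hpdi_high = hp[["high"]], mass = mass,
                       stringsAsFactors = FALSE),
            class = c("rate_summary", "data.frame"))
}

# shift the inter curves so their completion age exceeds intra's by delta
# years (shift a, hold b); inter otherwise copies the intra curve so the
# delta = 0 truth is exactly symmetric
shifted_truth <- function(base, delta_years) {
  curves <- base$curves
  for (soc in SOCIETIES) {
    intra <- curves[[curve_key(soc, "intra")]]
    curves[[curve_key(soc, "inter")]] <-
      curve_parameters(intra$a + delta_years, intra$b, intra$p_adult,
                       intra$a_g, intra$b_g, intra$p_g)
  }
  model_parameters(base$p_infant, curves)
}

#' Simulation-based power study for the completion-age contrast
#'
#' For each replicate, a study is simulated in which each society's
#' inter-ethnic curve equals its intra-ethnic curve with the midpoint age
#' shifted by `delta_years` (so the true completion-age difference is
#' exactly `delta_years`); the model is refit and the hypothesis-support
#' rule applied to the designated society's contrast. The detection fraction
#' is the share of replicates in which support is declared.
#'
#' @param delta_years true completion-age difference (>= 0), years.
#' @param n_participants total participants in each simulated study.
#' @param replicates number of simulated studies (>= 1).
#' @param truth base [model_parameters()]; its intra curves are kept and its
#'   inter curves replaced by the shifted intra curves.
#' @param threshold support threshold.
#' @param seed integer seed; replicate seeds are derived from it.
#' @param society society whose contrast is tested.
#' @param config [sampler_config()] used for each refit.
#' @return list of class `power_result`: `delta_years`, `n_participants`,
#'   `replicates`, `detection_fraction`, and the per-replicate posterior
#'   probabilities `prob_positive`.
#' @export
power_study <- function(delta_years, n_participants, replicates,
                        truth = identifiable_truth(), threshold = 0.75, seed = 1L,
                        society = "BaYaka",
                        config = sampler_config(chains = 2L, iterations = 3000L,
                                                seed = 1L)) {
  stopifnot(delta_years >= 0, replicates >= 1, n_participants >= 2)
  truth_d <- shifted_truth(truth, delta_years)
  design <- scaled_design(max(1L, round(n_participants / 2)))
  probs <- vapply(seq_len(replicates), function(r) {
    rep_seed <- (as.numeric(seed) * 1009 + r * 7919) %% 2147483647
    d <- simulate_trials(truth_d, design, seed = rep_seed)
    cfg <- config
    cfg$seed <- as.integer((rep_seed + 1) %% 2147483647)
    fit <- suppressWarnings(fit_trajectories(d, config = cfg))
    completion_contrast(fit, society)$prob_positive
  }, numeric(1))
  structure(list(delta_years = delta_years, n_participants = n_participants,
                 replicates = replicates,
                 detection_fraction = mean(probs > threshold),
                 prob_positive = probs, threshold = threshold,
                 society = society),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("<power_result> delta = %.2f y, n = %d, %d replicates: detection %.2f (threshold %.2f, %s)\n",
              x$delta_years, x$n_participants, x$replicates,
              x$detection_fraction, x$threshold, x$society))
  invisible(x)
}
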