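# Run configuration, trajectory plots and the consolidated run report.

#' Analysis run configuration
#'
#' Bundles the analysis constants: the prior specification, sampler
#' configuration, HPDI mass (default 0.89), completion-age mode (default
#' `approx`, the `a + 3/b` approximation), hypothesis-support threshold
#' (default 0.75) and master seed.
#'
#' @param prior a [prior_spec()].
#' @param sampler a [sampler_config()].
#' @param hpdi_mass HPDI probability mass in (0, 1).
#' @param completion_mode `"approx"` or `"exact"`.
#' @param threshold hypothesis-support threshold in (0, 1).
#' @param seed integer master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(prior = prior_spec(), sampler = sampler_config(),
                       hpdi_mass = 0.89, completion_mode = "approx",
                       threshold = 0.75, seed = 1L) {
  stopifnot(hpdi_mass > 0, hpdi_mass < 1, threshold > 0, threshold < 1)
  completion_mode <- match.arg(completion_mode, c("approx", "exact"))
  structure(list(prior = prior, sampler = sampler, hpdi_mass = hpdi_mass,
                 completion_mode = completion_mode, threshold = threshold,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Posterior predictive trajectory plot
#'
#' One panel per society x condition: thin lines are individual posterior
#' sample curves, the thick line the posterior-mean trajectory, and the
#' dotted vertical line the posterior-mean completion age. Curves
#' marginalize over gender (they use the base parameters, the average of
#' the two gender-specific adjustments).
#'
#' @param draws a `posterior_draws` object.
#' @param data optional [trial_dataset()]; observed GIVE fractions in age
#'   bins are overlaid as points when given.
#' @param path optional output file (written with `ggplot2::ggsave`; use a
#'   `.pdf` extension to stay display-free).
#' @param n_curves number of thin posterior sample curves per panel.
#' @param ages age grid for the curves.
#' @param mode completion-age mode for the vertical line.
#' @return the ggplot object, invisibly.
#' @export
plot_trajectories <- function(draws, data = NULL, path = NULL, n_curves = 100L,
                              ages = seq(5, 70, by = 0.5),
                              mode = c("approx", "exact")) {
  mode <- match.arg(mode)
  df <- draws_frame(draws)
  if (nrow(df) == 0L) stop("draws must be non-empty", call. = FALSE)
  pick <- round(seq(1, nrow(df), length.out = min(n_curves, nrow(df))))
  panels <- lapply(CURVE_KEYS, function(key) {
    soc <- sub("\\..*$", "", key)
    cond <- sub("^.*\\.", "", key)
    a <- df[[paste0("a.", key)]]; b <- df[[paste0("b.", key)]]
    pa <- df[[paste0("p_adult.", key)]]; pi_ <- df$p_infant
    curve_of <- function(i) pi_[i] + (pa[i] - pi_[i]) * plogis(b[i] * (ages - a[i]))
    thin <- do.call(rbind, lapply(pick, function(i) {
      data.frame(society = soc, condition = cond, draw = i, age = ages,
                 p = curve_of(i), stringsAsFactors = FALSE)
    }))
    mean_curve <- data.frame(
      society = soc, condition = cond, age = ages,
      p = rowMeans(vapply(seq_len(nrow(df)),
                          function(i) curve_of(i), numeric(length(ages)))),
      stringsAsFactors = FALSE)
    completion <- mean(completion_age(a, b, mode))
    list(thin = thin, mean = mean_curve,
         comp = data.frame(society = soc, condition = cond, x = completion,
                           stringsAsFactors = FALSE))
  })
  thin <- do.call(rbind, lapply(panels, `[[`, "thin"))
  mean_curve <- do.call(rbind, lapply(panels, `[[`, "mean"))
  comp <- do.call(rbind, lapply(panels, `[[`, "comp"))
  gg <- ggplot2::ggplot() +
    ggplot2::geom_line(data = thin,
                       ggplot2::aes(x = .data$age, y = .data$p,
                                    group = .data$draw),
                       linewidth = 0.2, alpha = 0.15, colour = "steelblue") +
    ggplot2::geom_line(data = mean_curve,
                       ggplot2::aes(x = .data$age, y = .data$p),
                       linewidth = 1.1, colour = "black") +
    ggplot2::geom_vline(data = comp,
                        ggplot2::aes(xintercept = .data$x),
                        linetype = "dotted") +
    ggplot2::facet_grid(society ~ condition) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Age (years)", y = "P(GIVE)") +
    ggplot2::theme_minimal()
  if (!is.null(data) && nrow(data) > 0) {
    bins <- cut(data$age_years, breaks = seq(0, 75, by = 5))
    obs <- stats::aggregate(
      list(p = data$choice),
      list(society = data$society, condition = data$condition, bin = bins,
           age = 5 * (as.integer(bins) - 0.5)),
      mean)
    gg <- gg + ggplot2::geom_point(data = obs,
                                   ggplot2::aes(x = .data$age, y = .data$p),
                                   shape = 1)
  }
  if (!is.null(path)) ggplot2::ggsave(path, gg, width = 8, height = 6)
  invisible(gg)
}

fmt_hpdi <- function(low, high) sprintf("[%.2f, %.2f]", low, high)

#' Render a consolidated run report
#'
#' Assembles the posterior summaries into a single human-readable markdown
#' document: sharing rates, completion ages, inter-vs-intra contrasts with
#' support verdicts, exclusion accounting and convergence warnings. Sections
#' whose summaries are absent are omitted entirely. Regenerating the report
#' from the same persisted draws reproduces it byte for byte.
#'
#' @param summaries list with any of: `rates` (rows from [marginal_rate()]),
#'   `completions` (rows from [completion_posterior()]), `contrasts` (rows
#'   from [completion_contrast()]), `threshold` (support threshold, used
#'   with `contrasts`), `exclusions` (an [apply_exclusions()] report),
#'   `diagnostics` (from [mcmc_diagnostics()]).
#' @param path optional output file.
#' @return character vector of report lines, invisibly.
#' @export
render_report <- function(summaries, path = NULL) {
  if (!is.list(summaries) || length(summaries) == 0L) {
    stop("at least one summary is required", call. = FALSE)
  }
  lines <- c("# Developmental trajectories of sharing norms: run report", "")
  if (!is.null(summaries$exclusions)) {
    rep_ <- summaries$exclusions
    lines <- c(lines, "## Exclusion accounting", "",
               sprintf("- recruited: %d", rep_$n_total),
               sprintf("- excluded (%s): %s", names(rep_$rule_counts),
                       rep_$rule_counts),
               sprintf("- retained: %d", rep_$n_retained), "")
  }
  if (!is.null(summaries$rates)) {
    r <- summaries$rates
    lines <- c(lines, "## Posterior sharing rates", "",
               "| rate | society | condition | mean | HPDI |",
               "|---|---|---|---|---|",
               sprintf("| %s | %s | %s | %.2f | %s |", r$which,
                       ifelse(is.na(r$society), "-", r$society),
                       ifelse(is.na(r$condition), "-", r$condition),
                       r$mean, fmt_hpdi(r$hpdi_low, r$hpdi_high)), "")
  }
  if (!is.null(summaries$completions)) {
    cm <- summaries$completions
    lines <- c(lines, "## Completion ages (years)", "",
               "| society | condition | mean | HPDI |",
               "|---|---|---|---|",
               sprintf("| %s | %s | %.2f | %s |", cm$society, cm$condition,
                       cm$mean, fmt_hpdi(cm$hpdi_low, cm$hpdi_high)), "")
  }
  if (!is.null(summaries$contrasts)) {
    ct <- summaries$contrasts
    threshold <- if (!is.null(summaries$threshold)) summaries$threshold else 0.75
    lines <- c(lines, "## Completion-age contrasts (inter - intra)", "",
               "| society | mean | HPDI | P(diff > 0) | supported |",
               "|---|---|---|---|---|",
               sprintf("| %s | %.2f | %s | %.2f | %s |", ct$society, ct$mean,
                       fmt_hpdi(ct$hpdi_low, ct$hpdi_high), ct$prob_positive,
                       ifelse(hypothesis_support(ct$prob_positive, threshold),
                              "yes", "no")), "")
  }
  if (!is.null(summaries$diagnostics)) {
    dg <- summaries$diagnostics
    flagged <- dg[dg$rhat > 1.01, , drop = FALSE]
    lines <- c(lines, "## Convergence", "",
               sprintf("- max split R-hat: %.3f", max(dg$rhat, na.rm = TRUE)),
               sprintf("- min bulk ESS: %.0f", min(dg$ess, na.rm = TRUE)))
    if (nrow(flagged) > 0) {
      lines <- c(lines,
                 sprintf("- WARNING: R-hat > 1.01 for %s",
                         paste(flagged$parameter, collapse = ", ")))
    }
    lines <- c(lines, "")
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
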