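# Posterior sampling, convergence diagnostics and posterior summaries.

#' Sampler configuration
#'
#' Defaults mirror the study's reported MCMC budget: 4 chains of 10,000
#' iterations each, with the first half of every chain discarded as warmup
#' (adaptation happens only during warmup). The implemented algorithm is a
#' componentwise adaptive random-walk Metropolis sampler on unconstrained
#' (log/logit) parameter space.
#'
#' @param chains number of chains (>= 1).
#' @param iterations iterations per chain (warmup included).
#' @param warmup_frac fraction of each chain used as adaptive warmup, in
#'   (0, 1). At least 100 post-warmup draws per chain are required.
#' @param seed integer RNG seed; fixes initial values and all proposals.
#' @param algorithm sampler name (only `"adaptive-metropolis"` is built in).
#' @return list of class `sampler_config`.
#' @export
sampler_config <- function(chains = 4L, iterations = 10000L, warmup_frac = 0.5,
                           seed = 1L, algorithm = "adaptive-metropolis") {
  chains <- as.integer(chains); iterations <- as.integer(iterations)
  stopifnot(chains >= 1, iterations >= 2, warmup_frac > 0, warmup_frac < 1)
  algorithm <- match.arg(algorithm, "adaptive-metropolis")
  n_warmup <- floor(iterations * warmup_frac)
  if (iterations - n_warmup < 100L) {
    stop("need at least 100 post-warmup draws per chain", call. = FALSE)
  }
  structure(list(chains = chains, iterations = iterations,
                 warmup_frac = warmup_frac, n_warmup = as.integer(n_warmup),
                 seed = as.integer(seed), algorithm = algorithm),
            class = "sampler_config")
}

# natural <-> unconstrained transforms over the 25-scalar layout
TRANSFORMS <- c("logit", rep(c("log", "log", "logit", "id", "id", "id"), 4))

to_unconstrained <- function(v) {
  out <- v
  out[TRANSFORMS == "log"] <- log(v[TRANSFORMS == "log"])
  out[TRANSFORMS == "logit"] <- qlogis(v[TRANSFORMS == "logit"])
  out
}

to_natural <- function(theta) {
  out <- theta
  out[TRANSFORMS == "log"] <- exp(theta[TRANSFORMS == "log"])
  out[TRANSFORMS == "logit"] <- plogis(theta[TRANSFORMS == "logit"])
  out
}

data_fingerprint <- function(data) {
  sprintf("n=%d;sum_choice=%d;sum_age=%.6f", nrow(data), sum(data$choice),
          sum(data$age_years))
}

#' Fit the developmental-trajectory model
#'
#' Samples the posterior defined by [log_prior()] + [log_likelihood()] with a
#' componentwise adaptive random-walk Metropolis sampler implemented in C++.
#' Parameters move on unconstrained space (log for `a` and `b`, logit for
#' probabilities), so the positive-quadrant truncation of the (a, b) prior
#' needs no rejection step; transform Jacobians are part of the kernel.
#' Chains are initialized from independent prior draws. Deterministic given
#' `(data, spec, config)` including the seed. A warning is emitted whenever
#' any split R-hat exceeds 1.01 (the run is never aborted).
#'
#' @param data a non-empty [trial_dataset()].
#' @param spec a [prior_spec()].
#' @param config a [sampler_config()].
#' @param fixed optional named numeric vector (names from [scalar_names()],
#'   values on the natural scale) of parameters to hold fixed.
#' @return object of class `posterior_draws`: list with `draws` (data frame
#'   with `chain`, `iteration` and one column per free scalar parameter, all
#'   on the natural scale), `config`, `fingerprint`, `fixed`, and
#'   `diagnostics` (see [mcmc_diagnostics()]; `NULL` for single-chain runs).
#' @export
fit_trajectories <- function(data, spec = prior_spec(), config = sampler_config(),
                             fixed = NULL) {
  stopifnot(inherits(data, "trial_dataset"))
  if (nrow(data) == 0L) stop("data must be non-empty", call. = FALSE)
  nm <- scalar_names()
  free <- rep(TRUE, length(nm))
  theta_fixed <- rep(NA_real_, length(nm))
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), nm)
    if (length(bad) > 0) stop("unknown fixed parameter(s): ",
                              paste(bad, collapse = ", "), call. = FALSE)
    idx <- match(names(fixed), nm)
    free[idx] <- FALSE
    full <- rep(NA_real_, length(nm)); full[idx] <- fixed
    theta_fixed <- suppressWarnings(to_unconstrained(full))
    if (any(!is.finite(theta_fixed[idx]))) {
      stop("fixed values must respect parameter supports", call. = FALSE)
    }
  }
  cell <- match(curve_key(data$society, data$condition), CURVE_KEYS) - 1L
  z <- gender_code(data$gender)
  set.seed(config$seed)
  inits <- sample_prior_thetas(spec, config$chains)
  chains <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    theta0 <- inits[[ch]]
    theta0[!free] <- theta_fixed[!free]
    res <- mh_sampler_cpp(data$age_years, data$choice, z, cell,
                          unclass(spec), theta0, free,
                          config$iterations, config$n_warmup, 0.3)
    nat <- t(apply(res$draws, 1L, to_natural))
    colnames(nat) <- nm
    chains[[ch]] <- data.frame(chain = ch, iteration = seq_len(nrow(nat)), nat,
                               check.names = FALSE)
  }
  draws <- do.call(rbind, chains)
  out <- structure(list(draws = draws, config = config,
                        fingerprint = data_fingerprint(data),
                        fixed = fixed, free = stats::setNames(free, nm)),
                   class = "posterior_draws")
  if (config$chains >= 2L) {
    out$diagnostics <- mcmc_diagnostics(out)
    worst <- max(out$diagnostics$rhat, na.rm = TRUE)
    if (is.finite(worst) && worst > 1.01) {
      warning(sprintf("max split R-hat = %.3f exceeds 1.01; inspect convergence",
                      worst), call. = FALSE)
    }
  }
  out
}

# prior draws expressed on the unconstrained scale (chain initial values);
# consumes the current RNG stream
sample_prior_thetas <- function(spec, n) {
  lapply(seq_len(n), function(i) {
    ab <- lapply(CURVE_KEYS, function(k) rtruncmvn_pos(1, spec$ab_mean, spec$ab_cov))
    v <- c(rbeta(1, spec$p_infant_shape[1], spec$p_infant_shape[2]),
           unlist(lapply(ab, function(m) {
             c(m[1, 1], m[1, 2],
               rbeta(1, spec$p_adult_shape[1], spec$p_adult_shape[2]),
               rnorm(3, 0, spec$gender_sd))
           })))
    to_unconstrained(v)
  })
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws> %d draws (%d chains x %d), %s\n",
              nrow(x$draws), x$config$chains,
              x$config$iterations - x$config$n_warmup, x$config$algorithm))
  if (!is.null(x$diagnostics)) {
    cat(sprintf("max split R-hat %.3f, min ESS %.0f\n",
                max(x$diagnostics$rhat, na.rm = TRUE),
                min(x$diagnostics$ess, na.rm = TRUE)))
  }
  invisible(x)
}

#' Highest posterior density interval
#'
#' The narrowest contiguous interval of the sorted sample containing
#' `ceiling(mass * n)` points. Width ties are broken by the lowest starting
#' index, making the result deterministic.
#'
#' @param samples numeric vector (>= 2 values).
#' @param mass probability mass in (0, 1); default 0.89.
#' @return named numeric `c(low, high)`.
#' @examples
#' hpdi(1:100, 0.89)  # c(1, 89)
#' @export
hpdi <- function(samples, mass = 0.89) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("need at least 2 samples", call. = FALSE)
  stopifnot(mass > 0, mass < 1)
  s <- sort(samples)
  n <- length(s)
  k <- ceiling(mass * n)
  if (k >= n) return(c(low = s[1], high = s[n]))
  starts <- seq_len(n - k + 1L)
  widths <- s[starts + k - 1L] - s[starts]
  i <- which.min(widths)  # which.min takes the first (lowest-start) tie
  c(low = s[i], high = s[i + k - 1L])
}

draws_frame <- function(draws) {
  if (inherits(draws, "posterior_draws")) draws$draws else as.data.frame(draws)
}

#' Reconstruct the model parameters of one posterior draw
#'
#' @param draws a `posterior_draws` object.
#' @param i draw (row) index.
#' @return a [model_parameters()].
#' @export
draw_parameters <- function(draws, i) {
  df <- draws_frame(draws)
  v <- unlist(df[i, scalar_names()])
  vector_to_params(v)
}

#' Posterior mean and HPDI of a scalar summary
#'
#' Pools all post-warmup draws across chains. `extractor` may be the name of
#' a scalar parameter column (fast path) or a function of a
#' [model_parameters()] object evaluated per draw.
#'
#' @param draws a `posterior_draws` object.
#' @param extractor scalar column name or `function(params) -> scalar`.
#' @param mass HPDI probability mass.
#' @return list with `mean`, `hpdi` (`c(low, high)`), `mass`.
#' @export
summarize_draws <- function(draws, extractor, mass = 0.89) {
  df <- draws_frame(draws)
  if (nrow(df) == 0L) stop("draws must be non-empty", call. = FALSE)
  if (is.character(extractor)) {
    if (!extractor %in% names(df)) {
      stop("unknown scalar: ", extractor, call. = FALSE)
    }
    x <- df[[extractor]]
  } else {
    x <- vapply(seq_len(nrow(df)),
                function(i) extractor(draw_parameters(draws, i)), numeric(1))
  }
  if (anyNA(x)) stop("extractor undefined for some draw", call. = FALSE)
  list(mean = mean(x), hpdi = hpdi(x, mass), mass = mass)
}

# FFT-based autocovariance (biased, as used in ESS estimation)
autocov_fft <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  m <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(x, rep(0, m - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / m
  ac / n
}

rank_normalize <- function(x) {
  qnorm((rank(x, ties.method = "average") - 3 / 8) / (length(x) + 1 / 4))
}

split_chains <- function(df, col) {
  out <- list()
  for (ch in unique(df$chain)) {
    x <- df[[col]][df$chain == ch]
    h <- floor(length(x) / 2)
    out <- c(out, list(x[seq_len(h)], x[h + seq_len(h)]))
  }
  out
}

rhat_split <- function(chains) {
  m <- length(chains)
  n <- length(chains[[1]])
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(1)
  sqrt((W * (n - 1) / n + B / n) / W)
}

ess_chains <- function(chains) {
  m <- length(chains)
  n <- length(chains[[1]])
  vars <- vapply(chains, var, numeric(1))
  means <- vapply(chains, mean, numeric(1))
  W <- mean(vars)
  var_plus <- W * (n - 1) / n + var(means)
  if (var_plus == 0) return(NA_real_)
  acs <- lapply(chains, autocov_fft)
  rho <- 1 - (W - vapply(seq_len(n - 1), function(t) {
    mean(vapply(acs, function(a) a[t + 1], numeric(1)))
  }, numeric(1))) / var_plus
  # Geyer initial monotone positive sequence over lag pairs
  tmax <- length(rho)
  pair <- numeric(0)
  t <- 1
  while (t + 1 <= tmax) {
    p <- rho[t] + rho[t + 1]
    if (p < 0) break
    pair <- c(pair, p)
    t <- t + 2
  }
  if (length(pair) > 1) pair <- cummin(pair)
  # tau = 1 + 2 * sum_t rho_t with pairs P_k = rho_{2k-1} + rho_{2k}
  tau <- 1 + 2 * sum(pair)
  max(m * n / tau, 1e-8)
}

#' Split R-hat and effective sample size
#'
#' Rank-normalized split R-hat and bulk effective sample size for every free
#' scalar parameter, computed from chains split in half (so a trending chain
#' is caught). Requires at least two chains.
#'
#' @param draws a `posterior_draws` object (or the draws data frame).
#' @return data frame with `parameter`, `rhat`, `ess`.
#' @export
mcmc_diagnostics <- function(draws) {
  df <- draws_frame(draws)
  if (length(unique(df$chain)) < 2L) {
    stop("diagnostics require at least two chains", call. = FALSE)
  }
  cols <- setdiff(names(df), c("chain", "iteration"))
  if (inherits(draws, "posterior_draws")) {
    cols <- names(which(draws$free))
  }
  res <- lapply(cols, function(col) {
    x <- df[[col]]
    if (sd(x) == 0) return(data.frame(parameter = col, rhat = 1, ess = NA_real_))
    zdf <- df[c("chain", col)]
    zdf[[col]] <- rank_normalize(zdf[[col]])
    chains <- split_chains(zdf, col)
    data.frame(parameter = col, rhat = rhat_split(chains),
               ess = ess_chains(chains))
  })
  do.call(rbind, res)
}

#' Persist posterior draws to CSV (plus metadata sidecar)
#'
#' One row per draw, one column per scalar, with `chain` and `iteration`
#' columns; a `<path>.meta` sidecar stores the sampler config and data
#' fingerprint as flat `key: value` lines. [read_draws()] restores the
#' object.
#'
#' @param draws a `posterior_draws` object.
#' @param path output CSV path.
#' @export
write_draws <- function(draws, path) {
  stopifnot(inherits(draws, "posterior_draws"))
  write.csv(draws$draws, path, row.names = FALSE)
  meta <- c(sprintf("chains: %d", draws$config$chains),
            sprintf("iterations: %d", draws$config$iterations),
            sprintf("warmup_frac: %.17g", draws$config$warmup_frac),
            sprintf("seed: %d", draws$config$seed),
            sprintf("algorithm: %s", draws$config$algorithm),
            sprintf("fingerprint: %s", draws$fingerprint))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  meta_path <- paste0(path, ".meta")
  config <- sampler_config()
  fingerprint <- NA_character_
  if (file.exists(meta_path)) {
    kv <- strsplit(readLines(meta_path), ": ", fixed = TRUE)
    vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                            vapply(kv, `[`, character(1), 1))
    config <- sampler_config(chains = as.integer(vals[["chains"]]),
                             iterations = as.integer(vals[["iterations"]]),
                             warmup_frac = as.numeric(vals[["warmup_frac"]]),
                             seed = as.integer(vals[["seed"]]),
                             algorithm = vals[["algorithm"]])
    fingerprint <- vals[["fingerprint"]]
  }
  free <- stats::setNames(scalar_names() %in% names(df), scalar_names())
  structure(list(draws = df, config = config, fingerprint = fingerprint,
                 fixed = NULL, free = free),
            class = "posterior_draws")
}
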