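test_that("hpdi returns the narrowest window with deterministic ties", {
  # all width-88 windows of 1..100 tie; the lowest start wins
  expect_equal(hpdi(1:100, 0.89), c(low = 1, high = 89))
  expect_equal(hpdi(rep(3.5, 10), 0.89), c(low = 3.5, high = 3.5))
  expect_error(hpdi(1, 0.89), "at least 2")

  set.seed(77)
  x <- rnorm(200000)
  h <- hpdi(x, 0.89)
  # symmetric density: HPDI equals the central interval, +/- 1.598
  q <- qnorm(0.5 + 0.89 / 2)
  expect_lt(abs(h[["low"]] + q), 0.05)
  expect_lt(abs(h[["high"]] - q), 0.05)
})

test_that("hpdi agrees with the brute-force window search on random samples", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(2:60, 1)
    x <- switch(sample(3, 1), rnorm(n), rexp(n), sample(1:10, n, replace = TRUE))
    mass <- runif(1, 0.3, 0.97)
    expect_equal(unname(hpdi(x, mass)), oracle_hpdi(x, mass))
  }
})

test_that("hpdi intervals nest as mass grows", {
  set.seed(13)
  x <- rgamma(500, 2, 1)
  h50 <- hpdi(x, 0.5); h89 <- hpdi(x, 0.89); h97 <- hpdi(x, 0.97)
  expect_gte(h50[["low"]], h89[["low"]]); expect_lte(h50[["high"]], h89[["high"]])
  expect_gte(h89[["low"]], h97[["low"]]); expect_lte(h89[["high"]], h97[["high"]])
})

test_that("summaries pool chains, honour extractors and ignore chain order", {
  d <- simulate_trials(identifiable_truth(), scaled_design(30), seed = 2)
  fit <- suppressWarnings(
    fit_trajectories(d, config = sampler_config(chains = 2, iterations = 600,
                                                seed = 5)))
  s1 <- summarize_draws(fit, "p_infant")
  expect_true(s1$hpdi[["low"]] <= s1$mean && s1$mean <= s1$hpdi[["high"]])

  # function extractor equals the column fast path
  s2 <- summarize_draws(fit, function(p) p$p_infant)
  expect_equal(s2, s1)

  # constant extractor collapses to (c, [c, c])
  s3 <- summarize_draws(fit, function(p) 7)
  expect_equal(s3$mean, 7); expect_equal(unname(s3$hpdi), c(7, 7))

  # permuting chain labels leaves pooled summaries unchanged
  flipped <- fit
  flipped$draws$chain <- 3L - flipped$draws$chain
  flipped$draws <- flipped$draws[order(flipped$draws$chain), ]
  expect_equal(summarize_draws(flipped, "p_infant"), s1)
})

test_that("prior-only draws summarize to the Beta(1.5, 1.5) mean", {
  prior_draws <- sample_prior(n = 4000, seed = 44)
  df <- as.data.frame(do.call(rbind, lapply(prior_draws, params_to_vector)))
  expect_lt(abs(summarize_draws(df, "p_infant")$mean - 0.5),
            3 * 0.25 / sqrt(4000))
})

test_that("fitting is deterministic given data, spec, config and seed", {
  d <- simulate_trials(identifiable_truth(), scaled_design(20), seed = 3)
  cfg <- sampler_config(chains = 2, iterations = 500, seed = 23)
  f1 <- suppressWarnings(fit_trajectories(d, config = cfg))
  f2 <- suppressWarnings(fit_trajectories(d, config = cfg))
  expect_identical(f1$draws, f2$draws)
  expect_error(fit_trajectories(d[0, ], config = cfg), "non-empty")
})

test_that("sampler marginals match a dense grid-integration oracle", {
  # reduction: a, b and all offsets fixed, data in one cell; the posterior
  # over (p_infant, p_adult) is integrable on a dense 2-D grid
  set.seed(5)
  n <- 60
  ages <- runif(n, 5, 40)
  a0 <- 8; b0 <- 0.6
  p_t <- 0.3 + (0.7 - 0.3) * plogis(b0 * (ages - a0))
  y <- rbinom(n, 1, p_t)
  d <- trial_dataset(data.frame(participant_id = sprintf("p%02d", 1:n),
                                society = "BaYaka", gender = "F",
                                age_years = ages, condition = "intra",
                                choice = y))
  keys <- c("BaYaka.intra", "BaYaka.inter", "Bandongo.intra", "Bandongo.inter")
  fixed <- c()
  for (key in keys) {
    fixed[paste0("a.", key)] <- a0; fixed[paste0("b.", key)] <- b0
    for (g in c("a_g", "b_g", "p_g")) fixed[paste0(g, ".", key)] <- 0
    if (key != "BaYaka.intra") fixed[paste0("p_adult.", key)] <- 0.5
  }
  fit <- suppressWarnings(
    fit_trajectories(d, config = sampler_config(chains = 2, iterations = 6000,
                                                seed = 11), fixed = fixed))
  g <- seq(0.0005, 0.9995, length.out = 400)
  w <- plogis(b0 * (ages - a0))
  logpost <- outer(g, g, Vectorize(function(pi_, pa) {
    p <- pi_ + (pa - pi_) * w
    sum(ifelse(y == 1, log(p), log1p(-p))) +
      dbeta(pi_, 1.5, 1.5, log = TRUE) + dbeta(pa, 0.75, 0.75, log = TRUE)
  }))
  post <- exp(logpost - max(logpost)); post <- post / sum(post)
  expect_lt(abs(mean(fit$draws$p_infant) - sum(rowSums(post) * g)), 0.01)
  expect_lt(abs(mean(fit$draws[["p_adult.BaYaka.intra"]]) -
                  sum(colSums(post) * g)), 0.01)
})

test_that("split R-hat and ESS behave for copied, iid and shifted chains", {
  set.seed(9)
  x <- rnorm(1000)
  copied <- data.frame(chain = rep(1:2, each = 1000), iteration = rep(1:1000, 2),
                       p_infant = c(x, x), check.names = FALSE)
  dg <- mcmc_diagnostics(copied)
  expect_lt(abs(dg$rhat[dg$parameter == "p_infant"] - 1), 1e-3)

  set.seed(10)
  iid <- data.frame(chain = rep(1:2, each = 5000), iteration = rep(1:5000, 2),
                    p_infant = rnorm(10000))
  dg2 <- mcmc_diagnostics(iid)
  expect_lt(abs(dg2$ess - 10000) / 10000, 0.2)

  shifted <- copied
  shifted$p_infant[shifted$chain == 2] <- shifted$p_infant[shifted$chain == 2] + 10
  expect_gt(mcmc_diagnostics(shifted)$rhat, 1.1)

  expect_error(mcmc_diagnostics(copied[copied$chain == 1, ]), "two chains")
})

test_that("draws persist to CSV with metadata and read back", {
  d <- simulate_trials(identifiable_truth(), scaled_design(20), seed = 3)
  fit <- suppressWarnings(
    fit_trajectories(d, config = sampler_config(chains = 2, iterations = 400,
                                                seed = 19)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_draws(fit, path)
  back <- read_draws(path)
  expect_equal(back$draws, fit$draws, tolerance = 1e-12)
  expect_equal(back$config$seed, fit$config$seed)
  expect_equal(back$fingerprint, fit$fingerprint)
  # summaries from reloaded draws agree with the originals
  expect_equal(completion_contrast(back, "BaYaka"),
               completion_contrast(fit, "BaYaka"), tolerance = 1e-12)
})
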