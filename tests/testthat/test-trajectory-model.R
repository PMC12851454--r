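test_that("gender adjustment follows the stated transform", {
  cv <- curve_parameters(a = 10, b = 0.3, p_adult = 0.5, a_g = 2, b_g = 0.1,
                         p_g = 2)
  # zero offsets leave the curve unchanged
  cv0 <- curve_parameters(10, 0.3, 0.5)
  eff0 <- effective_parameters(cv0, 0.5)
  expect_equal(c(eff0$a_eff, eff0$b_eff, eff0$p_adult_eff), c(10, 0.3, 0.5))

  eff <- effective_parameters(cv, 0.5)
  expect_equal(eff$a_eff, 11)
  expect_equal(eff$p_adult_eff, plogis(1), tolerance = 1e-12)
  effm <- effective_parameters(cv, -0.5)
  expect_equal(effm$a_eff, 9)
})

test_that("sharing probability evaluates the logistic trajectory", {
  cv <- curve_parameters(a = 10, b = 0.3, p_adult = 0.8)
  # midpoint identity at age = a
  expect_equal(sharing_probability(10, 0.4, cv), (0.4 + 0.8) / 2)
  # hand evaluation at age 20: 0.4 + 0.4 / (1 + e^-3)
  expect_equal(sharing_probability(20, 0.4, cv), 0.4 + 0.4 / (1 + exp(-3)),
               tolerance = 1e-12)
  # flat curve when p_adult = p_infant
  flat <- curve_parameters(10, 0.3, 0.55)
  expect_equal(sharing_probability(c(1, 20, 60), 0.55, flat), rep(0.55, 3))
  # monotone increasing towards p_adult when p_adult > p_infant
  ages <- seq(1, 80, by = 0.5)
  p <- sharing_probability(ages, 0.2, cv)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p >= 0.2 & p <= 0.8))
  expect_equal(sharing_probability(1e6, 0.2, cv), 0.8)
})

test_that("log-likelihood matches a record-wise oracle and basic cases", {
  params <- make_random_params(71)
  empty <- make_tiny_dataset()[0, ]
  expect_equal(log_likelihood(empty, params), 0)

  # one record at the curve midpoint with matched rates gives log(1/2)
  cv5 <- curve_parameters(10, 0.3, 0.5)
  keys <- c("BaYaka.intra", "BaYaka.inter", "Bandongo.intra", "Bandongo.inter")
  p5 <- model_parameters(0.5, setNames(rep(list(cv5), 4), keys))
  one <- trial_dataset(data.frame(participant_id = "p1", society = "BaYaka",
                                  gender = "F", age_years = 10,
                                  condition = "intra", choice = 1L))
  expect_equal(log_likelihood(one, p5), log(0.5), tolerance = 1e-12)

  set.seed(42)
  d <- simulate_trials(default_truth(), scaled_design(25), seed = 6)
  expect_equal(log_likelihood(d, params), oracle_log_likelihood(d, params),
               tolerance = 1e-12)
  # invariant to record order
  shuf <- trial_dataset(as.data.frame(d)[sample(nrow(d)), ])
  expect_equal(log_likelihood(shuf, params), log_likelihood(d, params),
               tolerance = 1e-12)
})

test_that("log-prior has the stated support and component densities", {
  spec <- prior_spec()
  params <- make_random_params(3)
  # Beta(1.5, 1.5) at 1/2 contributes log(4/pi)
  at_half <- params; at_half$p_infant <- 0.5
  at_third <- params; at_third$p_infant <- 0.3
  expect_equal(log_prior(at_half, spec) - log_prior(at_third, spec),
               dbeta(0.5, 1.5, 1.5, log = TRUE) - dbeta(0.3, 1.5, 1.5, log = TRUE),
               tolerance = 1e-12)
  expect_equal(dbeta(0.5, 1.5, 1.5, log = TRUE), log(4 / pi), tolerance = 1e-12)

  # outside the truncated support
  bad <- params
  bad$curves[["BaYaka.inter"]] <- curve_parameters(-1, 0.5, 0.5, validate = FALSE)
  expect_identical(log_prior(bad, spec), -Inf)

  # doubling the gender-effect scale softens the penalty of an offset
  # sitting two (original) scales from zero
  p0 <- make_random_params(4)
  for (key in names(p0$curves)) {
    p0$curves[[key]]$a_g <- 0; p0$curves[[key]]$b_g <- 0; p0$curves[[key]]$p_g <- 0
  }
  p1 <- p0
  p1$curves[["BaYaka.intra"]]$a_g <- 2 * spec$gender_sd
  wide <- prior_spec(gender_sd = 2 * spec$gender_sd)
  penalty_narrow <- log_prior(p1, spec) - log_prior(p0, spec)
  penalty_wide <- log_prior(p1, wide) - log_prior(p0, wide)
  expect_gt(penalty_wide, penalty_narrow)
})

test_that("posterior kernel equals an independently coded monolithic density", {
  # monolithic: single pass over all prior terms and all records
  monolithic <- function(data, params, spec) {
    v <- params_to_vector(params)
    lp <- dbeta(v[["p_infant"]], spec$p_infant_shape[1], spec$p_infant_shape[2],
                log = TRUE)
    ic <- solve(spec$ab_cov)
    for (key in c("BaYaka.intra", "BaYaka.inter", "Bandongo.intra", "Bandongo.inter")) {
      ab <- c(v[[paste0("a.", key)]], v[[paste0("b.", key)]]) - spec$ab_mean
      lp <- lp - 0.5 * drop(ab %*% ic %*% ab) -
        0.5 * log(det(2 * pi * spec$ab_cov)) +
        dbeta(v[[paste0("p_adult.", key)]], spec$p_adult_shape[1],
              spec$p_adult_shape[2], log = TRUE) +
        sum(dnorm(c(v[[paste0("a_g.", key)]], v[[paste0("b_g.", key)]],
                    v[[paste0("p_g.", key)]]), 0, spec$gender_sd, log = TRUE))
    }
    lp + oracle_log_likelihood(data, params)
  }
  spec <- prior_spec()
  d <- simulate_trials(default_truth(), scaled_design(10), seed = 17)
  for (s in 1:20) {
    params <- make_random_params(100 + s)
    expect_equal(log_prior(params, spec) + log_likelihood(d, params),
                 monolithic(d, params, spec), tolerance = 1e-10)
  }
})

test_that("prior draws respect truncation and reproduce the (a, b) correlation", {
  spec <- prior_spec()
  draws <- sample_prior(spec, n = 200, seed = 5)
  expect_length(draws, 200L)
  ab <- t(vapply(draws, function(p) {
    cv <- p$curves[["Bandongo.inter"]]
    c(cv$a, cv$b)
  }, numeric(2)))
  expect_true(all(ab > 0))
  expect_identical(length(sample_prior(spec, n = 0, seed = 1)), 0L)
  # determinism
  d2 <- sample_prior(spec, n = 200, seed = 5)
  expect_equal(draws, d2)

  # empirical correlation vs an independent large-sample rejection oracle
  big <- sample_prior(spec, n = 20000, seed = 99)
  ab_big <- t(vapply(big, function(p) {
    cv <- p$curves[["BaYaka.intra"]]
    c(cv$a, cv$b)
  }, numeric(2)))
  emp_cor <- cor(ab_big[, 1], ab_big[, 2])
  set.seed(1234)
  ref <- MASS::mvrnorm(200000, spec$ab_mean, spec$ab_cov)
  ref <- ref[ref[, 1] > 0 & ref[, 2] > 0, ]
  expect_gt(emp_cor, 0)
  expect_lt(abs(emp_cor - cor(ref[, 1], ref[, 2])), 0.03)

  expect_error(prior_spec(ab_cov = rbind(c(1, 2), c(2, 1))),
               "positive-definite")
})

test_that("parameters and prior specs serialize to flat key-value files", {
  params <- make_random_params(12)
  path <- withr::local_tempfile(fileext = ".txt")
  write_params(params, path)
  expect_true(any(grepl("^curve\\.BaYaka\\.intra\\.a:", readLines(path))))
  back <- read_params(path)
  expect_equal(params_to_vector(back), params_to_vector(params),
               tolerance = 1e-15)

  spec <- prior_spec(ab_mean = c(9, 0.3), gender_sd = 1.1)
  spath <- withr::local_tempfile(fileext = ".txt")
  write_prior_spec(spec, spath)
  expect_equal(read_prior_spec(spath), spec, tolerance = 1e-15)
})
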