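# Independent oracles and small fixture builders shared across tests.

# record-by-record Bernoulli log-pmf sum, written without reusing the
# package's vectorized grouping path
oracle_log_likelihood <- function(data, params) {
  total <- 0
  for (i in seq_len(nrow(data))) {
    row <- data[i, ]
    cv <- params$curves[[paste(row$society, row$condition, sep = ".")]]
    z <- if (row$gender == "F") 0.5 else -0.5
    a_eff <- cv$a + z * cv$a_g
    b_eff <- cv$b + z * cv$b_g
    p_ad <- 1 / (1 + exp(-(log(cv$p_adult / (1 - cv$p_adult)) + z * cv$p_g)))
    p <- params$p_infant +
      (p_ad - params$p_infant) / (1 + exp(-b_eff * (row$age_years - a_eff)))
    total <- total + dbinom(row$choice, 1, p, log = TRUE)
  }
  total
}

# exhaustive search over every contiguous window of the sorted sample
oracle_hpdi <- function(samples, mass) {
  s <- sort(samples)
  n <- length(s)
  k <- ceiling(mass * n)
  s <- as.numeric(s)
  if (k >= n) return(c(s[1], s[n]))
  best <- c(Inf, NA, NA)
  for (start in 1:(n - k + 1)) {
    w <- s[start + k - 1] - s[start]
    if (w < best[1]) best <- c(w, s[start], s[start + k - 1])
  }
  c(best[2], best[3])
}

# double loop over categories and lists, straight from the definition of
# Smith's S as the mean inverse percentile rank
oracle_salience <- function(lists) {
  ids <- unique(lists$participant_id)
  cats <- unique(lists$category)
  out <- numeric(length(cats))
  names(out) <- cats
  for (cat_ in cats) {
    acc <- 0
    for (id in ids) {
      sub <- lists[lists$participant_id == id, ]
      L <- nrow(sub)
      r <- sub$rank[sub$category == cat_]
      if (length(r) == 1) acc <- acc + (L - r + 1) / L
    }
    out[cat_] <- acc / length(ids)
  }
  out
}

# a small valid hand-built trial dataset
make_tiny_dataset <- function() {
  trial_dataset(data.frame(
    participant_id = rep(c("p1", "p2", "p3"), each = 2),
    society = rep(c("BaYaka", "Bandongo", "BaYaka"), each = 2),
    gender = rep(c("F", "M", "F"), each = 2),
    age_years = rep(c(7.5, 12, 34), each = 2),
    condition = rep(c("intra", "inter"), 3),
    choice = c(1L, 0L, 0L, 0L, 1L, 1L),
    presentation_order = rep(1:2, 3)))
}

# random but valid model parameters (seeded)
make_random_params <- function(seed) {
  set.seed(seed)
  keys <- c("BaYaka.intra", "BaYaka.inter", "Bandongo.intra", "Bandongo.inter")
  curves <- lapply(keys, function(k) {
    curve_parameters(a = runif(1, 1, 25), b = runif(1, 0.05, 2),
                     p_adult = runif(1, 0.05, 0.95),
                     a_g = rnorm(1, 0, 0.75), b_g = rnorm(1, 0, 0.75),
                     p_g = rnorm(1, 0, 0.75))
  })
  names(curves) <- keys
  model_parameters(runif(1, 0.05, 0.95), curves)
}

# random seeded free-list fixture in long format
make_random_lists <- function(seed, n_lists = 12, n_cats = 8) {
  set.seed(seed)
  cats <- paste0("cat", seq_len(n_cats))
  out <- lapply(seq_len(n_lists), function(i) {
    L <- sample(1:n_cats, 1)
    data.frame(participant_id = sprintf("p%03d", i), society = "BaYaka",
               domain = "intra", rank = seq_len(L),
               category = sample(cats, L), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# fix every scalar except those named, at the values of `at`
fixed_except <- function(free_names, at) {
  v <- params_to_vector(at)
  v[setdiff(names(v), free_names)]
}
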