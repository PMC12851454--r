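# The generative model: logistic developmental curve, Bernoulli likelihood,
# and priors, exposed as pure evaluable functions.

#' Parameters of one developmental curve
#'
#' Each society x condition curve is a logistic transition from the shared
#' infant sharing probability to its own adult probability `p_adult`. `a` is
#' the midpoint age (years; sharing halfway between infant and adult levels),
#' `b` the transition rate (per year). Gender enters additively through
#' offsets: for gender code `z` (+0.5 female, -0.5 male) the effective values
#' are `a + z*a_g`, `b + z*b_g` and `invlogit(logit(p_adult) + z*p_g)`, so the
#' base parameters are the average of the two gender-specific curves.
#'
#' @param a midpoint age, years, > 0.
#' @param b transition rate, per year, > 0.
#' @param p_adult adult sharing probability in (0, 1).
#' @param a_g,b_g,p_g gender offsets (years, per year, logits); unconstrained.
#' @param validate check the constraints (set `FALSE` only to evaluate
#'   densities at out-of-support points).
#' @return list of class `curve_parameters`.
#' @export
curve_parameters <- function(a, b, p_adult, a_g = 0, b_g = 0, p_g = 0,
                             validate = TRUE) {
  out <- list(a = as.numeric(a), b = as.numeric(b), p_adult = as.numeric(p_adult),
              a_g = as.numeric(a_g), b_g = as.numeric(b_g), p_g = as.numeric(p_g))
  if (validate) {
    if (!is.finite(out$a) || out$a <= 0) stop("a must be > 0", call. = FALSE)
    if (!is.finite(out$b) || out$b <= 0) stop("b must be > 0", call. = FALSE)
    if (!is.finite(out$p_adult) || out$p_adult <= 0 || out$p_adult >= 1) {
      stop("p_adult must lie in (0, 1)", call. = FALSE)
    }
  }
  structure(out, class = "curve_parameters")
}

#' Full model parameters
#'
#' The model couples a single infant sharing probability, shared across all
#' four developmental trajectories, with four independently shaped curves,
#' one per society x condition.
#'
#' @param p_infant shared infant sharing probability in (0, 1).
#' @param curves named list of four [curve_parameters()], names
#'   `BaYaka.intra`, `BaYaka.inter`, `Bandongo.intra`, `Bandongo.inter`.
#' @param validate check constraints.
#' @return list of class `model_parameters`.
#' @export
model_parameters <- function(p_infant, curves, validate = TRUE) {
  if (validate) {
    if (!is.finite(p_infant) || p_infant <= 0 || p_infant >= 1) {
      stop("p_infant must lie in (0, 1)", call. = FALSE)
    }
    if (!setequal(names(curves), CURVE_KEYS) || length(curves) != 4L) {
      stop("curves must be named exactly: ", paste(CURVE_KEYS, collapse = ", "),
           call. = FALSE)
    }
    ok <- vapply(curves, inherits, logical(1), what = "curve_parameters")
    if (!all(ok)) stop("all curves must be curve_parameters objects", call. = FALSE)
  }
  structure(list(p_infant = as.numeric(p_infant), curves = curves[CURVE_KEYS]),
            class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat(sprintf("<model_parameters> p_infant = %.3f\n", x$p_infant))
  for (key in names(x$curves)) {
    cv <- x$curves[[key]]
    cat(sprintf("  %-15s a = %6.2f  b = %6.3f  p_adult = %.3f  (a_g %.2f, b_g %.3f, p_g %.2f)\n",
                key, cv$a, cv$b, cv$p_adult, cv$a_g, cv$b_g, cv$p_g))
  }
  invisible(x)
}

#' Prior specification
#'
#' Defaults follow the study model: `p_infant ~ Beta(1.5, 1.5)`,
#' `p_adult ~ Beta(0.75, 0.75)` per curve, a bivariate normal prior on each
#' curve's `(a, b)` with mean `c(10, 0.2)` and covariance
#' `rbind(c(15, 0.75), c(0.75, 0.2))`, truncated to the positive quadrant
#' (the positive correlation encodes that curves starting later also finish
#' faster, keeping acquisition out of adulthood), and `N(0, sd = 0.75)`
#' priors on each gender offset.
#'
#' @param p_infant_shape two Beta shapes for the infant probability.
#' @param p_adult_shape two Beta shapes for each adult probability.
#' @param ab_mean length-2 mean of the (a, b) prior.
#' @param ab_cov 2x2 symmetric positive-definite covariance of (a, b).
#' @param gender_sd standard deviation of the gender-offset normals.
#' @return list of class `prior_spec`.
#' @export
prior_spec <- function(p_infant_shape = c(1.5, 1.5),
                       p_adult_shape = c(0.75, 0.75),
                       ab_mean = c(10, 0.2),
                       ab_cov = rbind(c(15, 0.75), c(0.75, 0.2)),
                       gender_sd = 0.75) {
  ab_cov <- as.matrix(ab_cov)
  if (any(p_infant_shape <= 0) || any(p_adult_shape <= 0)) {
    stop("Beta shapes must be positive", call. = FALSE)
  }
  if (!isTRUE(all.equal(ab_cov, t(ab_cov))) ||
      inherits(try(chol(ab_cov), silent = TRUE), "try-error")) {
    stop("ab_cov must be symmetric positive-definite", call. = FALSE)
  }
  if (gender_sd <= 0) stop("gender_sd must be positive", call. = FALSE)
  structure(list(p_infant_shape = as.numeric(p_infant_shape),
                 p_adult_shape = as.numeric(p_adult_shape),
                 ab_mean = as.numeric(ab_mean), ab_cov = ab_cov,
                 gender_sd = as.numeric(gender_sd)),
            class = "prior_spec")
}

#' Gender code
#'
#' Maps canonical gender labels to the +/- 0.5 code entering the gender
#' offsets: `F` -> +0.5, `M` -> -0.5. The symmetric offset prior makes
#' gender-marginal quantities invariant to this sign convention.
#'
#' @param gender character vector of canonical labels (`F`/`M`).
#' @return numeric vector of +0.5 / -0.5.
#' @export
gender_code <- function(gender) {
  ifelse(gender == "F", 0.5, ifelse(gender == "M", -0.5, NA_real_))
}

#' Gender-adjusted curve parameters
#'
#' @param curve a [curve_parameters()].
#' @param z gender code, +0.5 or -0.5 (vectors allowed).
#' @return list with `a_eff`, `b_eff`, `p_adult_eff`.
#' @examples
#' effective_parameters(curve_parameters(10, 0.3, 0.5, p_g = 2), z = 0.5)
#' @export
effective_parameters <- function(curve, z) {
  list(a_eff = curve$a + z * curve$a_g,
       b_eff = curve$b + z * curve$b_g,
       p_adult_eff = plogis(qlogis(curve$p_adult) + z * curve$p_g))
}

#' Sharing probability at a given age
#'
#' The logistic developmental trajectory
#' `p(x) = p_infant + (p_adult_eff - p_infant) / (1 + exp(-b_eff (x - a_eff)))`.
#'
#' @param age age in years (vectorized).
#' @param p_infant shared infant probability.
#' @param curve a [curve_parameters()].
#' @param z gender code (+0.5/-0.5); `0` gives the gender-averaged base curve.
#' @return probability vector, always between `p_infant` and `p_adult_eff`.
#' @export
sharing_probability <- function(age, p_infant, curve, z = 0) {
  eff <- effective_parameters(curve, z)
  p_infant + (eff$p_adult_eff - p_infant) * plogis(eff$b_eff * (age - eff$a_eff))
}

#' Bernoulli log-likelihood of a trial dataset
#'
#' Sum over records of `choice * log p + (1 - choice) * log(1 - p)` where `p`
#' is the record's [sharing_probability()] under its society/condition curve
#' and gender code. Probabilities are used exactly; a record with `p = 0` and
#' choice GIVE (or `p = 1` and KEEP) yields `-Inf`.
#'
#' @param data a [trial_dataset()].
#' @param params a [model_parameters()].
#' @return scalar log-likelihood (0 for an empty dataset).
#' @export
log_likelihood <- function(data, params) {
  if (nrow(data) == 0L) return(0)
  keys <- curve_key(data$society, data$condition)
  if (!all(keys %in% names(params$curves))) {
    stop("record with society/condition absent from params", call. = FALSE)
  }
  z <- gender_code(data$gender)
  ll <- 0
  for (key in unique(keys)) {
    sel <- keys == key
    p <- sharing_probability(data$age_years[sel], params$p_infant,
                             params$curves[[key]], z[sel])
    y <- data$choice[sel]
    ll <- ll + sum(ifelse(y == 1L, log(p), log1p(-p)))
  }
  ll
}

# bivariate normal log-density (no mvtnorm dependency needed for the 2-D case)
log_dmvnorm2 <- function(x, mean, cov) {
  d <- x - mean
  ic <- solve(cov)
  -0.5 * (d %*% ic %*% d)[1] - 0.5 * determinant(cov, logarithm = TRUE)$modulus[1] -
    log(2 * pi)
}

#' Log prior density (unnormalized)
#'
#' Beta log-densities for the infant and adult probabilities, the
#' untruncated bivariate-normal log-density for each curve's (a, b) -- the
#' positive-quadrant truncation constant is parameter-independent and
#' omitted, so values are comparable across parameters but unnormalized --
#' and normal log-densities for the gender offsets. Returns `-Inf` outside
#' the support (`a <= 0`, `b <= 0`, probabilities outside (0, 1)).
#'
#' @param params a [model_parameters()] (possibly built with
#'   `validate = FALSE` to probe out-of-support points).
#' @param spec a [prior_spec()].
#' @return scalar log prior density, up to an additive constant.
#' @export
log_prior <- function(params, spec = prior_spec()) {
  p_i <- params$p_infant
  if (!is.finite(p_i) || p_i <= 0 || p_i >= 1) return(-Inf)
  lp <- stats::dbeta(p_i, spec$p_infant_shape[1], spec$p_infant_shape[2], log = TRUE)
  for (key in CURVE_KEYS) {
    cv <- params$curves[[key]]
    if (cv$a <= 0 || cv$b <= 0) return(-Inf)
    if (cv$p_adult <= 0 || cv$p_adult >= 1) return(-Inf)
    lp <- lp +
      stats::dbeta(cv$p_adult, spec$p_adult_shape[1], spec$p_adult_shape[2], log = TRUE) +
      log_dmvnorm2(c(cv$a, cv$b), spec$ab_mean, spec$ab_cov) +
      sum(dnorm(c(cv$a_g, cv$b_g, cv$p_g), 0, spec$gender_sd, log = TRUE))
  }
  lp
}

# rejection sampler for the positive-quadrant truncated bivariate normal
rtruncmvn_pos <- function(n, mean, cov) {
  if (inherits(try(chol(cov), silent = TRUE), "try-error")) {
    stop("covariance must be positive-definite", call. = FALSE)
  }
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- max(2 * (n - nrow(out)), 100L)
    draw <- MASS::mvrnorm(m, mu = mean, Sigma = cov)
    keep <- draw[, 1] > 0 & draw[, 2] > 0
    out <- rbind(out, draw[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Draw model parameters from the prior
#'
#' The (a, b) pairs are drawn by rejection from the bivariate normal
#' restricted to the positive quadrant; probabilities from their Beta priors;
#' offsets from the gender normal. Deterministic given `seed`.
#'
#' @param spec a [prior_spec()].
#' @param n number of draws (>= 0).
#' @param seed integer RNG seed.
#' @return list of `n` [model_parameters()].
#' @export
sample_prior <- function(spec = prior_spec(), n, seed = 1L) {
  stopifnot(n >= 0)
  set.seed(seed)
  if (n == 0L) return(list())
  p_inf <- rbeta(n, spec$p_infant_shape[1], spec$p_infant_shape[2])
  per_curve <- lapply(CURVE_KEYS, function(key) {
    ab <- rtruncmvn_pos(n, spec$ab_mean, spec$ab_cov)
    list(a = ab[, 1], b = ab[, 2],
         p_adult = rbeta(n, spec$p_adult_shape[1], spec$p_adult_shape[2]),
         a_g = rnorm(n, 0, spec$gender_sd),
         b_g = rnorm(n, 0, spec$gender_sd),
         p_g = rnorm(n, 0, spec$gender_sd))
  })
  names(per_curve) <- CURVE_KEYS
  lapply(seq_len(n), function(i) {
    curves <- lapply(per_curve, function(pc) {
      curve_parameters(pc$a[i], pc$b[i], pc$p_adult[i],
                       pc$a_g[i], pc$b_g[i], pc$p_g[i])
    })
    model_parameters(p_inf[i], curves)
  })
}

#' Scalar parameter names
#'
#' Canonical order of the model's 25 scalar parameters: `p_infant`, then per
#' curve `a.<key>`, `b.<key>`, `p_adult.<key>`, `a_g.<key>`, `b_g.<key>`,
#' `p_g.<key>`.
#'
#' @return character vector of length 25.
#' @export
scalar_names <- function() {
  c("p_infant",
    unlist(lapply(CURVE_KEYS, function(key) {
      paste(c("a", "b", "p_adult", "a_g", "b_g", "p_g"), key, sep = ".")
    })))
}

#' Flatten / rebuild model parameters
#'
#' `params_to_vector()` returns the named numeric vector in [scalar_names()]
#' order; `vector_to_params()` inverts it.
#'
#' @param params a [model_parameters()].
#' @return named numeric vector of length 25.
#' @export
params_to_vector <- function(params) {
  out <- c(params$p_infant,
           unlist(lapply(params$curves[CURVE_KEYS], function(cv) {
             c(cv$a, cv$b, cv$p_adult, cv$a_g, cv$b_g, cv$p_g)
           })))
  names(out) <- scalar_names()
  out
}

#' @rdname params_to_vector
#' @param x named numeric vector in [scalar_names()] order.
#' @param validate check constraints.
#' @export
vector_to_params <- function(x, validate = TRUE) {
  x <- x[scalar_names()]
  curves <- lapply(seq_along(CURVE_KEYS), function(k) {
    v <- x[1 + 6 * (k - 1) + 1:6]
    curve_parameters(v[1], v[2], v[3], v[4], v[5], v[6], validate = validate)
  })
  names(curves) <- CURVE_KEYS
  model_parameters(x[[1]], curves, validate = validate)
}

#' Serialize parameters or a prior spec to a flat key-value file
#'
#' Plain-text `key: value` lines (keys like `curve.BaYaka.intra.a`), readable
#' back with [read_params()] / [read_prior_spec()].
#'
#' @param params a [model_parameters()].
#' @param path output file path.
#' @export
write_params <- function(params, path) {
  v <- params_to_vector(params)
  # p_infant stays bare; curve scalars become curve.<society>.<condition>.<field>
  keys <- names(v)
  keys[-1] <- vapply(keys[-1], function(k) {
    for (ck in CURVE_KEYS) {
      suffix <- paste0(".", ck)
      if (endsWith(k, suffix)) {
        field <- substr(k, 1L, nchar(k) - nchar(suffix))
        return(paste0("curve.", ck, ".", field))
      }
    }
    k
  }, character(1), USE.NAMES = FALSE)
  writeLines(sprintf("%s: %.17g", keys, v), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- vapply(kv, function(p) trimws(p[1]), character(1))
  vals <- vapply(kv, function(p) as.numeric(trimws(p[2])), numeric(1))
  flat_keys <- vapply(keys, function(k) {
    if (k == "p_infant") return(k)
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]  # curve, soc, cond, field
    paste(parts[4], parts[2], parts[3], sep = ".")
  }, character(1), USE.NAMES = FALSE)
  names(vals) <- flat_keys
  vector_to_params(vals)
}

#' @rdname write_params
#' @param spec a [prior_spec()].
#' @export
write_prior_spec <- function(spec, path) {
  v <- c(p_infant_shape1 = spec$p_infant_shape[1],
         p_infant_shape2 = spec$p_infant_shape[2],
         p_adult_shape1 = spec$p_adult_shape[1],
         p_adult_shape2 = spec$p_adult_shape[2],
         ab_mean_a = spec$ab_mean[1], ab_mean_b = spec$ab_mean[2],
         ab_cov_aa = spec$ab_cov[1, 1], ab_cov_ab = spec$ab_cov[1, 2],
         ab_cov_bb = spec$ab_cov[2, 2], gender_sd = spec$gender_sd)
  writeLines(sprintf("%s: %.17g", names(v), v), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_prior_spec <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, ":", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(p) as.numeric(trimws(p[2])), numeric(1)),
                          vapply(kv, function(p) trimws(p[1]), character(1)))
  prior_spec(p_infant_shape = c(vals[["p_infant_shape1"]], vals[["p_infant_shape2"]]),
             p_adult_shape = c(vals[["p_adult_shape1"]], vals[["p_adult_shape2"]]),
             ab_mean = c(vals[["ab_mean_a"]], vals[["ab_mean_b"]]),
             ab_cov = rbind(c(vals[["ab_cov_aa"]], vals[["ab_cov_ab"]]),
                            c(vals[["ab_cov_ab"]], vals[["ab_cov_bb"]])),
             gender_sd = vals[["gender_sd"]])
}
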