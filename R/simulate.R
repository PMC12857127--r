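#' Ground-truth covariate functions of the simulation study
#'
#' The default pair of nonlinear per-destination probability functions of two
#' covariates. Both share a non-monotonic cubic bump in the second covariate;
#' the first enters through a saturating Hill-type term (destination 2) and a
#' growing exponential (destination 3):
#' \deqn{g_{12}(\varphi) = \tfrac14\Big(\frac{0.5\,\varphi_1^3}{\varphi_1^3 +
#'   0.027} + 5\varphi_2(\varphi_2 - 0.9)(\varphi_2 - 0.8) + 0.05\Big)}
#' \deqn{g_{13}(\varphi) = \tfrac23\Big(e^{\varphi_1^3 + 2\varphi_1 - 4} +
#'   5\varphi_2(\varphi_2 - 0.9)(\varphi_2 - 0.8) + 0.15\Big)}
#' On `[0, 1]^2` both are positive and their sum stays below 1.
#'
#' @return A list of two functions, each mapping an `n x 2` covariate matrix
#'   to a length-`n` probability vector.
#' @export
default_truth_functions <- function() {
  bump <- function(x) 5 * x * (x - 0.9) * (x - 0.8)
  list(
    function(phi) {
      phi <- as.matrix(phi)
      0.25 * (0.5 * phi[, 1]^3 / (phi[, 1]^3 + 0.027) + bump(phi[, 2]) + 0.05)
    },
    function(phi) {
      phi <- as.matrix(phi)
      (2 / 3) * (exp(phi[, 1]^3 + 2 * phi[, 1] - 4) + bump(phi[, 2]) + 0.15)
    })
}

#' Constant ground-truth functions
#'
#' Convenience truth functions that ignore covariates, for parameter-recovery
#' experiments.
#'
#' @param lambdas Numeric vector of per-destination probabilities, sum < 1.
#' @return A list of functions suitable for `truth_functions` in
#'   [simulation_config()].
#' @export
constant_truth <- function(lambdas) {
  probability_row(lambdas)  # validate
  lapply(lambdas, function(l) {
    force(l)
    function(phi) rep(l, nrow(as.matrix(phi)))
  })
}

#' Simulation configuration
#'
#' Describes one synthetic star-topology dataset: all individuals start in
#' the origin state and can move to one of `length(truth_functions)`
#' absorbing destinations; covariates are independent uniforms on
#' `[covariate_low, covariate_high]`; a single proportional error draw per
#' transition perturbs the truth functions for the whole dataset; event times
#' are interval-censored by independent Poisson(1) widenings; and each
#' individual is right-censored with probability `right_censor_prob` at their
#' event time minus a Poisson(1) draw (floored at 0).
#'
#' @param n_individuals Number of individuals to simulate.
#' @param covariate_low,covariate_high Uniform covariate bounds (defaults
#'   0.02, 0.98).
#' @param noise_sd Standard deviation of the dataset-level proportional
#'   error on each transition probability (default 0.05).
#' @param poisson_rate Rate of the Poisson draws widening the observation
#'   interval around the true event time (default 1).
#' @param right_censor_prob Per-individual right-censoring probability
#'   (default 0.5).
#' @param right_censor_poisson_rate Rate of the Poisson draw subtracted from
#'   the event time to form the censoring time (default 1).
#' @param interval_censoring If `TRUE` (default) observed events carry an
#'   interval; if `FALSE` the exact event time is recorded on the
#'   completed-interval scale of the likelihood (trials minus one).
#' @param max_time Hard cap on sampled event times; individuals reaching it
#'   are recorded as right-censored there (default 10000).
#' @param seed RNG seed.
#' @param truth_functions List of per-destination probability functions of
#'   the covariate matrix; default [default_truth_functions()].
#' @param n_covariates Covariate dimension (default 2).
#' @param covariate_sampler Optional `function(n, d)` returning an `n x d`
#'   covariate matrix in `[0, 1]`, replacing the uniform sampler.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_individuals,
                              covariate_low = 0.02, covariate_high = 0.98,
                              noise_sd = 0.05, poisson_rate = 1,
                              right_censor_prob = 0.5,
                              right_censor_poisson_rate = 1,
                              interval_censoring = TRUE,
                              max_time = 10000, seed = NULL,
                              truth_functions = default_truth_functions(),
                              n_covariates = 2,
                              covariate_sampler = NULL) {
  assert_that(n_individuals >= 1, "n_individuals must be >= 1")
  assert_that(covariate_low >= 0 && covariate_low < covariate_high &&
                covariate_high <= 1,
              "need 0 <= covariate_low < covariate_high <= 1")
  assert_that(noise_sd >= 0, "noise_sd must be nonnegative")
  assert_that(right_censor_prob >= 0 && right_censor_prob <= 1,
              "right_censor_prob must be a probability")
  assert_that(is.list(truth_functions) && length(truth_functions) >= 1,
              "truth_functions must be a non-empty list of functions")
  structure(list(n_individuals = as.integer(n_individuals),
                 covariate_low = covariate_low,
                 covariate_high = covariate_high,
                 noise_sd = noise_sd,
                 poisson_rate = poisson_rate,
                 right_censor_prob = right_censor_prob,
                 right_censor_poisson_rate = right_censor_poisson_rate,
                 interval_censoring = isTRUE(interval_censoring),
                 max_time = as.integer(max_time),
                 seed = seed,
                 truth_functions = truth_functions,
                 n_covariates = as.integer(n_covariates),
                 covariate_sampler = covariate_sampler),
            class = "simulation_config")
}

#' Evaluate the ground-truth probability triple
#'
#' @param phi Covariate vector (length d) or `n x d` matrix with entries in
#'   `[0, 1]`.
#' @param truth_functions List of per-destination truth functions; default
#'   [default_truth_functions()].
#' @return For a single covariate vector, a named vector with the
#'   per-destination probabilities and the stay probability (complement); for
#'   a matrix, a data frame with one row per individual.
#' @export
truth_probs <- function(phi, truth_functions = default_truth_functions()) {
  single <- is.null(dim(phi))
  phi <- if (single) matrix(phi, nrow = 1) else as.matrix(phi)
  assert_that(all(phi >= 0 & phi <= 1), "covariates must lie in [0, 1]")
  g <- vapply(truth_functions, function(f) f(phi), numeric(nrow(phi)))
  g <- matrix(g, nrow = nrow(phi))
  stay <- 1 - rowSums(g)
  out <- data.frame(g, stay)
  names(out) <- c(paste0("lambda_", seq_along(truth_functions) + 1), "stay")
  if (single) unlist(out[1, ]) else out
}

#' Apply a dataset-level proportional error to truth probabilities
#'
#' Each transition probability is scaled by `1 + eps` with one error draw per
#' transition shared across all individuals, then clipped so probabilities
#' stay nonnegative and each row's total leaving probability stays below 1;
#' the stay probability is recomputed as the complement.
#'
#' @param g Matrix (`n x N`) of noise-free per-destination probabilities.
#' @param eps Numeric vector of N proportional errors.
#' @return Matrix of perturbed probabilities with attribute `stay`.
#' @export
apply_proportional_noise <- function(g, eps) {
  g <- as.matrix(g)
  assert_that(length(eps) == ncol(g), "need one error per transition")
  lam <- sweep(g, 2, 1 + eps, "*")
  lam[lam < 0] <- 0
  tot <- rowSums(lam)
  over <- tot > 1 - 1e-9
  if (any(over)) {
    lam[over, ] <- lam[over, , drop = FALSE] * ((1 - 1e-9) / tot[over])
  }
  attr(lam, "stay") <- 1 - rowSums(lam)
  lam
}

#' Sample destinations and transition times
#'
#' Each individual repeatedly draws a categorical outcome (stay, or one of
#' the destinations) until leaving the origin; the number of draws is the
#' transition time `k_star` (minimum 1) and the drawn category the
#' destination. The implementation uses the exact closed form — a geometric
#' time with success probability `sum(lambda)` and an independent categorical
#' destination draw — which is distributionally identical. Times exceeding
#' `max_time` are truncated and flagged.
#'
#' @param lambda Matrix (`n x N`) of per-individual destination
#'   probabilities.
#' @param max_time Truncation cap.
#' @return Data frame with `destination_idx` (1..N, `NA` if truncated),
#'   `k_star`, and logical `truncated`.
#' @export
sample_transition_times <- function(lambda, max_time = 10000) {
  lambda <- as.matrix(lambda)
  n <- nrow(lambda)
  p <- rowSums(lambda)
  assert_that(all(p <= 1 + 1e-12) && all(lambda >= 0),
              "invalid probability rows")
  k <- rep(NA_real_, n)
  pos <- p > 0
  k[pos] <- stats::rgeom(sum(pos), p[pos]) + 1
  truncated <- !pos | is.na(k) | k > max_time
  k[truncated] <- max_time
  dest <- rep(NA_integer_, n)
  ok <- which(!truncated)
  if (length(ok)) {
    u <- stats::runif(length(ok)) * p[ok]
    cum <- lambda[ok, , drop = FALSE]
    if (ncol(cum) > 1) {
      for (j in 2:ncol(cum)) cum[, j] <- cum[, j] + cum[, j - 1]
    }
    # destination = first column whose cumulative probability reaches u
    dest[ok] <- pmin(1L + rowSums(cum < u), ncol(lambda))
  }
  data.frame(destination_idx = dest, k_star = k, truncated = truncated)
}

#' Censor sampled event times into observation records
#'
#' With probability `right_censor_prob` an individual is right-censored at
#' `max(k_star - Poisson(rate), 0)`; otherwise the event is kept, either at
#' its exact time or — when `interval_censoring` — inside the interval
#' `(max(k_star - sigma1, 0), k_star + sigma2]` with independent Poisson
#' draws, degenerate intervals widened to `(k_star - 1, k_star]`.
#'
#' @param sampled Data frame from [sample_transition_times()].
#' @param config A [simulation_config()].
#' @return Data frame of observation columns (no covariates yet).
#' @export
censor_observations <- function(sampled, config) {
  n <- nrow(sampled)
  cens <- stats::runif(n) < config$right_censor_prob
  cens <- cens | sampled$truncated
  out <- data.frame(event = as.integer(!cens),
                    destination = NA_integer_,
                    time_kind = "exact",
                    k_star = NA_real_, k1 = NA_real_, k2 = NA_real_,
                    stringsAsFactors = FALSE)
  # right-censored: censor time = event time minus a Poisson draw, >= 0
  drop_draw <- stats::rpois(n, config$right_censor_poisson_rate)
  out$k_star[cens] <- pmax(sampled$k_star[cens] - drop_draw[cens], 0)
  out$k_star[sampled$truncated] <- config$max_time
  ev <- !cens
  out$destination[ev] <- sampled$destination_idx[ev]
  if (config$interval_censoring) {
    s1 <- stats::rpois(n, config$poisson_rate)
    s2 <- stats::rpois(n, config$poisson_rate)
    k1 <- pmax(sampled$k_star - s1, 0)
    k2 <- sampled$k_star + s2
    deg <- k1 >= k2
    k1[deg] <- sampled$k_star[deg] - 1
    k2[deg] <- sampled$k_star[deg]
    out$time_kind[ev] <- "interval"
    out$k1[ev] <- k1[ev]
    out$k2[ev] <- k2[ev]
  } else {
    # Exact recording uses the completed-interval scale of the likelihood:
    # an individual transitioning on trial T survived T - 1 full intervals,
    # so the recorded exact time is T - 1 (pmf lambda * (1 - p)^k, k >= 0).
    # Interval bounds stay on the trial scale, where candidate trial t
    # corresponds to completed time t - 1.
    out$k_star[ev] <- sampled$k_star[ev] - 1
  }
  out
}

#' Generate a complete synthetic dataset
#'
#' Runs the full generator: covariate sampling, dataset-level proportional
#' noise, destination/time sampling, and censoring. Returns both the
#' observation records and the per-individual ground truth (noise-free and
#' noise-applied probabilities), fully reproducible under the config seed.
#'
#' @param config A [simulation_config()].
#' @param epsilon Optional fixed proportional-error vector (one entry per
#'   transition), overriding the random draw — used to share one perturbed
#'   truth between a training and a validation dataset.
#' @return A `simulated_dataset` list with elements `observations`
#'   (a `transition_data`), `truth` (data frame of noise-free `g_*`,
#'   noise-applied `lambda_*`, and `stay` per individual), `epsilon`,
#'   `config`, and `seed`.
#' @export
simulate_dataset <- function(config, epsilon = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  N <- length(config$truth_functions)
  d <- config$n_covariates
  with_seed(config$seed, {
    X <- if (is.null(config$covariate_sampler)) {
      matrix(stats::runif(config$n_individuals * d,
                          config$covariate_low, config$covariate_high),
             ncol = d)
    } else {
      config$covariate_sampler(config$n_individuals, d)
    }
    colnames(X) <- paste0("x", seq_len(d))
    g <- vapply(config$truth_functions, function(f) f(X),
                numeric(config$n_individuals))
    g <- matrix(g, ncol = N)
    assert_that(all(g >= 0) && all(rowSums(g) < 1),
                "truth functions must produce valid probability rows")
    if (is.null(epsilon)) {
      epsilon <- stats::rnorm(N, 0, config$noise_sd)
    }
    lam <- apply_proportional_noise(g, epsilon)
    sampled <- sample_transition_times(lam, config$max_time)
    obs <- censor_observations(sampled, config)
  })

  dest_labels <- seq_len(N) + 1L
  df <- data.frame(id = seq_len(config$n_individuals),
                   origin = 1L,
                   event = obs$event,
                   destination = ifelse(is.na(obs$destination), NA_integer_,
                                        dest_labels[obs$destination]),
                   time_kind = obs$time_kind,
                   k_star = obs$k_star, k1 = obs$k1, k2 = obs$k2)
  df <- cbind(df, as.data.frame(X))
  st <- transition_structure(c(1L, dest_labels), 1L, dest_labels)
  truth <- data.frame(id = df$id, g, lam, 1 - rowSums(lam))
  names(truth) <- c("id",
                    paste0("g_", dest_labels),
                    paste0("lambda_", dest_labels),
                    "stay")
  structure(list(observations = as_transition_data(df,
                                                   covariates = colnames(X),
                                                   structure = st),
                 truth = truth,
                 epsilon = epsilon,
                 config = config,
                 seed = config$seed),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("Simulated star-topology dataset\n")
  cat("  individuals:", nrow(x$truth),
      " right-censored:", sum(x$observations$event == 0), "\n")
  cat("  proportional errors:", format(x$epsilon, digits = 3), "\n")
  invisible(x)
}
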