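# Small builders shared across test files. Fixtures are constructed in code;
# nothing is read from disk.

make_obs_df <- function() {
  data.frame(id = 1:6, origin = 1,
             event = c(1, 1, 0, 1, 1, 0),
             destination = c(2, 3, NA, 2, 3, NA),
             time_kind = c("exact", "exact", "exact",
                           "interval", "interval", "exact"),
             k_star = c(2, 0, 3, NA, NA, 0),
             k1 = c(NA, NA, NA, 0, 2, NA),
             k2 = c(NA, NA, NA, 3, 5, NA),
             x1 = c(0.1, 0.4, 0.9, 0.3, 0.6, 0.5),
             x2 = c(0.8, 0.2, 0.5, 0.7, 0.1, 0.9))
}

make_transition_data <- function() as_transition_data(make_obs_df())

# Constant predictor whose probability row is exactly `lambdas`.
constant_predictor <- function(lambdas, n_covariates = 2) {
  lam <- probability_row(lambdas)
  scores <- log(lam$lambdas / lam$stay)
  predictor("constant", n_destinations = length(lambdas),
            n_covariates = n_covariates, parameters = scores)
}

# Enumerate every outcome of a constant competing-risk row up to horizon T:
# events at completed-interval times 0..T-1 plus censoring at T. Returns a
# data.frame of outcomes with their probabilities (they sum to 1).
enumerate_outcomes <- function(lambdas, T) {
  p <- sum(lambdas)
  rows <- list()
  for (k in 0:(T - 1)) {
    for (d in seq_along(lambdas)) {
      rows[[length(rows) + 1]] <-
        data.frame(event = 1, destination = d, k_star = k,
                   prob = lambdas[d] * (1 - p)^k)
    }
  }
  rows[[length(rows) + 1]] <-
    data.frame(event = 0, destination = NA, k_star = T, prob = (1 - p)^T)
  do.call(rbind, rows)
}
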