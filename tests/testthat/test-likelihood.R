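test_that("survival_prob is the power of the total stay probability", {
  expect_equal(survival_prob(c(0.1, 0.2), 3), 0.7^3)
  expect_equal(survival_prob(c(0.1, 0.2), 0), 1)
  expect_equal(survival_prob(0.5, 2), 0.25)
  expect_error(survival_prob(0.5, -1), "nonnegative")
})

test_that("exact-time log-likelihood matches hand-computed values", {
  expect_equal(loglik_exact(c(0.1, 0.2), k_star = 2, event = 1,
                            destination = 1),
               log(0.1) + 2 * log(0.7), tolerance = 1e-12)
  # censored at time 0 carries no information
  expect_equal(loglik_exact(c(0.1, 0.2), k_star = 0, event = 0), 0)
  # single risk, event with one survived interval
  expect_equal(loglik_exact(0.5, k_star = 1, event = 1, destination = 1),
               log(0.25), tolerance = 1e-12)
  expect_warning(ll <- loglik_exact(c(0, 0.2), 1, 1, 1), "probability 0")
  expect_identical(ll, -Inf)
  expect_error(loglik_exact(c(0.1, 0.2), 1, 1), "destination")
})

test_that("interval log-likelihood telescopes to the survival difference", {
  # single risk closed form: S(k1) - S(k2) with S(k) = (1 - lambda)^k
  expect_equal(loglik_interval(0.5, 1, 1, 2), log(0.5 - 0.25),
               tolerance = 1e-12)
  grid <- expand.grid(lam = c(0.05, 0.3, 0.6, 0.95),
                      k1 = c(0, 1, 4, 10), width = c(1, 2, 7))
  for (i in seq_len(nrow(grid))) {
    lam <- grid$lam[i]; k1 <- grid$k1[i]; k2 <- k1 + grid$width[i]
    # stable form of log[(1-lam)^k1 - (1-lam)^k2]; absolute tolerance, the
    # log-likelihood can itself be arbitrarily close to 0
    closed <- k1 * log(1 - lam) + log1p(-(1 - lam)^(k2 - k1))
    expect_lt(abs(loglik_interval(lam, 1, k1, k2) - closed), 1e-12)
  }
  # competing risks, term-by-term
  expect_equal(loglik_interval(c(0.1, 0.2), 1, 0, 2),
               log(0.1 * 1 + 0.1 * 0.7), tolerance = 1e-12)
  expect_error(loglik_interval(0.5, 1, 2, 2), "k1 < k2")
  expect_warning(ll <- loglik_interval(c(0, 0.2), 1, 0, 2), "no probability")
  expect_identical(ll, -Inf)
})

test_that("an interval covering all times approaches the sub-distribution mass", {
  lam <- c(0.15, 0.25)
  # destination 1 ever: lambda_1 / (lambda_1 + lambda_2), geometric series
  expect_equal(loglik_interval(lam, 1, 0, 2000),
               log(0.15 / 0.4), tolerance = 1e-10)
})

test_that("interval likelihood equals the sum of exact-event masses", {
  # candidate trials k1+1..k2 correspond to completed-interval times
  # k1..k2-1, where the exact-event mass is lambda * stay^k
  set.seed(4)
  for (i in 1:40) {
    lam <- runif(2, 0.01, 0.45); lam <- lam / max(1.2, sum(lam) * 1.5)
    k1 <- sample(0:6, 1); k2 <- k1 + sample(1:5, 1)
    d <- sample(1:2, 1)
    exact <- vapply(k1:(k2 - 1), function(k)
      loglik_exact(lam, k, 1, d), numeric(1))
    expect_equal(loglik_interval(lam, d, k1, k2),
                 log(sum(exp(exact))), tolerance = 1e-10)
  }
})

test_that("event masses and survival conserve total probability", {
  for (lam in list(c(0.3), c(0.1, 0.2), c(0.02, 0.05, 0.4))) {
    for (T in c(1, 5, 60)) {
      mass <- sum(vapply(1:T, function(k)
        sum(lam) * survival_prob(lam, k - 1), numeric(1)))
      expect_lt(abs(mass + survival_prob(lam, T) - 1), 1e-10)
    }
  }
})

test_that("single-risk forms are the N = 1 case of the competing-risk code", {
  for (lam in seq(0.05, 0.95, by = 0.1)) {
    for (k in c(0, 1, 3, 9)) {
      expect_equal(loglik_exact(lam, k, 1, 1),
                   log(lam) + k * log(1 - lam), tolerance = 1e-12)
      expect_equal(loglik_exact(lam, k, 0),
                   k * log(1 - lam), tolerance = 1e-12)
    }
  }
})

test_that("dataset_negloglik sums per-individual contributions", {
  p <- constant_predictor(c(0.1, 0.2))
  one <- as_transition_data(
    data.frame(id = 1, origin = 1, event = 1, destination = 2,
               time_kind = "exact", k_star = 2, k1 = NA, k2 = NA,
               x1 = 0.5, x2 = 0.5),
    structure = transition_structure(1:3, 1, c(2, 3)))
  expect_equal(dataset_negloglik(p, one), -(log(0.1) + 2 * log(0.7)),
               tolerance = 1e-10)
  two <- as_transition_data(rbind(as.data.frame(one), as.data.frame(one)),
                            structure = attr(one, "structure"))
  expect_equal(dataset_negloglik(p, two), 2 * dataset_negloglik(p, one),
               tolerance = 1e-12)
})

test_that("expected negative log-likelihood equals the outcome entropy", {
  lam <- c(0.12, 0.3)
  p <- constant_predictor(lam)
  st <- transition_structure(1:3, 1, c(2, 3))
  out <- enumerate_outcomes(lam, T = 12)
  expect_equal(sum(out$prob), 1, tolerance = 1e-10)
  nll <- vapply(seq_len(nrow(out)), function(i) {
    df <- data.frame(id = 1, origin = 1, event = out$event[i],
                     destination = if (out$event[i] == 1)
                       out$destination[i] + 1L else NA_integer_,
                     time_kind = "exact", k_star = out$k_star[i],
                     k1 = NA, k2 = NA, x1 = 0.5, x2 = 0.5)
    dataset_negloglik(p, as_transition_data(df, structure = st))
  }, numeric(1))
  expect_equal(sum(out$prob * nll), -sum(out$prob * log(out$prob)),
               tolerance = 1e-10)
})

test_that("constant single-risk likelihood peaks at the closed-form MLE", {
  # events at completed times 1 and 3: lambda-hat = D / (D + K) = 1/3
  td <- as_transition_data(
    data.frame(id = 1:2, origin = 1, event = 1, destination = 2,
               time_kind = "exact", k_star = c(1, 3), k1 = NA, k2 = NA,
               x1 = 0.5))
  nll <- function(lam) {
    p <- constant_predictor(lam, n_covariates = 1)
    dataset_negloglik(p, td)
  }
  opt <- optimize(nll, c(0.01, 0.99), tol = 1e-9)
  expect_equal(opt$minimum, 1 / 3, tolerance = 1e-5)
})
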