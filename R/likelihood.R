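#' Discrete-time survival probability under competing transitions
#'
#' Probability that an individual makes no transition out of the origin state
#' during the first `k` intervals, \eqn{(1 - \sum_n \lambda_n)^k}. With a
#' single destination this is the geometric survival function.
#'
#' @param row A [probability_row()] or numeric vector of destination
#'   probabilities.
#' @param k Nonnegative integer time (vectorised).
#' @return Numeric survival probabilities; `survival_prob(row, 0)` is 1.
#' @export
survival_prob <- function(row, k) {
  lam <- as_lambdas(row)
  assert_that(all(k >= 0) && all(k == round(k)),
              "`k` must be a nonnegative integer")
  (1 - sum(lam))^k
}

#' Log-likelihood of an exactly timed observation
#'
#' For an observed transition at discrete time `k_star` to destination `d`,
#' the contribution is \eqn{\log \lambda_d + k^* \log(1 - \sum_n \lambda_n)};
#' for a right-censored individual (`event = 0`) only the survival term
#' remains. A zero-probability observed destination yields `-Inf` with a
#' warning, flagging a degenerate model.
#'
#' @param row A [probability_row()] or numeric lambda vector.
#' @param k_star Nonnegative integer transition or censoring time.
#' @param event 1 if a transition was observed, 0 if censored.
#' @param destination Index (into `row`) of the observed destination;
#'   required iff `event = 1`.
#' @return Scalar log-likelihood.
#' @export
loglik_exact <- function(row, k_star, event = 1, destination = NULL) {
  lam <- as_lambdas(row)
  assert_that(k_star >= 0 && k_star == round(k_star),
              "`k_star` must be a nonnegative integer")
  stay <- 1 - sum(lam)
  surv <- if (k_star == 0) 0 else k_star * log(stay)
  if (event == 0) {
    assert_that(is.null(destination) || is.na(destination),
                "censored observations carry no destination")
    return(surv)
  }
  assert_that(!is.null(destination) && !is.na(destination),
              "an observed event needs a destination")
  assert_that(destination >= 1 && destination <= length(lam),
              "destination index out of range")
  ld <- lam[destination]
  if (ld == 0) {
    warning("observed destination has probability 0: log-likelihood is -Inf")
    return(-Inf)
  }
  log(ld) + surv
}

#' Log-likelihood of an interval-censored observation
#'
#' The transition to `destination` is known to have happened at some time in
#' `(k1, k2]`. The contribution sums the exact-time masses over the candidate
#' times,
#' \deqn{\log \sum_{k = k_1 + 1}^{k_2} \lambda_d \, (1 - \textstyle\sum_n
#'   \lambda_n)^{k - 1},}
#' computed in the log domain through the closed geometric form, which in the
#' single-destination case telescopes exactly to
#' \eqn{\log[(1-\lambda)^{k_1} - (1-\lambda)^{k_2}]}.
#'
#' @param row A [probability_row()] or numeric lambda vector.
#' @param destination Index of the observed destination.
#' @param k1,k2 Integer interval bounds, `0 <= k1 < k2`.
#' @return Scalar log-likelihood; `-Inf` with a warning if the interval
#'   carries no probability mass.
#' @export
loglik_interval <- function(row, destination, k1, k2) {
  lam <- as_lambdas(row)
  assert_that(k1 >= 0 && k1 < k2 && k1 == round(k1) && k2 == round(k2),
              "need integers 0 <= k1 < k2")
  assert_that(destination >= 1 && destination <= length(lam),
              "destination index out of range")
  ld <- lam[destination]
  stay <- 1 - sum(lam)
  if (ld == 0) {
    warning("interval carries no probability mass: log-likelihood is -Inf")
    return(-Inf)
  }
  log(ld) + log_geom_sum(log(stay), k1, k2 - k1)
}

# log( sum_{m=0}^{L-1} q^m ) + a*log(q), with q = exp(log_q) in [0, 1].
# Accurate for q near 1 (result -> log(L)) and q near 0 (result -> a*log q).
log_geom_sum <- function(log_q, a, L) {
  out <- numeric(length(log_q))
  a <- rep_len(a, length(log_q)); L <- rep_len(L, length(log_q))
  one <- log_q >= 0 | L * abs(log_q) < 1e-12
  out[one] <- log(L[one]) + a[one] * log_q[one]
  i <- !one
  if (any(i)) {
    lq <- log_q[i]
    out[i] <- a[i] * lq + log1mexp(L[i] * lq) - log1mexp(lq)
  }
  out
}

# Mean of the survival exponent j over j = a, ..., a+L-1 weighted by q^j;
# the quantity the score gradient of an interval observation needs.
mean_geom_exponent <- function(q, a, L) {
  r <- numeric(length(q))
  a <- rep_len(a, length(q)); L <- rep_len(L, length(q))
  near1 <- (1 - q) < 1e-8
  r[near1] <- a[near1] + (L[near1] - 1) / 2
  i <- !near1
  if (any(i)) {
    qi <- q[i]; Li <- L[i]
    num <- qi * (1 - Li * qi^(Li - 1) + (Li - 1) * qi^Li)
    den <- (1 - qi) * (1 - qi^Li)
    r[i] <- a[i] + ifelse(Li == 1, 0, num / den)
  }
  r
}

# Per-observation log-likelihoods from a lambda matrix + stay vector and
# compiled data. Returns a length-n vector.
loglik_vector <- function(lambda, stay, cd) {
  n <- cd$n
  ll <- numeric(n)
  ex <- !cd$interval
  if (any(ex)) {
    ks <- cd$k_star[ex]
    s <- stay[ex]
    surv <- ifelse(ks == 0, 0, ks * log(s))
    lle <- surv
    evi <- cd$event[ex] == 1
    if (any(evi)) {
      rows <- which(ex)[evi]
      lle[evi] <- lle[evi] + log(lambda[cbind(rows, cd$dest_idx[rows])])
    }
    ll[ex] <- lle
  }
  iv <- cd$interval
  if (any(iv)) {
    rows <- which(iv)
    ld <- lambda[cbind(rows, cd$dest_idx[rows])]
    ll[iv] <- log(ld) + log_geom_sum(log(stay[iv]), cd$a[iv], cd$L[iv])
  }
  ll
}

# Gradient of the per-observation log-likelihood with respect to the score
# matrix: G[i, j] = event_i * 1{j = dest_i} - (event_i + r_i) * lambda[i, j],
# where r_i is the (weighted mean) survival exponent of observation i.
loglik_score_grad <- function(lambda, stay, cd) {
  n <- cd$n
  r <- numeric(n)
  ex <- !cd$interval
  r[ex] <- cd$k_star[ex]
  iv <- cd$interval
  if (any(iv)) {
    r[iv] <- mean_geom_exponent(stay[iv], cd$a[iv], cd$L[iv])
  }
  w <- cd$event + r
  G <- -lambda * w
  evrows <- which(cd$event == 1)
  G[cbind(evrows, cd$dest_idx[evrows])] <-
    G[cbind(evrows, cd$dest_idx[evrows])] + 1
  G
}

#' Total negative log-likelihood of a dataset under a predictor
#'
#' Sums the per-individual contributions (exact, right-censored, and
#' interval-censored) over a [as_transition_data()] dataset, with each
#' individual's probability row produced by the predictor from their
#' covariates. This is the training objective and the validation "loss value".
#'
#' @param predictor A [predictor()].
#' @param data A `transition_data` object.
#' @return Scalar total negative log-likelihood (nats).
#' @export
dataset_negloglik <- function(predictor, data) {
  stopifnot(inherits(predictor, "markov_predictor"))
  cd <- compile_data(data)
  assert_that(cd$n >= 1, "empty dataset")
  assert_that(ncol(cd$X) == predictor$n_covariates,
              "covariate dimension does not match the predictor")
  assert_that(length(cd$structure$destinations) == predictor$n_destinations,
              "destination count does not match the predictor")
  S <- forward_scores(predictor, cd$X)$scores
  lk <- link_matrix(S)
  -sum(loglik_vector(lk$lambda, lk$stay, cd))
}

# Mean NLL over a subset of compiled rows plus its gradient wrt the flat
# parameter vector; used by the trainer.
nll_and_grad <- function(predictor, cd, idx = seq_len(cd$n)) {
  sub <- list(X = cd$X[idx, , drop = FALSE],
              n = length(idx),
              event = cd$event[idx],
              dest_idx = cd$dest_idx[idx],
              interval = cd$interval[idx],
              k_star = cd$k_star[idx],
              a = cd$a[idx],
              L = cd$L[idx],
              structure = cd$structure)
  fw <- forward_scores(predictor, sub$X)
  lk <- link_matrix(fw$scores)
  nll <- -mean(loglik_vector(lk$lambda, lk$stay, sub))
  G <- -loglik_score_grad(lk$lambda, lk$stay, sub) / sub$n
  list(value = nll, grad = backward_scores(predictor, fw, G))
}
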