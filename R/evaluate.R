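#' State occupation by the Chapman-Kolmogorov equation
#'
#' Propagates an initial state distribution `t` steps through a one-step
#' transition matrix: \eqn{\pi(t) = \pi_0 P^t}.
#'
#' @param P Square row-stochastic matrix.
#' @param pi0 Initial probability vector.
#' @param t Nonnegative integer number of steps.
#' @return Occupation probability vector at time `t`.
#' @export
occupation <- function(P, pi0, t) {
  P <- as.matrix(P)
  assert_that(nrow(P) == ncol(P), "P must be square")
  assert_that(all(abs(rowSums(P) - 1) < 1e-8) && all(P >= -1e-12),
              "P must be row-stochastic")
  assert_that(length(pi0) == nrow(P) && abs(sum(pi0) - 1) < 1e-8 &&
                all(pi0 >= 0), "pi0 must be a probability vector")
  assert_that(t >= 0 && t == round(t), "t must be a nonnegative integer")
  v <- matrix(pi0, nrow = 1)
  for (i in seq_len(t)) v <- v %*% P
  as.numeric(v)
}

#' Brier score of one individual at one time
#'
#' Squared distance between the predicted occupation vector and the one-hot
#' observed state occupation.
#'
#' @param pi Predicted occupation probability vector.
#' @param observed_state Index of the observed state.
#' @return Scalar score in `[0, 2]`.
#' @export
brier_individual <- function(pi, observed_state) {
  assert_that(observed_state >= 1 && observed_state <= length(pi),
              "observed state out of range")
  sigma <- numeric(length(pi))
  sigma[observed_state] <- 1
  sum((pi - sigma)^2)
}

#' Brier score of an interval-censored individual
#'
#' Averages the Brier score at the evaluation horizon over the candidate
#' transition times in `(k1, k2]`: for a candidate time at or before the
#' horizon the individual is observed in the destination at the horizon,
#' for later candidates still in the origin state. The mean is over the
#' `k2 - k1` candidates.
#'
#' @param P Individual one-step transition matrix.
#' @param pi0 Initial distribution.
#' @param k1,k2 Integer interval bounds, `k1 < k2`.
#' @param destination Index (state) of the observed destination.
#' @param origin Index of the origin state (default 1).
#' @param horizon Evaluation time (default 5).
#' @return Scalar averaged Brier score.
#' @export
brier_interval <- function(P, pi0, k1, k2, destination, origin = 1,
                           horizon = 5) {
  assert_that(k1 < k2 && k1 == round(k1) && k2 == round(k2),
              "need integers k1 < k2")
  pi_h <- occupation(P, pi0, horizon)
  scores <- vapply((k1 + 1):k2, function(k) {
    brier_individual(pi_h, if (k <= horizon) destination else origin)
  }, numeric(1))
  mean(scores)
}

# Occupation at `horizon` for every individual of a star model, closed form:
# pi_origin = stay^h, pi_dest_n = lambda_n * (1 - stay^h) / (1 - stay).
star_occupation <- function(lambda, stay, horizon) {
  sh <- stay^horizon
  fac <- ifelse(stay < 1, (1 - sh) / (1 - stay), horizon)
  cbind(sh, lambda * fac)
}

#' Dataset Brier score at an evaluation horizon
#'
#' Mean over individuals of the squared distance between the predicted state
#' occupation at `horizon` (Chapman-Kolmogorov propagation of each
#' individual's predicted transition matrix from the origin) and the observed
#' occupation. Interval-censored events are averaged over their candidate
#' transition times; right-censored individuals whose censoring time is
#' before the horizon have an unknown state there and are excluded by
#' default (set `include_unknown = TRUE` to score them at their last known
#' state, the origin).
#'
#' @param predictor A [predictor()].
#' @param data A `transition_data` dataset.
#' @param horizon Evaluation time (default 5).
#' @param include_unknown Score individuals censored before the horizon as
#'   remaining in the origin (default `FALSE`, excluded).
#' @return List with `brier` (mean score) and `n_used`.
#' @export
brier_score <- function(predictor, data, horizon = 5,
                        include_unknown = FALSE) {
  cd <- compile_data(data)
  lk <- link_matrix(forward_scores(predictor, cd$X)$scores)
  occ <- star_occupation(lk$lambda, lk$stay, horizon)  # origin first
  n <- cd$n
  N <- ncol(lk$lambda)
  score <- rep(NA_real_, n)

  base <- rowSums(occ^2)  # sum pi^2; BS for observed state s is base - 2*pi_s + 1
  bs_at <- function(i, state_col) base[i] - 2 * occ[cbind(i, state_col)] + 1

  ex <- which(!cd$interval & cd$event == 1)
  if (length(ex)) {
    # exact times count completed intervals: the transition happens during
    # interval k_star + 1, so the individual is absorbed by `horizon` iff
    # k_star < horizon
    col <- ifelse(cd$k_star[ex] < horizon, cd$dest_idx[ex] + 1L, 1L)
    score[ex] <- bs_at(ex, col)
  }
  cens <- which(cd$event == 0)
  if (length(cens)) {
    known <- cd$k_star[cens] >= horizon
    score[cens[known]] <- bs_at(cens[known], 1L)
    if (include_unknown) {
      score[cens[!known]] <- bs_at(cens[!known], 1L)
    }
  }
  iv <- which(cd$interval)
  if (length(iv)) {
    # candidate k <= horizon -> destination; later -> origin. Count each.
    a <- cd$a[iv]; b <- a + cd$L[iv]
    n_dest <- pmax(pmin(b, horizon) - a, 0)        # candidates in (a, min(b,h)]
    n_orig <- cd$L[iv] - n_dest
    bs_dest <- bs_at(iv, cd$dest_idx[iv] + 1L)
    bs_orig <- bs_at(iv, 1L)
    score[iv] <- (n_dest * bs_dest + n_orig * bs_orig) / cd$L[iv]
  }
  used <- !is.na(score)
  list(brier = mean(score[used]), n_used = sum(used))
}

#' Per-transition mean squared error against simulation truth
#'
#' Mean over individuals of the squared difference between the noise-applied
#' generating probability and the predicted probability, for the stay
#' probability and each destination.
#'
#' @param truth A `simulated_dataset` from [simulate_dataset()].
#' @param predictor A [predictor()].
#' @return Named numeric vector (`lambda_11`-style names built from the
#'   structure's state labels).
#' @export
mse_transitions <- function(truth, predictor) {
  stopifnot(inherits(truth, "simulated_dataset"))
  data <- truth$observations
  st <- attr(data, "structure")
  pred <- predict_probs(predictor, data)
  assert_that(nrow(pred) == nrow(truth$truth) &&
                all(data$id == truth$truth$id),
              "truth and observations are misaligned")
  true_cols <- c("stay", paste0("lambda_", st$destinations))
  tm <- as.matrix(truth$truth[, true_cols])
  err <- colMeans((tm - pred)^2)
  names(err) <- c(paste0("lambda_", st$origin, st$origin),
                  paste0("lambda_", st$origin, st$destinations))
  err
}

#' Evaluate a fitted predictor on a validation dataset
#'
#' Computes the validation negative log-likelihood (same interval-censored
#' likelihood as training), the Brier score at the horizon, and — when
#' simulation truth is supplied — the per-transition MSE.
#'
#' @param predictor A fitted [predictor()].
#' @param data A `transition_data` validation dataset, or a
#'   `simulated_dataset` (whose truth then feeds the MSE).
#' @param horizon Brier evaluation time (default 5).
#' @param include_unknown Passed to [brier_score()].
#' @return An `evaluation_report` list with `negloglik`, `brier`,
#'   `brier_n`, `mse` (or `NULL`), `n_individuals`, `horizon`, `model`.
#' @export
evaluate_model <- function(predictor, data, horizon = 5,
                           include_unknown = FALSE) {
  truth <- NULL
  if (inherits(data, "simulated_dataset")) {
    truth <- data
    data <- data$observations
  }
  bs <- brier_score(predictor, data, horizon, include_unknown)
  structure(list(negloglik = dataset_negloglik(predictor, data),
                 brier = bs$brier,
                 brier_n = bs$n_used,
                 mse = if (!is.null(truth)) mse_transitions(truth, predictor),
                 n_individuals = nrow(data),
                 horizon = horizon,
                 model = predictor$kind),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation report (", x$model, " model, n = ", x$n_individuals,
      ")\n", sep = "")
  cat("  NLL:  ", format(x$negloglik, digits = 7), "\n")
  cat("  Brier(t=", x$horizon, "): ", format(x$brier, digits = 5),
      " over ", x$brier_n, " individuals\n", sep = "")
  if (!is.null(x$mse)) {
    cat("  MSE: ", paste(names(x$mse), format(x$mse, digits = 4),
                         sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Pairwise model comparison across replicate datasets
#'
#' For each replicate, subtracts the ANN model's metric from each reference
#' model's metric (loss, per-transition MSE, Brier); positive differences
#' mean the ANN performed better. Across replicates the median and 2.5/97.5
#' percentiles are reported.
#'
#' @param replicates List of replicates; each replicate is a named list of
#'   `evaluation_report`s containing at least the element named in `ann`.
#' @param ann Name of the ANN (baseline) model in each replicate
#'   (default `"ann"`).
#' @return A `delta_report` data frame with columns `metric`, `reference`,
#'   `median`, `lower`, `upper`.
#' @export
compare_models <- function(replicates, ann = "ann") {
  assert_that(length(replicates) >= 1, "need at least one replicate")
  refs <- setdiff(names(replicates[[1]]), ann)
  assert_that(length(refs) >= 1 && ann %in% names(replicates[[1]]),
              "each replicate needs the ANN model and at least one reference")
  metric_vec <- function(rep) {
    c(loss = rep$negloglik,
      if (!is.null(rep$mse)) stats::setNames(rep$mse,
                                             paste0("mse_", names(rep$mse))),
      brier = rep$brier)
  }
  rows <- list()
  for (ref in refs) {
    deltas <- vapply(replicates, function(r) {
      assert_that(all(c(ref, ann) %in% names(r)),
                  "replicates carry different model sets")
      metric_vec(r[[ref]]) - metric_vec(r[[ann]])
    }, metric_vec(replicates[[1]][[ref]]))
    deltas <- matrix(deltas, ncol = length(replicates),
                     dimnames = list(names(metric_vec(replicates[[1]][[ref]]))))
    rows[[ref]] <- data.frame(
      metric = rownames(deltas),
      reference = ref,
      median = apply(deltas, 1, stats::median),
      lower = apply(deltas, 1, stats::quantile, probs = 0.025),
      upper = apply(deltas, 1, stats::quantile, probs = 0.975),
      row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("delta_report", class(out))
  out
}

#' @export
print.delta_report <- function(x, ...) {
  cat("Model comparison (reference minus ANN; positive favours the ANN)\n")
  y <- as.data.frame(x)
  y$median <- signif(y$median, 4)
  y$lower <- signif(y$lower, 4)
  y$upper <- signif(y$upper, 4)
  print(y)
  invisible(x)
}

#' Run the full simulation comparison study
#'
#' Generates replicate training/validation dataset pairs with the synthetic
#' generator (each pair shares its dataset-level proportional-error draw, so
#' both describe the same perturbed population), fits the requested models on
#' each training set, and evaluates them on the matching validation set.
#'
#' @param n_replicates Number of replicate pairs (default 3).
#' @param n_train,n_validation Individuals per training / validation dataset
#'   (defaults 3000 and 1000).
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param models Character subset of `c("constant", "linear", "ann")`.
#' @param hidden ANN hidden-layer widths (default `c(50, 50)`).
#' @param config A [train_config()] shared by all fits (its seed is
#'   re-derived per replicate and model).
#' @param sim_args Extra arguments passed to [simulation_config()].
#' @param horizon Brier evaluation time (default 5).
#' @return List with `replicates` (per-replicate named lists of
#'   `evaluation_report`s), `deltas` (a [compare_models()] report when the
#'   ANN was fitted), and `fits` of the last replicate.
#' @export
replicate_study <- function(n_replicates = 3, n_train = 3000,
                            n_validation = 1000, seed = 1,
                            models = c("constant", "linear", "ann"),
                            hidden = c(50, 50),
                            config = train_config(),
                            sim_args = list(), horizon = 5) {
  sub_seeds <- with_seed(seed, matrix(sample.int(2^31 - 1,
                                                 n_replicates * (2 + length(models))),
                                      nrow = n_replicates))
  replicates <- vector("list", n_replicates)
  fits <- NULL
  for (r in seq_len(n_replicates)) {
    tr_cfg <- do.call(simulation_config,
                      c(list(n_individuals = n_train,
                             seed = sub_seeds[r, 1]), sim_args))
    train_ds <- simulate_dataset(tr_cfg)
    va_cfg <- do.call(simulation_config,
                      c(list(n_individuals = n_validation,
                             seed = sub_seeds[r, 2]), sim_args))
    val_ds <- simulate_dataset(va_cfg, epsilon = train_ds$epsilon)

    reports <- list()
    fits <- list()
    for (m in seq_along(models)) {
      kind <- models[m]
      fit_seed <- sub_seeds[r, 2 + m]
      p0 <- predictor(kind,
                      n_destinations = length(tr_cfg$truth_functions),
                      n_covariates = tr_cfg$n_covariates,
                      hidden = hidden, seed = fit_seed)
      cfg <- config
      cfg$seed <- fit_seed
      fit <- train_predictor(p0, train_ds$observations, cfg)
      fits[[kind]] <- fit
      reports[[kind]] <- evaluate_model(fit$predictor, val_ds,
                                        horizon = horizon)
    }
    replicates[[r]] <- reports
  }
  list(replicates = replicates,
       deltas = if ("ann" %in% models && length(models) > 1) {
         compare_models(replicates, ann = "ann")
       },
       fits = fits)
}
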