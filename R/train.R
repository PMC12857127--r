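#' Training configuration
#'
#' @param batch_size Individuals per minibatch (default 128).
#' @param iterations Number of ADAM steps (default 500); each step consumes
#'   one minibatch.
#' @param learning_rate ADAM base step size (default 0.05; see the methods
#'   vignette for how this default was chosen).
#' @param lr_schedule `"cosine"` (default) anneals the step size from
#'   `learning_rate` to 0 over the run, removing end-stage minibatch
#'   oscillation so short runs finish at their optimum; `"constant"` keeps
#'   it fixed.
#' @param weight_decay Optional L2 penalty coefficient added to the gradient
#'   (default 0; off).
#' @param seed RNG seed controlling batch shuffling (default 1).
#' @param shuffle Reshuffle individuals at each pass through the data
#'   (default `TRUE`).
#' @param trace_every If positive, emit a log line with the batch NLL every
#'   this many steps.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 128, iterations = 500,
                         learning_rate = 0.05,
                         lr_schedule = c("cosine", "constant"),
                         weight_decay = 0,
                         seed = 1, shuffle = TRUE, trace_every = 0) {
  assert_that(batch_size >= 1, "batch_size must be >= 1")
  assert_that(iterations >= 1, "iterations must be >= 1")
  assert_that(learning_rate > 0, "learning_rate must be positive")
  assert_that(weight_decay >= 0, "weight_decay must be nonnegative")
  structure(list(batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations),
                 learning_rate = learning_rate,
                 lr_schedule = match.arg(lr_schedule),
                 weight_decay = weight_decay,
                 seed = seed,
                 shuffle = isTRUE(shuffle),
                 trace_every = as.integer(trace_every)),
            class = "train_config")
}

#' Fit a predictor by minibatch likelihood maximisation
#'
#' Runs ADAM (beta1 = 0.9, beta2 = 0.999, eps = 1e-8) on the per-individual
#' mean negative log-likelihood of minibatches drawn without replacement:
#' individuals are shuffled, partitioned sequentially into batches of
#' `batch_size` (the last short batch is kept), and reshuffled once
#' exhausted. Runs are bitwise reproducible under a fixed seed; the caller's
#' RNG state is untouched.
#'
#' @param predictor A [predictor()] providing the initial parameters.
#' @param data A `transition_data` dataset.
#' @param config A [train_config()].
#' @return A `train_result` with elements `predictor` (fitted), `loss_trace`
#'   (batch mean NLL per step, length `iterations`), `final_nll` (total
#'   negative log-likelihood on the full dataset at the fitted parameters),
#'   and `config`.
#' @export
train_predictor <- function(predictor, data, config = train_config()) {
  stopifnot(inherits(predictor, "markov_predictor"),
            inherits(config, "train_config"))
  cd <- compile_data(data)
  assert_that(cd$n >= 1, "empty dataset")
  assert_that(ncol(cd$X) == predictor$n_covariates,
              "covariate dimension does not match the predictor")
  theta <- predictor$parameters
  m <- numeric(length(theta)); v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  trace <- numeric(config$iterations)

  with_seed(config$seed, {
    order_idx <- if (config$shuffle) sample.int(cd$n) else seq_len(cd$n)
    cursor <- 0L
    for (step in seq_len(config$iterations)) {
      if (cursor >= cd$n) {
        order_idx <- if (config$shuffle) sample.int(cd$n) else seq_len(cd$n)
        cursor <- 0L
      }
      idx <- order_idx[(cursor + 1L):min(cursor + config$batch_size, cd$n)]
      cursor <- cursor + length(idx)

      predictor$parameters <- theta
      ng <- nll_and_grad(predictor, cd, idx)
      if (!is.finite(ng$value) || !all(is.finite(ng$grad))) {
        stop("non-finite loss or gradient at training step ", step,
             " (batch NLL = ", format(ng$value),
             "); check for degenerate observations", call. = FALSE)
      }
      g <- ng$grad
      if (config$weight_decay > 0) g <- g + config$weight_decay * theta
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      mhat <- m / (1 - b1^step)
      vhat <- v / (1 - b2^step)
      lr_t <- if (config$lr_schedule == "cosine") {
        lr * 0.5 * (1 + cos(pi * (step - 1) / config$iterations))
      } else lr
      theta <- theta - lr_t * mhat / (sqrt(vhat) + eps)
      trace[step] <- ng$value
      if (config$trace_every > 0 && step %% config$trace_every == 0) {
        message(sprintf("step %d/%d batch NLL %.4f",
                        step, config$iterations, ng$value))
      }
    }
  })

  predictor$parameters <- theta
  structure(list(predictor = predictor,
                 loss_trace = trace,
                 final_nll = dataset_negloglik(predictor, data),
                 config = config),
            class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  cat("Fitted", x$predictor$kind, "Markov predictor\n")
  cat("  steps:", length(x$loss_trace),
      " final batch NLL:", format(utils::tail(x$loss_trace, 1), digits = 5), "\n")
  cat("  full-data NLL:", format(x$final_nll, digits = 7), "\n")
  invisible(x)
}
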