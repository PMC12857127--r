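#' Covariate-to-score predictors for transition probabilities
#'
#' Builds one of the three mappings from an individual's covariate vector to
#' the pre-link scores of the competing destinations:
#' \describe{
#'   \item{`constant`}{one free score per destination, covariates ignored;}
#'   \item{`linear`}{an affine map (intercept + weights) per destination;}
#'   \item{`ann`}{a multilayer perceptron, by default two hidden layers of 50
#'     units with swish activation (`x * sigmoid(x)`), either one shared
#'     network with one output unit per destination (default) or fully
#'     separate networks per destination.}
#' }
#' Scores feed [link()], so transition probabilities of one row are always
#' modeled jointly. Covariates are assumed pre-scaled to `[0, 1]`.
#'
#' @param kind One of `"constant"`, `"linear"`, `"ann"`.
#' @param n_destinations Number of competing destinations N.
#' @param n_covariates Covariate dimension d.
#' @param hidden Integer vector of hidden-layer widths (ANN only).
#' @param activation Hidden activation, `"swish"` (default) or `"tanh"`.
#' @param shared_trunk If `TRUE` (default) one network with N outputs; if
#'   `FALSE`, N separate single-output networks.
#' @param parameters Optional flat numeric parameter vector; defaults to
#'   [init_parameters()].
#' @param seed Seed for the random ANN initialisation.
#' @return An object of class `markov_predictor`.
#' @export
predictor <- function(kind = c("constant", "linear", "ann"),
                      n_destinations, n_covariates,
                      hidden = c(50, 50), activation = "swish",
                      shared_trunk = TRUE, parameters = NULL, seed = NULL) {
  kind <- match.arg(kind)
  assert_that(n_destinations >= 1, "need at least one destination")
  assert_that(n_covariates >= 0, "negative covariate dimension")
  assert_that(activation %in% c("swish", "tanh"), "unknown activation")
  p <- structure(list(kind = kind,
                      n_destinations = as.integer(n_destinations),
                      n_covariates = as.integer(n_covariates),
                      hidden = as.integer(hidden),
                      activation = activation,
                      shared_trunk = isTRUE(shared_trunk),
                      parameters = NULL),
                 class = "markov_predictor")
  p$layout <- parameter_layout(p)
  expected <- sum(vapply(p$layout, function(l) prod(l$dim), numeric(1)))
  if (is.null(parameters)) {
    parameters <- init_parameters(kind, n_destinations, n_covariates,
                                  hidden = hidden, seed = seed,
                                  shared_trunk = shared_trunk)
  }
  assert_that(length(parameters) == expected,
              sprintf("expected %d parameters, got %d",
                      expected, length(parameters)))
  assert_that(all(is.finite(parameters)), "parameters must be finite")
  p$parameters <- as.numeric(parameters)
  p
}

#' @export
print.markov_predictor <- function(x, ...) {
  cat("Markov transition predictor (", x$kind, ")\n", sep = "")
  cat("  destinations:", x$n_destinations,
      " covariates:", x$n_covariates, "\n")
  if (x$kind == "ann") {
    cat("  architecture:", paste(c(x$n_covariates, x$hidden), collapse = "-"),
        "-", x$n_destinations, ", ", x$activation,
        if (x$shared_trunk) ", shared trunk" else ", separate networks",
        "\n", sep = "")
  }
  cat("  parameters:", length(x$parameters), "\n")
  invisible(x)
}

# Deterministic flat layout: list of (name, dim) blocks in parameter order.
parameter_layout <- function(p) {
  N <- p$n_destinations; d <- p$n_covariates
  switch(p$kind,
    constant = list(list(name = "theta", dim = N)),
    linear = list(list(name = "W", dim = c(d + 1L, N))),
    ann = {
      mlp <- function(sizes, tag) {
        out <- list()
        for (l in seq_len(length(sizes) - 1)) {
          out[[length(out) + 1]] <- list(name = sprintf("%sW%d", tag, l),
                                         dim = c(sizes[l], sizes[l + 1]))
          out[[length(out) + 1]] <- list(name = sprintf("%sb%d", tag, l),
                                         dim = sizes[l + 1])
        }
        out
      }
      if (p$shared_trunk) {
        mlp(c(d, p$hidden, N), "")
      } else {
        do.call(c, lapply(seq_len(N), function(n)
          mlp(c(d, p$hidden, 1L), sprintf("net%d.", n))))
      }
    })
}

unpack_parameters <- function(p) {
  out <- list(); pos <- 0L
  for (blk in p$layout) {
    len <- prod(blk$dim)
    v <- p$parameters[pos + seq_len(len)]
    out[[blk$name]] <- if (length(blk$dim) == 2) {
      matrix(v, blk$dim[1], blk$dim[2])
    } else v
    pos <- pos + len
  }
  out
}

pack_gradient <- function(p, grads) {
  unlist(lapply(p$layout, function(blk) as.numeric(grads[[blk$name]])),
         use.names = FALSE)
}

#' Initialise predictor parameters
#'
#' Constant and linear predictors start at zero, so every initial probability
#' row is uniform over its outcomes. ANN weights use Glorot (fan-based)
#' uniform draws with zero biases, reproducible under `seed`.
#'
#' @inheritParams predictor
#' @return Flat numeric parameter vector.
#' @export
init_parameters <- function(kind, n_destinations, n_covariates,
                            hidden = c(50, 50), seed = NULL,
                            shared_trunk = TRUE) {
  skel <- structure(list(kind = kind, n_destinations = as.integer(n_destinations),
                         n_covariates = as.integer(n_covariates),
                         hidden = as.integer(hidden),
                         shared_trunk = isTRUE(shared_trunk)),
                    class = "markov_predictor")
  layout <- parameter_layout(skel)
  if (kind != "ann") {
    return(numeric(sum(vapply(layout, function(l) prod(l$dim), numeric(1)))))
  }
  with_seed(seed, {
    unlist(lapply(layout, function(blk) {
      if (length(blk$dim) == 2) {
        lim <- sqrt(6 / (blk$dim[1] + blk$dim[2]))
        stats::runif(prod(blk$dim), -lim, lim)
      } else {
        numeric(blk$dim)
      }
    }), use.names = FALSE)
  })
}

act_fun <- function(name) {
  switch(name,
    swish = list(f = function(x) x * stats::plogis(x),
                 df = function(x) {
                   s <- stats::plogis(x)
                   s * (1 + x * (1 - s))
                 }),
    tanh = list(f = tanh, df = function(x) 1 - tanh(x)^2))
}

mlp_forward <- function(X, W, b, act) {
  L <- length(W)
  pre <- vector("list", L); post <- vector("list", L)
  H <- X
  for (l in seq_len(L)) {
    Z <- H %*% W[[l]]
    Z <- sweep(Z, 2, b[[l]], "+")
    pre[[l]] <- Z
    H <- if (l < L) act$f(Z) else Z
    post[[l]] <- H
  }
  list(out = H, pre = pre, post = post, X = X)
}

mlp_backward <- function(fw, W, act, Gout) {
  L <- length(W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- Gout
  for (l in rev(seq_len(L))) {
    if (l < L) delta <- delta * act$df(fw$pre[[l]])
    H_in <- if (l == 1) fw$X else fw$post[[l - 1]]
    gW[[l]] <- crossprod(H_in, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) delta <- delta %*% t(W[[l]])
  }
  list(gW = gW, gb = gb)
}

# Forward pass: n x d covariate matrix -> n x N score matrix (+ caches).
forward_scores <- function(p, X) {
  X <- as.matrix(X)
  n <- nrow(X)
  assert_that(ncol(X) == p$n_covariates, "covariate dimension mismatch")
  assert_that(all(is.finite(X)), "covariates must be finite")
  par <- unpack_parameters(p)
  switch(p$kind,
    constant = list(scores = matrix(par$theta, n, p$n_destinations,
                                    byrow = TRUE)),
    linear = list(scores = cbind(1, X) %*% par$W, X = X),
    ann = {
      act <- act_fun(p$activation)
      nW <- length(p$hidden) + 1L
      if (p$shared_trunk) {
        W <- lapply(seq_len(nW), function(l) par[[sprintf("W%d", l)]])
        b <- lapply(seq_len(nW), function(l) par[[sprintf("b%d", l)]])
        fw <- mlp_forward(X, W, b, act)
        list(scores = fw$out, fw = fw, W = W)
      } else {
        nets <- lapply(seq_len(p$n_destinations), function(nn) {
          W <- lapply(seq_len(nW), function(l) par[[sprintf("net%d.W%d", nn, l)]])
          b <- lapply(seq_len(nW), function(l) par[[sprintf("net%d.b%d", nn, l)]])
          fw <- mlp_forward(X, W, b, act)
          list(fw = fw, W = W)
        })
        scores <- do.call(cbind, lapply(nets, function(nt) nt$fw$out))
        list(scores = scores, nets = nets)
      }
    })
}

# Backward pass: gradient of a scalar loss wrt scores (n x N) -> flat
# gradient wrt parameters, in layout order.
backward_scores <- function(p, fwd, Gscores) {
  switch(p$kind,
    constant = colSums(Gscores),
    linear = as.numeric(crossprod(cbind(1, fwd$X), Gscores)),
    ann = {
      act <- act_fun(p$activation)
      if (p$shared_trunk) {
        bk <- mlp_backward(fwd$fw, fwd$W, act, Gscores)
        unlist(lapply(seq_along(bk$gW), function(l)
          c(as.numeric(bk$gW[[l]]), bk$gb[[l]])), use.names = FALSE)
      } else {
        unlist(lapply(seq_len(p$n_destinations), function(nn) {
          bk <- mlp_backward(fwd$nets[[nn]]$fw, fwd$nets[[nn]]$W, act,
                             Gscores[, nn, drop = FALSE])
          unlist(lapply(seq_along(bk$gW), function(l)
            c(as.numeric(bk$gW[[l]]), bk$gb[[l]])), use.names = FALSE)
        }), use.names = FALSE)
      }
    })
}

#' Predict transition probabilities for a covariate matrix
#'
#' @param predictor A [predictor()].
#' @param newdata Numeric covariate matrix (one row per individual, values in
#'   the scale used for training) or a `transition_data` object.
#' @return Matrix with one row per individual: first column `stay`, then one
#'   column per destination.
#' @export
predict_probs <- function(predictor, newdata) {
  X <- if (inherits(newdata, "transition_data")) {
    covariate_matrix(newdata)
  } else as.matrix(newdata)
  lk <- link_matrix(forward_scores(predictor, X)$scores)
  st <- if (inherits(newdata, "transition_data")) {
    attr(newdata, "structure")
  } else NULL
  out <- cbind(lk$stay, lk$lambda)
  colnames(out) <- c("stay",
                     if (!is.null(st)) paste0("dest_", st$destinations)
                     else paste0("dest_", seq_len(predictor$n_destinations)))
  out
}

#' Predict one probability row
#'
#' @param predictor A [predictor()].
#' @param covariates Numeric covariate vector of length `n_covariates`.
#' @return A [probability_row()].
#' @export
predict_row <- function(predictor, covariates) {
  assert_that(length(covariates) == predictor$n_covariates,
              "covariate dimension mismatch")
  S <- forward_scores(predictor, matrix(covariates, nrow = 1))$scores
  link(as.numeric(S))
}

#' Save / load a fitted predictor as JSON
#'
#' The flat parameter vector is written at full precision together with a
#' sidecar description of each parameter block's name and shape, so models
#' round-trip across sessions and languages.
#'
#' @param predictor A [predictor()].
#' @param path File path for the JSON model file.
#' @return `save_predictor` returns `path` invisibly; `load_predictor`
#'   returns the reconstructed predictor.
#' @export
save_predictor <- function(predictor, path) {
  stopifnot(inherits(predictor, "markov_predictor"))
  obj <- list(kind = predictor$kind,
              n_destinations = predictor$n_destinations,
              n_covariates = predictor$n_covariates,
              hidden = predictor$hidden,
              activation = predictor$activation,
              shared_trunk = predictor$shared_trunk,
              layout = lapply(predictor$layout, function(b)
                list(name = b$name, dim = as.integer(b$dim))),
              parameters = predictor$parameters)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_predictor
#' @export
load_predictor <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  predictor(kind = obj$kind,
            n_destinations = obj$n_destinations,
            n_covariates = obj$n_covariates,
            hidden = if (length(obj$hidden)) obj$hidden else integer(),
            activation = obj$activation,
            shared_trunk = obj$shared_trunk,
            parameters = obj$parameters)
}
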