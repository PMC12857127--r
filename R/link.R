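#' A row of competing transition probabilities
#'
#' Container for the probabilities of the competing transitions out of one
#' transient state during a single discrete time interval. The probability of
#' remaining (`stay`) is always derived as the complement, so the implied
#' matrix row sums to 1 exactly.
#'
#' @param lambdas Numeric vector of per-destination transition probabilities;
#'   each must lie in `[0, 1)` and their sum must be strictly below 1.
#' @return An object of class `probability_row` with elements `lambdas` and
#'   `stay`.
#' @examples
#' probability_row(c(0.1, 0.2))
#' @export
probability_row <- function(lambdas) {
  assert_that(is.numeric(lambdas) && length(lambdas) >= 1,
              "`lambdas` must be a non-empty numeric vector")
  assert_that(all(is.finite(lambdas)), "`lambdas` must be finite")
  assert_that(all(lambdas >= 0) && all(lambdas < 1),
              "each transition probability must lie in [0, 1)")
  total <- sum(lambdas)
  assert_that(total < 1, "transition probabilities must sum to less than 1")
  structure(list(lambdas = as.numeric(lambdas), stay = 1 - total),
            class = "probability_row")
}

#' @export
print.probability_row <- function(x, ...) {
  cat("Transition probability row (", length(x$lambdas), " destination",
      if (length(x$lambdas) > 1) "s", ")\n", sep = "")
  cat("  lambda:", format(x$lambdas, digits = 4), "\n")
  cat("  stay:  ", format(x$stay, digits = 4), "\n")
  invisible(x)
}

as_lambdas <- function(row) {
  if (inherits(row, "probability_row")) row$lambdas else as.numeric(row)
}

#' Multinomial-logistic link from scores to transition probabilities
#'
#' Maps a vector of unconstrained real-valued scores, one per competing
#' destination, to transition probabilities
#' \deqn{\lambda_n = \frac{e^{s_n}}{1 + \sum_j e^{s_j}},}
#' with the stay probability \eqn{1 / (1 + \sum_j e^{s_j})} as the implicit
#' reference category. With a single destination this is exactly the logistic
#' function. Computation shifts by the maximum score before exponentiating,
#' so the link is stable for scores of large magnitude.
#'
#' @param scores Numeric vector of finite scores, one per destination.
#' @return A [probability_row()].
#' @examples
#' link(0)          # logistic at zero: 0.5
#' link(c(0, 0))    # symmetric three-way split
#' @export
link <- function(scores) {
  assert_that(is.numeric(scores) && length(scores) >= 1,
              "`scores` must be a non-empty numeric vector")
  if (!all(is.finite(scores))) {
    stop("link(): all scores must be finite; got ",
         paste(format(scores), collapse = ", "), call. = FALSE)
  }
  z <- c(0, scores)             # leading 0 = stay category
  m <- max(z)
  w <- exp(z - m)
  p <- w / sum(w)
  # built directly: the normalised row is valid by construction, and for
  # scores beyond ~36 the strict sum < 1 check would reject mere rounding
  structure(list(lambdas = p[-1], stay = p[1]), class = "probability_row")
}

# Vectorised link: S is an n x N score matrix; returns list(lambda = n x N
# matrix, stay = length-n vector). Row-wise max shift for stability.
link_matrix <- function(S) {
  S <- as.matrix(S)
  m <- pmax(0, apply(S, 1L, max))
  E <- exp(S - m)
  denom <- exp(-m) + rowSums(E)
  list(lambda = E / denom, stay = exp(-m) / denom)
}
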