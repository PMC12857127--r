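#' Define a multi-state transition structure
#'
#' Describes the state space of a star-shaped discrete-time Markov model: one
#' transient origin state and a set of reachable destination states. Each
#' modeled row of the transition matrix has exactly one origin; destinations
#' are absorbing by default (once entered they are never left).
#'
#' @param state_labels Character or integer vector of unique state labels, in
#'   matrix order.
#' @param origin Label of the transient origin state.
#' @param destinations Labels of the states reachable from the origin, in the
#'   order used by probability rows and predictors.
#' @param absorbing Logical vector, one flag per state; defaults to marking
#'   every state except the origin as absorbing.
#' @return An object of class `transition_structure`.
#' @examples
#' transition_structure(1:3, origin = 1, destinations = c(2, 3))
#' @export
transition_structure <- function(state_labels, origin, destinations,
                                 absorbing = NULL) {
  state_labels <- as.character(state_labels)
  assert_that(!anyDuplicated(state_labels), "state labels must be unique")
  origin <- as.character(origin)
  destinations <- as.character(destinations)
  assert_that(origin %in% state_labels, "origin must be one of the states")
  assert_that(length(destinations) >= 1, "need at least one destination")
  assert_that(all(destinations %in% state_labels),
              "all destinations must be states")
  assert_that(!origin %in% destinations,
              "the origin cannot be its own destination")
  assert_that(!anyDuplicated(destinations), "destinations must be unique")
  if (is.null(absorbing)) {
    absorbing <- state_labels != origin
  }
  assert_that(length(absorbing) == length(state_labels),
              "`absorbing` needs one flag per state")
  assert_that(!absorbing[match(origin, state_labels)],
              "the origin state cannot be absorbing")
  structure(list(state_labels = state_labels,
                 origin = origin,
                 destinations = destinations,
                 absorbing = as.logical(absorbing)),
            class = "transition_structure")
}

#' @export
print.transition_structure <- function(x, ...) {
  cat("Transition structure:", length(x$state_labels), "states\n")
  cat("  origin:      ", x$origin, "\n")
  cat("  destinations:", paste(x$destinations, collapse = ", "), "\n")
  cat("  absorbing:   ",
      paste(x$state_labels[x$absorbing], collapse = ", "), "\n")
  invisible(x)
}

#' Number of competing destinations of a structure
#' @param structure A [transition_structure()].
#' @return Integer count of destination states.
#' @export
n_destinations <- function(structure) {
  stopifnot(inherits(structure, "transition_structure"))
  length(structure$destinations)
}

#' Realize the full transition probability matrix
#'
#' Places a probability row into the square one-step transition matrix implied
#' by a structure: the origin row carries the stay probability on its diagonal
#' and the per-destination probabilities in their columns; absorbing states get
#' unit rows; transitions the structure does not allow are 0. Every row sums
#' to 1.
#'
#' @param structure A [transition_structure()].
#' @param row A [probability_row()] or plain numeric vector of destination
#'   probabilities, in `structure$destinations` order.
#' @return A square row-stochastic matrix with state labels as dimnames.
#' @examples
#' st <- transition_structure(1:3, 1, c(2, 3))
#' realize_matrix(st, c(0.25, 0.25))
#' @export
realize_matrix <- function(structure, row) {
  stopifnot(inherits(structure, "transition_structure"))
  lam <- as_lambdas(row)
  assert_that(length(lam) == n_destinations(structure),
              "probability row length must match the number of destinations")
  lam <- probability_row(lam)   # re-validate plain vectors
  k <- length(structure$state_labels)
  P <- diag(1, k)               # non-origin states keep themselves
  i <- match(structure$origin, structure$state_labels)
  j <- match(structure$destinations, structure$state_labels)
  P[i, ] <- 0
  P[i, i] <- lam$stay
  P[i, j] <- lam$lambdas
  dimnames(P) <- list(structure$state_labels, structure$state_labels)
  P
}
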