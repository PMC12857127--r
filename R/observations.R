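RESERVED_COLUMNS <- c("id", "origin", "event", "destination",
                      "time_kind", "k_star", "k1", "k2")

#' Validate a long-format transition dataset
#'
#' Checks a data frame of per-individual transition records and attaches the
#' metadata the modeling functions need. Each row is one individual's record
#' from a single transient origin state:
#' \itemize{
#'   \item `event = 1` with an exact time: a transition to `destination` was
#'     observed at discrete time `k_star`.
#'   \item `event = 1` with `time_kind = "interval"`: the transition happened
#'     at some time in the half-open interval `(k1, k2]`.
#'   \item `event = 0`: right-censored at `k_star`; measurements stopped with
#'     no transition observed, so the row contributes survival mass only.
#' }
#' Exact times count completed time intervals: an event with `k_star = k`
#' survived `k` full intervals and transitioned during the next one, so its
#' probability mass is `lambda * (1 - sum(lambda))^k`. Interval bounds are on
#' the trial scale, where candidate trial `t` corresponds to completed time
#' `t - 1`. Covariates must already be scaled to `[0, 1]`; see
#' [encode_covariates()] for the categorical encoding used for real data.
#'
#' @param df Data frame with columns `id`, `origin`, `event`, `destination`,
#'   `time_kind`, `k_star`, `k1`, `k2` plus one numeric column per covariate.
#'   Missing time columns are created as `NA` when unused.
#' @param covariates Character vector naming the covariate columns; defaults
#'   to every non-reserved column.
#' @param structure Optional [transition_structure()]; inferred as a star over
#'   the observed origin/destinations when absent.
#' @return The data frame with class `transition_data` and attributes
#'   `covariates` and `structure`.
#' @export
as_transition_data <- function(df, covariates = NULL, structure = NULL) {
  df <- as.data.frame(df)
  for (col in c("destination", "k_star", "k1", "k2")) {
    if (!col %in% names(df)) df[[col]] <- NA
  }
  needed <- setdiff(RESERVED_COLUMNS, names(df))
  assert_that(length(needed) == 0,
              paste("missing required columns:", paste(needed, collapse = ", ")))
  if (is.null(covariates)) covariates <- setdiff(names(df), RESERVED_COLUMNS)

  bad <- function(rows, why) {
    if (any(rows)) {
      stop("invalid transition data (", why, ") at row",
           if (sum(rows) > 1) "s", " ",
           paste(utils::head(which(rows), 5), collapse = ", "),
           if (sum(rows) > 5) ", ...", call. = FALSE)
    }
  }
  bad(!df$event %in% c(0, 1), "event must be 0 or 1")
  bad(!df$time_kind %in% c("exact", "interval"), "unknown time_kind")
  ev <- df$event == 1
  exact <- df$time_kind == "exact"
  bad(ev & exact & is.na(df$destination), "event = 1 without a destination")
  bad(!ev & !is.na(df$destination), "censored row carries a destination")
  bad(!ev & !exact, "right-censored rows must have an exact censoring time")
  bad(exact & (is.na(df$k_star) | df$k_star < 0 | df$k_star != round(df$k_star)),
      "exact rows need an integer k_star >= 0")
  itv <- !exact
  bad(itv & (is.na(df$k1) | is.na(df$k2)), "interval rows need k1 and k2")
  bad(itv & !is.na(df$k1) & !is.na(df$k2) &
        (df$k1 < 0 | df$k1 >= df$k2 |
           df$k1 != round(df$k1) | df$k2 != round(df$k2)),
      "interval rows need integers 0 <= k1 < k2")
  for (cv in covariates) {
    assert_that(cv %in% names(df), paste("covariate column not found:", cv))
    x <- df[[cv]]
    bad(!is.numeric(x) | !is.finite(x), paste("covariate", cv, "not finite numeric"))
    bad(x < 0 | x > 1, paste("covariate", cv, "outside [0, 1]"))
  }

  if (is.null(structure)) {
    dests <- sort(unique(df$destination[!is.na(df$destination)]))
    org <- unique(df$origin)
    assert_that(length(org) == 1,
                "all rows must share one origin state (star topology)")
    if (length(dests) == 0) {
      stop("cannot infer destinations from a fully censored dataset; ",
           "pass `structure` explicitly", call. = FALSE)
    }
    structure <- transition_structure(c(org, dests), org, dests)
  }
  bad(ev & !is.na(df$destination) &
        !as.character(df$destination) %in% structure$destinations,
      "destination not in the transition structure")

  attr(df, "covariates") <- covariates
  attr(df, "structure") <- structure
  class(df) <- unique(c("transition_data", class(df)))
  df
}

#' @export
print.transition_data <- function(x, ...) {
  st <- attr(x, "structure")
  cat("Transition data:", nrow(x), "individuals,",
      sum(x$event == 1), "events,",
      sum(x$event == 0), "right-censored\n")
  cat("  interval-censored events:",
      sum(x$event == 1 & x$time_kind == "interval"), "\n")
  cat("  covariates:", paste(attr(x, "covariates"), collapse = ", "), "\n")
  cat("  destinations:", paste(st$destinations, collapse = ", "), "\n")
  NextMethod()
}

covariate_matrix <- function(data) {
  as.matrix(as.data.frame(data)[, attr(data, "covariates"), drop = FALSE])
}

# Precompute the quantities the likelihood needs as flat vectors/matrices.
compile_data <- function(data) {
  stopifnot(inherits(data, "transition_data"))
  st <- attr(data, "structure")
  dest_idx <- match(as.character(data$destination), st$destinations)
  interval <- data$time_kind == "interval"
  list(X = covariate_matrix(data),
       n = nrow(data),
       event = as.integer(data$event),
       dest_idx = dest_idx,
       interval = interval,
       k_star = ifelse(interval, NA_real_, as.numeric(data$k_star)),
       a = ifelse(interval, as.numeric(data$k1), NA_real_),
       L = ifelse(interval, as.numeric(data$k2 - data$k1), NA_real_),
       structure = st)
}
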