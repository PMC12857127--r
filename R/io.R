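#' Read and write long-format transition data
#'
#' The on-disk format is a plain CSV with one row per individual and the
#' columns `id, origin, event, destination, time_kind, k_star, k1, k2`
#' followed by covariate columns. `read_transition_data()` validates rows
#' (reporting offending row numbers), optionally encodes categorical
#' covariates, and returns a [as_transition_data()] object;
#' `write_transition_data()` is its inverse and round-trips exactly.
#'
#' @param data A `transition_data` object.
#' @param path CSV file path.
#' @param covariates Covariate column names; default: every non-reserved
#'   column.
#' @param encoding Optional [covariate_encoding()] applied before
#'   validation.
#' @param structure Optional [transition_structure()].
#' @return `write_transition_data` returns `path` invisibly;
#'   `read_transition_data` returns a `transition_data` object.
#' @export
write_transition_data <- function(data, path) {
  stopifnot(inherits(data, "transition_data"))
  utils::write.csv(as.data.frame(data)[, c(RESERVED_COLUMNS,
                                           attr(data, "covariates"))],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transition_data
#' @export
read_transition_data <- function(path, covariates = NULL, encoding = NULL,
                                 structure = NULL) {
  assert_that(file.exists(path), paste("file not found:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(encoding)) df <- encode_covariates(df, encoding)
  as_transition_data(df, covariates = covariates, structure = structure)
}

#' Map categorical covariates onto the unit interval
#'
#' Builds the encoding used for categorical covariates: two-category
#' covariates map to `{0, 1}`, three-category covariates to `{0, 0.5, 1}`,
#' and in general `k` ordered categories map to an equally spaced grid on
#' `[0, 1]`.
#'
#' @param levels_by_covariate Named list; each element is a character vector
#'   of category labels in their intended order, or an already-named numeric
#'   vector of category values in `[0, 1]`.
#' @return A `covariate_encoding` named list of category-to-value maps.
#' @examples
#' covariate_encoding(list(tcd = c("No", "Yes", "Unknown")))
#' @export
covariate_encoding <- function(levels_by_covariate) {
  assert_that(is.list(levels_by_covariate) &&
                !is.null(names(levels_by_covariate)),
              "need a named list of category levels")
  enc <- lapply(levels_by_covariate, function(lv) {
    if (is.numeric(lv)) {
      assert_that(!is.null(names(lv)) && all(lv >= 0 & lv <= 1),
                  "numeric encodings must be named values in [0, 1]")
      return(lv)
    }
    assert_that(length(lv) >= 2, "each covariate needs >= 2 categories")
    stats::setNames(seq(0, 1, length.out = length(lv)), lv)
  })
  structure(enc, class = "covariate_encoding")
}

#' Apply a covariate encoding to a data frame
#'
#' @param df Data frame holding the raw categorical columns.
#' @param encoding A [covariate_encoding()].
#' @return The data frame with encoded numeric columns.
#' @export
encode_covariates <- function(df, encoding) {
  stopifnot(inherits(encoding, "covariate_encoding"))
  for (cv in names(encoding)) {
    assert_that(cv %in% names(df), paste("column not found:", cv))
    map <- encoding[[cv]]
    vals <- as.character(df[[cv]])
    unknown <- !vals %in% names(map)
    if (any(unknown)) {
      stop("unknown categories in `", cv, "`: ",
           paste(unique(vals[unknown]), collapse = ", "), call. = FALSE)
    }
    df[[cv]] <- unname(map[vals])
  }
  df
}

#' Stratified train/validation split
#'
#' Splits individuals so every transition type (each destination, plus the
#' right-censored group) appears in similar proportions in both parts. Strata
#' with fewer than two members go to the training set with a warning.
#'
#' @param data A `transition_data` dataset.
#' @param fraction Training fraction, strictly between 0 and 1.
#' @param seed RNG seed for the within-stratum draws.
#' @return List with elements `train` and `validation`, both
#'   `transition_data`, disjoint and exhaustive.
#' @export
split_stratified <- function(data, fraction, seed = NULL) {
  stopifnot(inherits(data, "transition_data"))
  assert_that(fraction > 0 && fraction < 1,
              "fraction must be strictly between 0 and 1")
  strata <- ifelse(data$event == 1,
                   paste0("dest_", data$destination), "censored")
  take_train <- logical(nrow(data))
  with_seed(seed, {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      if (length(idx) < 2) {
        warning("stratum `", s, "` has fewer than 2 members; ",
                "assigned to the training set")
        take_train[idx] <- TRUE
        next
      }
      n_tr <- round(fraction * length(idx))
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
      take_train[sample(idx, n_tr)] <- TRUE
    }
  })
  keep_attrs <- function(rows) {
    out <- as.data.frame(data)[rows, , drop = FALSE]
    as_transition_data(out, covariates = attr(data, "covariates"),
                       structure = attr(data, "structure"))
  }
  list(train = keep_attrs(take_train), validation = keep_attrs(!take_train))
}

#' Convert an EBMT-style survival table to long transition format
#'
#' Adapter from a data frame shaped like the `ebmt2` dataset of the mstate
#' package (one row per transplanted patient; a survival time in days; a
#' status code 0 for censored or 1..6 for the cause of death; four
#' categorical covariates) to this package's long format: a 7-state star with
#' state 1 = alive post-transplant and states 2..7 the absorbing causes of
#' death. Calendar time is discretised as `ceiling(time / days_per_unit)`
#' for events (the unit in which death occurred, minimum 1) and
#' `floor(time / days_per_unit)` for censored patients (complete units
#' survived); the chosen unit is recorded in the result's attributes, since
#' no canonical discretisation exists for these data.
#'
#' @param df Data frame with the time, status, and covariate columns.
#' @param days_per_unit Length of one discrete interval in days (e.g. 365.25
#'   for yearly intervals).
#' @param time_col,status_col Column names (defaults `"time"`, `"status"`).
#' @param covariate_cols Names of the categorical covariate columns; default
#'   `c("dissub", "match", "tcd", "age")`.
#' @param encoding Optional [covariate_encoding()]; by default built from
#'   the observed category levels of each column (factor-level order).
#' @return A `transition_data` object with attribute `days_per_unit`.
#' @export
ebmt2_to_long <- function(df, days_per_unit,
                          time_col = "time", status_col = "status",
                          covariate_cols = c("dissub", "match", "tcd", "age"),
                          encoding = NULL) {
  assert_that(days_per_unit > 0, "days_per_unit must be positive")
  for (col in c(time_col, status_col, covariate_cols)) {
    assert_that(col %in% names(df), paste("column not found:", col))
  }
  status <- as.integer(df[[status_col]])
  assert_that(all(status %in% 0:6), "status codes must be 0 (censored) or 1..6")
  event <- as.integer(status > 0)
  time <- as.numeric(df[[time_col]])
  assert_that(all(time >= 0), "times must be nonnegative")
  k <- ifelse(event == 1,
              pmax(ceiling(time / days_per_unit), 1),
              floor(time / days_per_unit))
  if (is.null(encoding)) {
    encoding <- covariate_encoding(lapply(
      stats::setNames(covariate_cols, covariate_cols),
      function(cv) {
        x <- df[[cv]]
        if (is.factor(x)) levels(x) else sort(unique(as.character(x)))
      }))
  }
  covs <- encode_covariates(df[, covariate_cols, drop = FALSE], encoding)
  long <- data.frame(id = seq_len(nrow(df)),
                     origin = 1L,
                     event = event,
                     destination = ifelse(event == 1, status + 1L, NA_integer_),
                     time_kind = "exact",
                     k_star = k, k1 = NA_real_, k2 = NA_real_)
  long <- cbind(long, covs)
  st <- transition_structure(1:7, 1, 2:7)
  out <- as_transition_data(long, covariates = covariate_cols, structure = st)
  attr(out, "days_per_unit") <- days_per_unit
  out
}

#' Read a run configuration file
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON configuration file.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  assert_that(file.exists(path), paste("config file not found:", path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    # keep single-letter keys like `n` out of YAML 1.1 boolean coercion
    keep <- function(x) {
      if (tolower(x) %in% c("true", "yes")) TRUE
      else if (tolower(x) %in% c("false", "no")) FALSE
      else x
    }
    yaml::read_yaml(path, handlers = list("bool#yes" = keep,
                                          "bool#no" = keep))
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
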