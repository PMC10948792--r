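#' The default emotion category list
#'
#' The thirteen emotion categories used throughout the package, in their
#' canonical (alphabetical) order. All probability tables and prior vectors
#' carry an ordered category list; this is the default.
#'
#' @return Character vector of 13 lower-case category labels.
#' @export
#' @examples
#' emotion_categories()
emotion_categories <- function() {
  c("amusement", "anger", "awe", "contempt", "disgust", "embarrassment",
    "fear", "happiness", "interest", "pride", "sadness", "shame", "surprise")
}

#' Construct a stimulus-by-emotion probability table
#'
#' A `probability_table` is a numeric matrix with one row per stimulus and one
#' column per emotion category. Every entry lies in \[0, 1\] and every row sums
#' to 1 (tolerance 1e-9). Rows that had to be replaced by the uniform
#' distribution (all-zero input rows) are recorded in the `degenerate`
#' attribute so the anomaly stays auditable downstream.
#'
#' @param x Numeric matrix of non-negative values, stimuli in rows, emotions
#'   in columns. Rows need not be normalized: they are divided by their row
#'   sums, and all-zero rows fall back to the uniform distribution.
#' @param stimulus_ids Optional character vector of row identifiers; defaults
#'   to `rownames(x)`.
#' @param emotions Optional character vector of column categories; defaults to
#'   `colnames(x)`.
#' @return A `probability_table`: the normalized matrix with a `degenerate`
#'   attribute listing stimulus ids whose rows were replaced by the uniform
#'   fallback.
#' @export
#' @examples
#' pt <- probability_table(matrix(c(3, 1, 0, 1, 1, 2), 2, byrow = TRUE,
#'   dimnames = list(c("s1", "s2"), c("anger", "fear", "pride"))))
#' rowSums(pt)
probability_table <- function(x, stimulus_ids = rownames(x),
                              emotions = colnames(x)) {
  x <- as.matrix(x)
  if (is.null(stimulus_ids)) {
    stimulus_ids <- paste0("stim_", seq_len(nrow(x)))
  }
  if (is.null(emotions)) {
    stop("probability_table: emotion column names are required")
  }
  if (length(stimulus_ids) != nrow(x) || length(emotions) != ncol(x)) {
    stop("probability_table: dimnames do not match matrix dimensions")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("probability_table: entries must be finite and non-missing")
  }
  if (any(x < 0)) {
    stop("probability_table: entries must be non-negative")
  }
  dimnames(x) <- list(stimulus_ids, emotions)
  norm <- normalize_rows(x)
  structure(norm$matrix, degenerate = norm$degenerate,
            class = c("probability_table", "matrix", "array"))
}

# Row-normalize a non-negative matrix; all-zero rows become uniform and their
# row names are returned as `degenerate`.
normalize_rows <- function(x) {
  rs <- rowSums(x)
  zero <- rs <= 0
  out <- x
  if (any(!zero)) {
    out[!zero, ] <- x[!zero, , drop = FALSE] / rs[!zero]
  }
  if (any(zero)) {
    out[zero, ] <- 1 / ncol(x)
  }
  list(matrix = out, degenerate = rownames(x)[zero])
}

#' @export
print.probability_table <- function(x, ...) {
  cat(sprintf("probability_table: %d stimuli x %d emotions\n", nrow(x), ncol(x)))
  deg <- attr(x, "degenerate")
  if (length(deg)) {
    cat(sprintf("  degenerate (uniform fallback) rows: %s\n",
                paste(deg, collapse = ", ")))
  }
  print(utils::head(unclass(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Stimuli flagged as degenerate in a probability table
#'
#' @param x A `probability_table` or `integration_result`.
#' @return Character vector of stimulus ids whose rows fell back to the
#'   uniform distribution.
#' @export
degenerate_rows <- function(x) {
  if (inherits(x, "integration_result")) x <- x$table
  attr(x, "degenerate") %||% character()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validate a probability_table invariant set; used by tests and readers.
validate_probability_table <- function(x, tol = 1e-9) {
  stopifnot(inherits(x, "probability_table"))
  if (any(x < -tol) || any(x > 1 + tol)) {
    stop("probability_table: entries outside [0, 1]")
  }
  if (any(abs(rowSums(x) - 1) > tol)) {
    stop("probability_table: rows do not sum to 1 within tolerance")
  }
  invisible(x)
}

#' Construct a prior probability vector over emotions
#'
#' A `prior_vector` is a named numeric vector of strictly positive
#' probabilities over the configured emotion categories, summing to 1. A small
#' floor keeps every entry strictly positive so that division by the prior in
#' the cue-integration model is always defined.
#'
#' @param probabilities Non-negative numeric vector (normalized internally).
#' @param emotions Category labels; defaults to `names(probabilities)`.
#' @param floor Minimum probability after normalization; entries below it are
#'   raised to the floor and the vector renormalized. Default `1e-6`.
#' @return A `prior_vector`.
#' @seealso [prior_vector()] to estimate one from likelihood ratings,
#'   [uniform_prior()].
#' @export
new_prior_vector <- function(probabilities, emotions = names(probabilities),
                             floor = 1e-6) {
  if (is.null(emotions) || length(emotions) != length(probabilities)) {
    stop("new_prior_vector: emotions must label every probability")
  }
  p <- as.numeric(probabilities)
  if (anyNA(p) || any(!is.finite(p)) || any(p < 0)) {
    stop("new_prior_vector: probabilities must be finite and non-negative")
  }
  if (sum(p) <= 0) {
    p <- rep(1, length(p))
  }
  p <- p / sum(p)
  if (any(p < floor)) {
    p[p < floor] <- floor
    p <- p / sum(p)
  }
  names(p) <- emotions
  structure(p, floor = floor, class = c("prior_vector", "numeric"))
}

#' @export
print.prior_vector <- function(x, ...) {
  cat(sprintf("prior_vector over %d emotion categories\n", length(x)))
  print(round(unclass(x), 5), ...)
  invisible(x)
}

#' Uniform prior over a category list
#'
#' @param emotions Non-empty character vector of categories.
#' @return A `prior_vector` with every entry `1/K`.
#' @export
#' @examples
#' uniform_prior(c("anger", "fear"))
uniform_prior <- function(emotions = emotion_categories()) {
  if (length(emotions) < 1L) {
    stop("uniform_prior: the emotion category list is empty")
  }
  new_prior_vector(rep(1 / length(emotions), length(emotions)),
                   emotions = emotions)
}
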