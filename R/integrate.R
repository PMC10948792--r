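#' Combine situation and face cues under the lay-theory Bayesian model
#'
#' Implements the cue-integration rule in which an observer's belief that a
#' target feels emotion *e* given situation *s* and facial expression *f* is
#' proportional to `P(e|s) * P(e|f) / P(e)`: the product of the two single-cue
#' likelihoods divided by the prior over emotions, with the implicit
#' proportionality constant restored by renormalizing each stimulus row to
#' sum to 1. The rule follows from a causal lay theory in which situations
#' cause emotions and emotions cause expressions, so the two cues are
#' conditionally independent given the emotion.
#'
#' With `flat_prior = TRUE` the supplied prior is replaced by the uniform
#' distribution before combining, giving the flat-prior variant used to test
#' whether empirically measured priors are informative.
#'
#' @param situation,face `probability_table`s sharing identical stimulus and
#'   emotion orderings (P(e|s) and P(e|f)).
#' @param prior A `prior_vector` over the same emotions, strictly positive.
#' @param flat_prior Replace `prior` by the uniform distribution first?
#' @return An `integration_result`: list with `table` (the model P(e|s,f) as a
#'   `probability_table`), `prior_used`, and `flat_prior`.
#' @export
#' @examples
#' em <- c("anger", "fear", "pride")
#' S <- probability_table(matrix(c(0.6, 0.3, 0.1), 1,
#'   dimnames = list("s1", em)))
#' F <- probability_table(matrix(c(0.2, 0.5, 0.3), 1,
#'   dimnames = list("s1", em)))
#' integrate_cues(S, F, uniform_prior(em))$table
integrate_cues <- function(situation, face, prior, flat_prior = FALSE) {
  check_axes(situation, face, what = c("situation", "face"))
  emotions <- colnames(situation)
  if (!identical(names(prior), emotions)) {
    stop(sprintf("prior categories do not match the tables: prior has [%s], tables have [%s]",
                 paste(names(prior), collapse = ", "),
                 paste(emotions, collapse = ", ")))
  }
  if (flat_prior) {
    prior <- uniform_prior(emotions)
  }
  if (any(prior <= 0)) {
    stop("prior has zero entries; rebuild it with a positive floor (see new_prior_vector)")
  }
  raw <- unclass(situation) * unclass(face)
  raw <- sweep(raw, 2L, as.numeric(prior), "/")
  table <- probability_table(raw, stimulus_ids = rownames(situation),
                             emotions = emotions)
  structure(list(table = table, prior_used = prior, flat_prior = flat_prior),
            class = "integration_result")
}

#' @export
print.integration_result <- function(x, ...) {
  cat(sprintf("cue-integration model table (%s prior)\n",
              if (x$flat_prior) "flat" else "empirical"))
  print(x$table, ...)
  invisible(x)
}

# Shared axis check: identical stimulus ids and emotion orderings.
check_axes <- function(a, b, what = c("empirical", "model")) {
  if (!identical(rownames(a), rownames(b))) {
    only_a <- setdiff(rownames(a), rownames(b))
    only_b <- setdiff(rownames(b), rownames(a))
    stop(sprintf(
      "stimulus axes differ (%s vs %s): only in %s: [%s]; only in %s: [%s]%s",
      what[1], what[2],
      what[1], paste(utils::head(only_a, 5), collapse = ", "),
      what[2], paste(utils::head(only_b, 5), collapse = ", "),
      if (!length(only_a) && !length(only_b)) "; same ids, different order" else ""))
  }
  if (!identical(colnames(a), colnames(b))) {
    stop(sprintf("emotion axes differ (%s vs %s): [%s] vs [%s]",
                 what[1], what[2],
                 paste(colnames(a), collapse = ", "),
                 paste(colnames(b), collapse = ", ")))
  }
  invisible(TRUE)
}
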