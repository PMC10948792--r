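# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

toy_emotions <- c("anger", "fear", "pride")

# A probability table from explicit rows (list of numeric vectors).
toy_table <- function(rows, emotions = toy_emotions,
                      ids = sprintf("s%d", seq_along(rows))) {
  probability_table(do.call(rbind, rows), stimulus_ids = ids,
                    emotions = emotions)
}

# Long-format rating records from a stimulus x emotion intensity matrix for
# one participant and condition.
records_from_matrix <- function(m, participant_id = "p1", condition = "joint",
                                emotions = colnames(m)) {
  data.frame(
    participant_id = participant_id,
    stimulus_id = rep(rownames(m), times = ncol(m)),
    condition = condition,
    emotion = rep(emotions, each = nrow(m)),
    presence = c(m) > 0,
    intensity = as.integer(c(m)),
    session = NA_integer_,
    quality = "valid",
    stringsAsFactors = FALSE
  )
}

# Random valid rating set: n_raters x n_stimuli x emotions, one condition.
random_records <- function(n_raters, n_stimuli, emotions = toy_emotions,
                           condition = "joint", seed = 1) {
  set.seed(seed)
  out <- lapply(seq_len(n_raters), function(p) {
    m <- matrix(sample(0:4, n_stimuli * length(emotions), replace = TRUE),
                nrow = n_stimuli,
                dimnames = list(sprintf("s%02d", seq_len(n_stimuli)),
                                emotions))
    records_from_matrix(m, participant_id = sprintf("p%02d", p),
                        condition = condition)
  })
  do.call(rbind, out)
}

# Map from rater_profile types to classify_best_model labels.
type_label <- c(situation = "situation", face = "face",
                integrator = "integration")
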