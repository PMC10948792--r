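#' Encode a presence/intensity judgment on the 0--4 ordinal scale
#'
#' Raters first judge whether an emotion is present (yes/no) and, only if
#' present, rate its intensity on a 4-point Likert scale (*slightly*,
#' *moderately*, *strongly*, *intensely*). The encoded score is 0 when the
#' emotion is judged absent and 1--4 otherwise, a monotone map of the labels.
#'
#' @param presence Logical (or `"yes"`/`"no"`) vector.
#' @param intensity_label Character vector drawn from `"absent"`,
#'   `"slightly"`, `"moderately"`, `"strongly"`, `"intensely"`.
#' @return Integer vector in `0:4`.
#' @export
#' @examples
#' encode_rating(c(TRUE, TRUE, FALSE), c("slightly", "intensely", "absent"))
encode_rating <- function(presence, intensity_label) {
  presence <- parse_presence(presence)
  levels <- c(absent = 0L, slightly = 1L, moderately = 2L, strongly = 3L,
              intensely = 4L)
  unknown <- setdiff(unique(intensity_label), names(levels))
  if (length(unknown)) {
    stop(sprintf("encode_rating: unknown intensity label(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  score <- unname(levels[intensity_label])
  score[!presence] <- 0L
  score
}

parse_presence <- function(presence) {
  if (is.character(presence) || is.factor(presence)) {
    p <- tolower(as.character(presence))
    ok <- p %in% c("yes", "no", "true", "false")
    if (any(!ok)) {
      stop(sprintf("presence values must be yes/no or true/false; got: %s",
                   paste(unique(p[!ok]), collapse = ", ")))
    }
    return(p %in% c("yes", "true"))
  }
  as.logical(presence)
}

#' Derive trial quality annotations from raw presence/intensity pairs
#'
#' On the rating platform an intensity rating could not be undone, so raters
#' were instructed to mark *slight* intensity when an accidental rating slipped
#' through for an emotion judged absent. A trial is therefore `accidental`
#' when presence is "no" but intensity is exactly 1, `incorrect` when presence
#' is "no" but intensity exceeds 1, `missing` when either response is missing,
#' and `valid` otherwise.
#'
#' @param records Rating data frame with `presence` and `intensity` columns.
#' @return The records with a `quality` column filled in (existing non-missing
#'   quality annotations are kept).
#' @export
infer_quality <- function(records) {
  q <- if ("quality" %in% names(records)) as.character(records$quality)
       else rep(NA_character_, nrow(records))
  derived <- rep("valid", nrow(records))
  derived[is.na(records$presence) | is.na(records$intensity)] <- "missing"
  absent <- !is.na(records$presence) & !records$presence &
    !is.na(records$intensity)
  derived[absent & records$intensity == 1] <- "accidental"
  derived[absent & records$intensity > 1] <- "incorrect"
  q[is.na(q) | q == ""] <- derived[is.na(q) | q == ""]
  records$quality <- q
  records
}

#' Correct accidental trials and drop incorrect ones
#'
#' Accidental intensity ratings (emotion marked absent, intensity rated
#' *slightly*) are corrected to "emotion absent" (presence `FALSE`, intensity
#' 0) and kept; fully incorrect trials (absent but intensity above *slightly*)
#' are removed on a trial-by-trial basis, as are trials with missing
#' responses. The correction report counts, per participant, total trials and
#' trials in each problem category, and is the input to
#' [exclude_participants()].
#'
#' @param records Rating data frame including a `quality` column (see
#'   [infer_quality()]); a missing column is inferred.
#' @return List with `records` (corrected data frame) and `report` (data frame
#'   with columns `participant_id`, `n_trials`, `n_accidental`, `n_incorrect`,
#'   `n_missing`, `bad_fraction`).
#' @export
correct_trials <- function(records) {
  if (!all(c("participant_id", "presence", "intensity") %in% names(records))) {
    stop("correct_trials: records need participant_id, presence, intensity")
  }
  if (!"quality" %in% names(records) || anyNA(records$quality)) {
    records <- infer_quality(records)
  }
  qual <- records$quality
  ids <- unique(records$participant_id)
  tab <- function(flag) {
    n <- tapply(flag, records$participant_id, sum)
    as.integer(n[ids])
  }
  report <- data.frame(
    participant_id = ids,
    n_trials = tab(rep(TRUE, nrow(records))),
    n_accidental = tab(qual == "accidental"),
    n_incorrect = tab(qual == "incorrect"),
    n_missing = tab(qual == "missing"),
    stringsAsFactors = FALSE
  )
  report$bad_fraction <- (report$n_accidental + report$n_incorrect +
                            report$n_missing) / report$n_trials
  acc <- qual == "accidental"
  records$presence[acc] <- FALSE
  records$intensity[acc] <- 0L
  records$quality[acc] <- "valid"
  out <- records[!qual %in% c("incorrect", "missing"), , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, report = report)
}

#' Exclude participants with too many problem trials
#'
#' Participants whose fraction of accidental, incorrect or missing trials
#' strictly exceeds `max_bad_fraction` are removed entirely; a participant at
#' exactly the threshold is retained.
#'
#' @param records Corrected rating data frame (output of [correct_trials()]).
#' @param report The correction report from [correct_trials()].
#' @param max_bad_fraction Exclusion threshold as a fraction; default `0.10`.
#' @return List with `records` (retained rows) and `excluded` (data frame of
#'   excluded `participant_id` and `bad_fraction`).
#' @export
exclude_participants <- function(records, report, max_bad_fraction = 0.10) {
  if (nrow(records) == 0L) {
    warning("exclude_participants: no records supplied")
    return(list(records = records,
                excluded = data.frame(participant_id = character(),
                                      bad_fraction = numeric())))
  }
  bad <- report$bad_fraction > max_bad_fraction
  excluded <- report[bad, c("participant_id", "bad_fraction"), drop = FALSE]
  rownames(excluded) <- NULL
  keep <- !(records$participant_id %in% excluded$participant_id)
  list(records = records[keep, , drop = FALSE], excluded = excluded)
}

#' Aggregate one condition's ratings into a probability table
#'
#' For the requested condition, the 0--4 intensity scores (absent coded 0) are
#' averaged across raters for each emotion category and stimulus, and the
#' per-stimulus means are then normalized across emotions so each row sums
#' to 1. Missing (participant, stimulus, emotion) cells contribute no rater:
#' the cell mean is taken over the raters who actually rated it. Stimuli whose
#' raters judged every emotion absent fall back to the uniform row and are
#' flagged degenerate.
#'
#' @param records Cleaned rating data frame with columns `participant_id`,
#'   `stimulus_id`, `condition`, `emotion`, `intensity`.
#' @param condition One of `"face_only"`, `"situation_only"`, `"joint"`.
#' @param emotions Ordered category list; default [emotion_categories()].
#' @return A [probability_table()] housing the condition's estimated
#'   P(emotion | cue) distribution per stimulus.
#' @export
condition_probability_table <- function(records, condition,
                                        emotions = emotion_categories()) {
  sub <- records[records$condition == condition, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop(sprintf("no records for condition '%s'", condition))
  }
  unknown <- setdiff(unique(sub$emotion), emotions)
  if (length(unknown)) {
    stop(sprintf("unknown emotion label(s): %s", paste(unknown, collapse = ", ")))
  }
  stimuli <- sort(unique(as.character(sub$stimulus_id)))
  means <- mean_intensity_matrix(sub, stimuli, emotions)
  nocov <- is.na(means)
  if (any(nocov)) {
    # a stimulus rated for some emotions but not others is a ragged design
    bad <- rownames(means)[rowSums(nocov) > 0 & rowSums(nocov) < ncol(means)]
    if (length(bad)) {
      stop(sprintf("ragged design: stimuli rated for only some emotions: %s",
                   paste(bad, collapse = ", ")))
    }
    stop(sprintf("stimuli with no ratings at all in condition '%s'", condition))
  }
  probability_table(means, stimulus_ids = stimuli, emotions = emotions)
}

# stimulus x emotion matrix of mean intensities (NA where no rater covered a
# cell); shared by group and participant-level aggregation.
mean_intensity_matrix <- function(records, stimuli, emotions) {
  s <- factor(as.character(records$stimulus_id), levels = stimuli)
  e <- factor(as.character(records$emotion), levels = emotions)
  sums <- tapply(as.numeric(records$intensity), list(s, e), sum)
  counts <- tapply(rep(1, nrow(records)), list(s, e), sum)
  out <- sums / counts
  dimnames(out) <- list(stimuli, emotions)
  out
}

#' Estimate the prior over emotions from everyday-likelihood ratings
#'
#' Participants rate how likely they are to perceive each emotion category in
#' everyday life on a 1--7 Likert scale. The prior is the per-emotion mean of
#' these ratings normalized to sum to 1 across categories, with a small floor
#' applied so no entry is exactly zero.
#'
#' @param prior_records Data frame with columns `participant_id`, `emotion`,
#'   `likelihood` (integers 1--7).
#' @param emotions Ordered category list; every category must be rated.
#' @param floor Minimum probability after normalization (default `1e-6`).
#' @return A `prior_vector`.
#' @export
#' @examples
#' recs <- expand.grid(participant_id = c("p1", "p2"),
#'                     emotion = c("anger", "fear"))
#' recs$likelihood <- c(6, 6, 2, 2)
#' prior_vector(recs, emotions = c("anger", "fear"))
prior_vector <- function(prior_records, emotions = emotion_categories(),
                         floor = 1e-6) {
  need <- c("participant_id", "emotion", "likelihood")
  if (!all(need %in% names(prior_records))) {
    stop("prior_vector: records need participant_id, emotion, likelihood")
  }
  lik <- prior_records$likelihood
  if (any(!is.na(lik) & (lik < 1 | lik > 7))) {
    stop("prior_vector: likelihood ratings must lie in 1..7")
  }
  missing <- setdiff(emotions, unique(as.character(prior_records$emotion)))
  if (length(missing)) {
    stop(sprintf("prior_vector: missing emotion categories: %s",
                 paste(missing, collapse = ", ")))
  }
  e <- factor(as.character(prior_records$emotion), levels = emotions)
  m <- tapply(as.numeric(lik), e, mean, na.rm = TRUE)
  new_prior_vector(as.numeric(m), emotions = emotions, floor = floor)
}
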