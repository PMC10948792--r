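#' Read long-format rating records from CSV
#'
#' Expects a UTF-8 comma-separated file with header columns `participant_id`,
#' `stimulus_id`, `condition`, `emotion`, `presence`, `intensity`, and
#' optionally `session` and `quality`. Presence may be encoded yes/no or
#' true/false. Unknown emotion labels are an error citing the offending rows;
#' rows with malformed presence or intensity are collected and reported
#' rather than silently dropped.
#'
#' @param path CSV file path.
#' @param emotions Ordered category list used for validation.
#' @return Rating data frame (see [simulate_raters()] for the column layout).
#' @export
read_ratings <- function(path, emotions = emotion_categories()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("participant_id", "stimulus_id", "condition", "emotion",
            "presence", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("read_ratings: missing required column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  bad_emotion <- which(!df$emotion %in% emotions)
  if (length(bad_emotion)) {
    stop(sprintf("read_ratings: unknown emotion label(s) %s at row(s) %s",
                 paste(unique(df$emotion[bad_emotion]), collapse = ", "),
                 paste(utils::head(bad_emotion, 10), collapse = ", ")))
  }
  df$presence <- parse_presence(df$presence)
  if (!is.numeric(df$intensity)) {
    suppressWarnings(df$intensity <- as.numeric(df$intensity))
  }
  bad_int <- which(!is.na(df$intensity) &
                     (df$intensity < 0 | df$intensity > 4 |
                        df$intensity != round(df$intensity)))
  if (length(bad_int)) {
    stop(sprintf("read_ratings: intensity outside the 0..4 grid at row(s) %s",
                 paste(utils::head(bad_int, 10), collapse = ", ")))
  }
  df$intensity <- as.integer(df$intensity)
  if (!"session" %in% names(df)) df$session <- NA_integer_
  if (!"quality" %in% names(df)) df <- infer_quality(df)
  df
}

#' Write rating records to CSV
#'
#' Inverse of [read_ratings()]: `read_ratings(write_ratings(x, p))` restores
#' the record set. Presence is written as yes/no.
#'
#' @param records Rating data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(records, path) {
  out <- records
  out$presence <- ifelse(parse_presence(records$presence), "yes", "no")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a probability table as wide CSV
#'
#' The wide dialect has a first column `stimulus_id` followed by one column
#' per emotion in the configured order.
#'
#' @param path CSV file path.
#' @param x A `probability_table`.
#' @return `read_probability_table()` returns a `probability_table`;
#'   `write_probability_table()` returns `path` invisibly.
#' @export
read_probability_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "stimulus_id") {
    stop("read_probability_table: first column must be stimulus_id")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  probability_table(m, stimulus_ids = as.character(df$stimulus_id),
                    emotions = colnames(m))
}

#' @rdname read_probability_table
#' @export
write_probability_table <- function(x, path) {
  x <- as_prob_table(x)
  df <- data.frame(stimulus_id = rownames(x), unclass(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a prior vector as two-column CSV
#'
#' Columns `emotion` and `probability`.
#'
#' @param path CSV file path.
#' @param x A `prior_vector`.
#' @return `read_prior()` returns a `prior_vector`; `write_prior()` returns
#'   `path` invisibly.
#' @export
read_prior <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("emotion", "probability") %in% names(df))) {
    stop("read_prior: need columns emotion, probability")
  }
  new_prior_vector(df$probability, emotions = df$emotion)
}

#' @rdname read_prior
#' @export
write_prior <- function(x, path) {
  utils::write.csv(data.frame(emotion = names(x),
                              probability = as.numeric(x)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read prior likelihood ratings (participant by emotion) from CSV
#'
#' Columns `participant_id`, `emotion`, `likelihood` (1--7).
#'
#' @param path CSV file path.
#' @param emotions Ordered category list used for validation.
#' @return Data frame of prior rating records for [prior_vector()].
#' @export
read_prior_ratings <- function(path, emotions = emotion_categories()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "emotion", "likelihood")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("read_prior_ratings: missing column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  bad <- which(!df$emotion %in% emotions)
  if (length(bad)) {
    stop(sprintf("read_prior_ratings: unknown emotion label(s) at row(s) %s",
                 paste(utils::head(bad, 10), collapse = ", ")))
  }
  df
}

#' Assemble a serializable analysis report
#'
#' Collects per-stage outputs (model fits, correlation contrasts,
#' participant estimates, reliability and covariate results) together with a
#' provenance block: MD5 hashes of the input files, an echo of the
#' configuration actually used (thresholds, bootstrap size, seeds, tie-break
#' rule, ICC form), and the package version. The report round-trips
#' losslessly through [write_report()] / [read_report()].
#'
#' @param ... Named result objects or lists of them; S3 result classes are
#'   flattened to plain lists for serialization.
#' @param config Named list echoing the run configuration.
#' @param input_paths Character vector of input files to hash (optional).
#' @return An `analysis_report` list with elements `results`, `provenance`.
#' @export
analysis_report <- function(..., config = list(), input_paths = character()) {
  results <- lapply(list(...), strip_classes)
  hashes <- if (length(input_paths)) {
    h <- tools::md5sum(input_paths)
    as.list(h)
  } else {
    list()
  }
  structure(list(
    schema_version = "1.0",
    results = results,
    provenance = list(
      package = "emocue",
      version = as.character(utils::packageVersion("emocue")),
      config = config,
      input_md5 = hashes
    )
  ), class = "analysis_report")
}

strip_classes <- function(x) {
  if (inherits(x, "probability_table")) {
    return(list(stimulus_ids = rownames(x), emotions = colnames(x),
                probabilities = unname(apply(unclass(x), 1L, c,
                                             simplify = FALSE)),
                degenerate_rows = degenerate_rows(x)))
  }
  if (is.list(x)) {
    return(lapply(unclass(x), strip_classes))
  }
  if (is.object(x)) return(unclass(x))
  x
}

#' Write / read an analysis report as JSON
#'
#' Numbers are serialized at full precision and the report is
#' schema-versioned; `read_report(write_report(x, p))` recovers the same
#' content.
#'
#' @param report An `analysis_report`.
#' @param path Output JSON path.
#' @return `write_report()` returns `path` invisibly; `read_report()` returns
#'   the parsed report list.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
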