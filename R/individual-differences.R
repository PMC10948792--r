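#' Build one participant's joint-cue probability table
#'
#' Single-rater analogue of [condition_probability_table()]: the participant's
#' 0--4 intensity scores are averaged per stimulus-by-emotion cell (one rating
#' per cell in the standard design) and each stimulus row is normalized to
#' sum to 1. Stimuli the participant did not rate for every emotion are
#' dropped with a warning (downstream comparisons are pairwise complete over
#' the retained stimuli); all-absent stimuli fall back to the uniform row and
#' are flagged degenerate.
#'
#' @param records Cleaned rating data frame for a single participant.
#' @param condition Condition to use; default `"joint"`.
#' @param emotions Ordered category list.
#' @return A [probability_table()].
#' @export
participant_probability_table <- function(records, condition = "joint",
                                          emotions = emotion_categories()) {
  if (length(unique(records$participant_id)) > 1L) {
    stop("participant_probability_table: records span several participants")
  }
  sub <- records[records$condition == condition, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop(sprintf("no records for condition '%s'", condition))
  }
  stimuli <- sort(unique(as.character(sub$stimulus_id)))
  means <- mean_intensity_matrix(sub, stimuli, emotions)
  incomplete <- rowSums(is.na(means)) > 0
  if (any(incomplete)) {
    warning(sprintf("dropping %d stimuli with incomplete emotion coverage: %s",
                    sum(incomplete),
                    paste(utils::head(stimuli[incomplete], 5), collapse = ", ")))
    means <- means[!incomplete, , drop = FALSE]
    stimuli <- stimuli[!incomplete]
  }
  if (nrow(means) == 0L) stop("participant has no complete stimuli")
  probability_table(means, stimulus_ids = stimuli, emotions = emotions)
}

#' Estimate a participant's cue-reliance from the group-level model tables
#'
#' Correlates the participant's joint-cue probability table with the fixed
#' group-level Face-only, Situation-only and cue-integration tables over the
#' shared stimuli (all stimulus-by-emotion cells), yielding the participant's
#' face-reliance, situation-reliance and cue-integration estimates. Fisher
#' z transforms are stored and the best-fitting model recorded via
#' [classify_best_model()]. A participant with zero variance across cells is
#' flagged unusable (`usable = FALSE`, all estimates `NA`).
#'
#' @param participant_table The participant's `probability_table` (joint cue).
#' @param situation,face,integration Group-level model tables covering the
#'   participant's stimuli (extra stimuli in the model tables are fine).
#' @param participant_id Identifier carried into the result.
#' @return A `participant_estimates`: list with `participant_id`, `n_pairs`,
#'   `r_face`, `r_situation`, `r_integration`, matching `z_*` values,
#'   `best_model` and `usable`.
#' @export
reliance_estimates <- function(participant_table, situation, face, integration,
                               participant_id = "participant") {
  models <- list(situation = as_prob_table(situation),
                 face = as_prob_table(face),
                 integration = as_prob_table(integration))
  shared <- Reduce(intersect, c(list(rownames(participant_table)),
                                lapply(models, rownames)))
  if (length(shared) < 3L) {
    stop("reliance_estimates: fewer than 3 shared stimuli with the model tables")
  }
  emotions <- colnames(participant_table)
  for (nm in names(models)) {
    if (!identical(colnames(models[[nm]]), emotions)) {
      stop(sprintf("emotion axes differ between participant and %s table", nm))
    }
  }
  p <- as.numeric(unclass(participant_table)[shared, , drop = FALSE])
  n <- length(p)
  if (stats::sd(p) == 0) {
    out <- list(participant_id = participant_id, n_pairs = n,
                r_face = NA_real_, r_situation = NA_real_,
                r_integration = NA_real_, z_face = NA_real_,
                z_situation = NA_real_, z_integration = NA_real_,
                best_model = NA_character_, usable = FALSE)
    return(structure(out, class = "participant_estimates"))
  }
  r <- vapply(models, function(m) {
    stats::cor(p, as.numeric(unclass(m)[shared, , drop = FALSE]))
  }, numeric(1))
  structure(list(
    participant_id = participant_id, n_pairs = n,
    r_face = r[["face"]], r_situation = r[["situation"]],
    r_integration = r[["integration"]],
    z_face = fisher_z(r[["face"]]), z_situation = fisher_z(r[["situation"]]),
    z_integration = fisher_z(r[["integration"]]),
    best_model = classify_best_model(r[["face"]], r[["situation"]],
                                     r[["integration"]]),
    usable = TRUE
  ), class = "participant_estimates")
}

#' @export
print.participant_estimates <- function(x, ...) {
  cat(sprintf(
    "participant_estimates [%s]: r_face = %.3f, r_situation = %.3f, r_integration = %.3f; best = %s (n = %d)\n",
    x$participant_id, x$r_face, x$r_situation, x$r_integration,
    x$best_model, x$n_pairs))
  invisible(x)
}

#' Classify each participant's best-fitting model
#'
#' Argmax over the three cue-reliance correlations. Exact ties are broken by
#' the fixed precedence situation > integration > face, favouring the simpler
#' single-cue account.
#'
#' @param r_face,r_situation,r_integration Numeric vectors of correlations
#'   (recycled to a common length).
#' @return Character vector of `"situation"`, `"integration"` or `"face"`;
#'   `NA` where any input is non-finite.
#' @export
#' @examples
#' classify_best_model(0.3, 0.7, 0.5)
classify_best_model <- function(r_face, r_situation, r_integration) {
  n <- max(length(r_face), length(r_situation), length(r_integration))
  r <- cbind(situation = rep_len(r_situation, n),
             integration = rep_len(r_integration, n),
             face = rep_len(r_face, n))
  out <- rep(NA_character_, n)
  ok <- apply(is.finite(r), 1L, all)
  # which.max takes the first maximum, so column order encodes the tie rule
  out[ok] <- colnames(r)[apply(r[ok, , drop = FALSE], 1L, which.max)]
  out
}

#' Cohort shares of each best-fitting model
#'
#' @param best_model Character vector of per-participant labels from
#'   [classify_best_model()]; `NA`s are dropped.
#' @return Named numeric vector of percentages for `situation`,
#'   `integration`, `face`.
#' @export
best_model_shares <- function(best_model) {
  best_model <- best_model[!is.na(best_model)]
  levels <- c("situation", "integration", "face")
  counts <- table(factor(best_model, levels = levels))
  out <- 100 * as.numeric(counts) / max(1L, length(best_model))
  names(out) <- levels
  out
}

#' Estimate cue-reliance for every participant in a rating set
#'
#' Runs [participant_probability_table()] and [reliance_estimates()] for each
#' participant in a cleaned joint-cue rating set against fixed group-level
#' model tables, returning one row per participant.
#'
#' @param records Cleaned rating data frame (joint condition) for a cohort.
#' @param situation,face,integration Group-level model tables.
#' @param emotions Ordered category list.
#' @return Data frame with one row per usable participant: `participant_id`,
#'   `n_pairs`, `r_*`, `z_*`, `best_model`.
#' @export
estimate_cohort <- function(records, situation, face, integration,
                            emotions = emotion_categories()) {
  ids <- unique(as.character(records$participant_id))
  chunks <- split(records, factor(records$participant_id, levels = ids))
  rows <- lapply(ids, function(id) {
    tab <- participant_probability_table(chunks[[id]], emotions = emotions)
    est <- reliance_estimates(tab, situation, face, integration,
                              participant_id = id)
    if (!est$usable) return(NULL)
    as.data.frame(est[c("participant_id", "n_pairs", "r_face", "r_situation",
                        "r_integration", "z_face", "z_situation",
                        "z_integration", "best_model")],
                  stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag multivariate outliers by Mahalanobis distance
#'
#' Squared Mahalanobis distances of each row from the column-mean vector
#' under the classical sample covariance; rows exceeding the chi-square
#' quantile at `1 - alpha` with df equal to the number of columns are
#' flagged.
#'
#' @param z_matrix Numeric matrix (participants in rows, estimate columns),
#'   with more rows than columns and finite entries.
#' @param alpha Tail probability for the chi-square cutoff (default 0.001).
#' @return Character vector (or row indices when unnamed) of flagged rows,
#'   with the squared distances and the cutoff attached as attributes
#'   `distances` and `cutoff`.
#' @export
mahalanobis_outliers <- function(z_matrix, alpha = 0.001) {
  z <- as.matrix(z_matrix)
  if (anyNA(z) || any(!is.finite(z))) {
    stop("mahalanobis_outliers: entries must be finite")
  }
  if (nrow(z) <= ncol(z)) {
    stop("mahalanobis_outliers: need more rows than columns to estimate the covariance")
  }
  S <- stats::cov(z)
  if (rcond_sym(S) < .Machine$double.eps * 100) {
    stop("mahalanobis_outliers: covariance is singular; prune collinear columns")
  }
  d2 <- stats::mahalanobis(z, colMeans(z), S)
  cutoff <- stats::qchisq(1 - alpha, df = ncol(z))
  flagged <- which(d2 > cutoff)
  ids <- if (!is.null(rownames(z))) rownames(z)[flagged] else flagged
  structure(ids, distances = d2, cutoff = cutoff)
}

rcond_sym <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(0)
  min(ev) / max(ev)
}

#' Bonferroni-adjusted Pearson association with a covariate
#'
#' Two-tailed Pearson correlation between a (Fisher-z) cue-reliance estimate
#' and a participant covariate, with `t = r * sqrt((n - 2) / (1 - r^2))`, the
#' Bonferroni-adjusted p value (raw p multiplied by the family size, capped
#' at 1) and a 95% confidence interval from the Fisher-z interval.
#'
#' @param estimate Numeric vector of per-participant estimates.
#' @param covariate Numeric vector of the covariate, same order.
#' @param n_tests Bonferroni family size (number of estimate-by-covariate
#'   tests in the study run); default 1.
#' @param estimate_name,covariate_name Labels for the report.
#' @return A `covariate_association`: list with `r`, `t_stat`, `df`, `p_raw`,
#'   `p_adjusted`, `ci_low`, `ci_high`, `n`, `n_tests` and the labels.
#' @export
covariate_association <- function(estimate, covariate, n_tests = 1L,
                                  estimate_name = "estimate",
                                  covariate_name = "covariate") {
  keep <- is.finite(estimate) & is.finite(covariate)
  x <- estimate[keep]
  y <- covariate[keep]
  n <- length(x)
  if (n < 4L) stop("covariate_association: need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("covariate_association: zero variance on one side")
  }
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p_raw <- 2 * stats::pt(-abs(tstat), df = n - 2)
  z <- fisher_z(r)
  half <- stats::qnorm(0.975) / sqrt(n - 3)
  structure(list(
    estimate_name = estimate_name, covariate_name = covariate_name,
    r = r, t_stat = tstat, df = n - 2L,
    p_raw = p_raw, p_adjusted = min(1, p_raw * n_tests),
    ci_low = tanh(z - half), ci_high = tanh(z + half),
    n = n, n_tests = as.integer(n_tests)
  ), class = "covariate_association")
}

#' @export
print.covariate_association <- function(x, ...) {
  cat(sprintf(
    "covariate_association [%s ~ %s]: r(%d) = %.3f, t = %.3f, p(adj, %d tests) = %.3g, 95%% CI [%.3f, %.3f]\n",
    x$estimate_name, x$covariate_name, x$df, x$r, x$t_stat, x$n_tests,
    x$p_adjusted, x$ci_low, x$ci_high))
  invisible(x)
}

#' Test-retest intraclass correlation (two-way, single measure, consistency)
#'
#' Quantifies the consistency of per-participant cue-reliance estimates
#' across two sessions with the two-way mixed, single-measure, consistency
#' form of the intraclass correlation, `ICC(C,1) = (MS_rows - MS_error) /
#' (MS_rows + (k - 1) MS_error)` from the participants-by-sessions two-way
#' decomposition. Its F statistic `MS_rows / MS_error` has degrees of freedom
#' `(n - 1, (n - 1)(k - 1))` -- `(n - 1, n - 1)` for two sessions -- and the
#' 95% confidence interval comes from the F-based interval. The two-tailed p
#' value doubles the smaller tail of the F distribution.
#'
#' @param session1,session2 Numeric vectors of per-participant estimates,
#'   aligned by participant (named vectors are matched and mismatches are an
#'   error).
#' @param type `"consistency"` (default) or `"agreement"` (ICC(A,1)).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A `reliability_result`: list with `icc`, `f_stat`, `df1`, `df2`,
#'   `p`, `ci_low`, `ci_high`, `n_subjects`, `k_sessions`, `type`.
#' @export
icc_consistency <- function(session1, session2,
                            type = c("consistency", "agreement"),
                            conf_level = 0.95) {
  type <- match.arg(type)
  if (!is.null(names(session1)) && !is.null(names(session2))) {
    only1 <- setdiff(names(session1), names(session2))
    only2 <- setdiff(names(session2), names(session1))
    if (length(only1) || length(only2)) {
      stop(sprintf("participant sets differ: only in session 1: [%s]; only in session 2: [%s]",
                   paste(only1, collapse = ", "),
                   paste(only2, collapse = ", ")))
    }
    session2 <- session2[names(session1)]
  }
  if (length(session1) != length(session2)) {
    stop("icc_consistency: sessions have different lengths")
  }
  keep <- is.finite(session1) & is.finite(session2)
  x <- cbind(session1[keep], session2[keep])
  n <- nrow(x)
  k <- 2L
  if (n < 5L) stop("icc_consistency: need at least 5 participants")
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  df1 <- n - 1L
  df2 <- (n - 1L) * (k - 1L)
  alpha <- 1 - conf_level
  if (mse <= .Machine$double.eps * msr) {
    # identical sessions: perfect consistency, F degenerate
    out <- list(icc = 1, f_stat = Inf, df1 = df1, df2 = df2, p = 0,
                ci_low = 1, ci_high = 1, n_subjects = n, k_sessions = k,
                type = type)
    return(structure(out, class = "reliability_result"))
  }
  if (type == "consistency") {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    fobs <- msr / mse
    fl <- fobs / stats::qf(1 - alpha / 2, df1, df2)
    fu <- fobs * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    fobs <- msr / mse
    # Shrout-Fleiss style interval for ICC(A,1)
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_low <- stats::qf(1 - alpha / 2, n - 1, v)
    f_up <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_low * mse) /
      (f_low * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_up * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_up * msr)
    ci <- c(lower, upper)
  }
  p_upper <- stats::pf(fobs, df1, df2, lower.tail = FALSE)
  structure(list(
    icc = icc, f_stat = fobs, df1 = df1, df2 = df2,
    p = min(1, 2 * min(p_upper, 1 - p_upper)),
    ci_low = ci[1], ci_high = ci[2],
    n_subjects = n, k_sessions = k, type = type
  ), class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf(
    "reliability_result (%s): ICC = %.3f, F(%d, %d) = %.3f, p = %.3g, 95%% CI [%.3f, %.3f], n = %d\n",
    x$type, x$icc, x$df1, x$df2, x$f_stat, x$p, x$ci_low, x$ci_high,
    x$n_subjects))
  invisible(x)
}
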