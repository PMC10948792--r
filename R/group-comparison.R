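#' Fisher r-to-z transform
#'
#' Variance-stabilizing transform `atanh(r)` applied before averaging or
#' correlating correlation coefficients. Inputs with `|r| >= 1 - 1e-7` are
#' clamped so degenerate perfect-fit correlations stay finite.
#'
#' @param r Numeric vector of correlations in \[-1, 1\].
#' @return `atanh` of the (clamped) input.
#' @export
#' @examples
#' fisher_z(c(-0.5, 0, 0.5, 1))
fisher_z <- function(r) {
  lim <- 1 - 1e-7
  atanh(pmin(pmax(r, -lim), lim))
}

#' Flatten matched probability tables into paired observation vectors
#'
#' Pairs every stimulus-by-emotion cell of the empirical table with the
#' corresponding model cell, optionally restricted to a single emotion
#' category (one pair per stimulus). With the full 604-stimulus, 13-category
#' design this yields 7852 pairs overall and 604 per category.
#'
#' @param empirical,model `probability_table`s with identical axes (an
#'   `integration_result` is accepted for either).
#' @param emotion Optional single category; restricts pairs to that column.
#' @return Data frame with columns `stimulus_id`, `emotion`, `empirical`,
#'   `model`.
#' @export
flatten_pairs <- function(empirical, model, emotion = NULL) {
  empirical <- as_prob_table(empirical)
  model <- as_prob_table(model)
  check_axes(empirical, model, what = c("empirical", "model"))
  if (!is.null(emotion)) {
    if (!emotion %in% colnames(empirical)) {
      stop(sprintf("emotion '%s' not in the table categories", emotion))
    }
    return(data.frame(stimulus_id = rownames(empirical),
                      emotion = emotion,
                      empirical = as.numeric(empirical[, emotion]),
                      model = as.numeric(model[, emotion]),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    stimulus_id = rep(rownames(empirical), times = ncol(empirical)),
    emotion = rep(colnames(empirical), each = nrow(empirical)),
    empirical = as.numeric(unclass(empirical)),
    model = as.numeric(unclass(model)),
    stringsAsFactors = FALSE
  )
}

as_prob_table <- function(x) {
  if (inherits(x, "integration_result")) x$table else x
}

#' Score a model table against empirical joint-cue probabilities
#'
#' Computes the two-tailed Pearson correlation and root-mean-squared error
#' between the model's stimulus-by-emotion probabilities and the empirical
#' ones, with 95% percentile bootstrap confidence intervals obtained by
#' resampling the (stimulus, emotion) observation pairs. The Fisher z
#' transform of r, the t statistic `t = r * sqrt((n-2)/(1-r^2))` and its
#' two-tailed p value are stored alongside.
#'
#' @param empirical,model `probability_table`s with identical axes.
#' @param B Number of bootstrap replicates (default 10000).
#' @param seed Integer seed for the bootstrap; mandatory for reproducibility.
#' @param model_name Label stored in the fit.
#' @param emotion Optional single category to score (pairs are then stimuli).
#' @param resample One of `"pairs"` (default; resample individual
#'   stimulus-by-emotion observation pairs) or `"stimuli"` (resample whole
#'   stimulus rows).
#' @return A `model_fit`: list with `model_name`, `n_pairs`, `r`, `z`, `t`,
#'   `df`, `p`, `rmse`, `ci_low`, `ci_high`, `rmse_ci_low`, `rmse_ci_high`,
#'   `B`, `seed`.
#' @export
fit_model <- function(empirical, model, B = 10000L, seed,
                      model_name = "model", emotion = NULL,
                      resample = c("pairs", "stimuli")) {
  resample <- match.arg(resample)
  if (missing(seed)) stop("fit_model: a seed is required")
  pairs <- flatten_pairs(empirical, model, emotion = emotion)
  e <- pairs$empirical
  m <- pairs$model
  n <- length(e)
  if (n < 3L) stop("fit_model: need at least 3 pairs")
  if (any(!is.finite(e)) || any(!is.finite(m))) {
    stop("fit_model: non-finite values in the pairs")
  }
  if (stats::sd(e) == 0) stop("fit_model: zero variance on the empirical side")
  if (stats::sd(m) == 0) stop("fit_model: zero variance on the model side")
  r <- stats::cor(e, m)
  rmse <- sqrt(mean((e - m)^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  boot <- if (resample == "pairs") {
    boot_pairs(e, m, B = B, seed = seed)
  } else {
    boot_rows(unclass(as_prob_table(empirical)), unclass(as_prob_table(model)),
              B = B, seed = seed, emotion = emotion)
  }
  ci_r <- stats::quantile(boot$r, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
  ci_rmse <- stats::quantile(boot$rmse, c(0.025, 0.975), names = FALSE,
                             na.rm = TRUE)
  structure(list(
    model_name = model_name, n_pairs = n,
    r = r, z = fisher_z(r), t = tstat, df = n - 2L,
    p = 2 * stats::pt(-abs(tstat), df = n - 2),
    rmse = rmse,
    ci_low = ci_r[1], ci_high = ci_r[2],
    rmse_ci_low = ci_rmse[1], rmse_ci_high = ci_rmse[2],
    B = as.integer(B), seed = as.integer(seed), resample = resample
  ), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf(
    "model_fit [%s]: r(%d) = %.3f, 95%% CI [%.3f, %.3f]; RMSE = %.3f [%.3f, %.3f]; t = %.2f, p = %.3g (B = %d)\n",
    x$model_name, x$df, x$r, x$ci_low, x$ci_high, x$rmse,
    x$rmse_ci_low, x$rmse_ci_high, x$t, x$p, x$B))
  invisible(x)
}

#' Percentile bootstrap confidence interval for a Pearson correlation
#'
#' Resamples the paired observations with replacement and returns the
#' percentile interval of the correlation across replicates. This is the
#' interval construction [fit_model()] uses for its model-fit correlations,
#' exposed for arbitrary paired data.
#'
#' @param x,y Paired numeric vectors.
#' @param B Number of bootstrap replicates (default 10000).
#' @param seed Integer seed (mandatory).
#' @param conf_level Confidence level (default 0.95).
#' @return Numeric vector `c(low, high)` with the observed correlation as
#'   attribute `r` and the replicate count as `B`.
#' @export
bootstrap_cor_ci <- function(x, y, B = 10000L, seed, conf_level = 0.95) {
  if (missing(seed)) stop("bootstrap_cor_ci: a seed is required")
  if (length(x) != length(y)) stop("x and y must have equal length")
  boot <- boot_pairs(x, y, B = B, seed = seed)
  a <- (1 - conf_level) / 2
  ci <- stats::quantile(boot$r, c(a, 1 - a), names = FALSE, na.rm = TRUE)
  structure(ci, r = stats::cor(x, y), B = as.integer(B))
}

# Vectorized pair-resampling bootstrap of Pearson r and RMSE; chunked so the
# index matrices stay small at large n and B.
boot_pairs <- function(e, m, B, seed, chunk = 500L) {
  set.seed(seed)
  n <- length(e)
  r <- numeric(B)
  rmse <- numeric(B)
  done <- 0L
  while (done < B) {
    k <- min(chunk, B - done)
    idx <- matrix(sample.int(n, n * k, replace = TRUE), nrow = n)
    E <- matrix(e[idx], nrow = n)
    M <- matrix(m[idx], nrow = n)
    res <- cor_rmse_cols(E, M)
    r[done + seq_len(k)] <- res$r
    rmse[done + seq_len(k)] <- res$rmse
    done <- done + k
  }
  list(r = r, rmse = rmse)
}

# Column-wise Pearson r and RMSE for two matrices of bootstrap replicates.
cor_rmse_cols <- function(E, M) {
  n <- nrow(E)
  me <- colMeans(E)
  mm <- colMeans(M)
  cov <- colMeans(E * M) - me * mm
  ve <- colMeans(E * E) - me^2
  vm <- colMeans(M * M) - mm^2
  r <- cov / sqrt(ve * vm)
  r[ve <= 0 | vm <= 0] <- NA_real_
  list(r = r, rmse = sqrt(colMeans((E - M)^2)))
}

# Stimulus-row resampling bootstrap (alternative resampling unit).
boot_rows <- function(E, M, B, seed, emotion = NULL, chunk = 200L) {
  set.seed(seed)
  ns <- nrow(E)
  if (!is.null(emotion)) {
    E <- E[, emotion, drop = FALSE]
    M <- M[, emotion, drop = FALSE]
  }
  r <- numeric(B)
  rmse <- numeric(B)
  for (b in seq_len(B)) {
    idx <- sample.int(ns, ns, replace = TRUE)
    e <- as.numeric(E[idx, ])
    m <- as.numeric(M[idx, ])
    if (stats::sd(e) == 0 || stats::sd(m) == 0) {
      r[b] <- NA_real_
      rmse[b] <- sqrt(mean((e - m)^2))
    } else {
      r[b] <- stats::cor(e, m)
      rmse[b] <- sqrt(mean((e - m)^2))
    }
  }
  list(r = r, rmse = rmse)
}

#' Hotelling--Williams test for two dependent overlapping correlations
#'
#' Tests whether two models correlate differently with the same empirical
#' vector, accounting for the correlation between the two model vectors. Both
#' model-vs-empirical correlations share the empirical side, so the ordinary
#' independent-samples comparison does not apply; the Williams modification of
#' Hotelling's test is the standard remedy:
#' \deqn{t = (r_{ae} - r_{be}) \sqrt{\frac{(n-1)(1+r_{ab})}
#'   {2 \frac{n-1}{n-3} |R| + \bar r^2 (1 - r_{ab})^3}}}
#' with \eqn{|R| = 1 - r_{ae}^2 - r_{be}^2 - r_{ab}^2 + 2 r_{ae} r_{be} r_{ab}}
#' and \eqn{\bar r = (r_{ae} + r_{be})/2}.
#'
#' The conventional degrees of freedom for this statistic are `n - 3`; the
#' reported `df` follows the `n - 2` convention used when quoting paired
#' correlation comparisons alongside the correlations themselves, and both are
#' stored. The two-tailed p value uses the reported df.
#'
#' @param r_ae Correlation of model A with the empirical vector.
#' @param r_be Correlation of model B with the empirical vector.
#' @param r_ab Correlation between the two model vectors.
#' @param n Number of observation pairs (must be at least 4).
#' @param model_a,model_b Labels for the report.
#' @return A `correlation_difference`: list with `model_a`, `model_b`,
#'   `t_stat`, `df` (reported, `n - 2`), `df_conventional` (`n - 3`), `p`
#'   (two-tailed).
#' @export
#' @examples
#' dependent_correlation_test(0.865, 0.840, 0.9, n = 7852)
dependent_correlation_test <- function(r_ae, r_be, r_ab, n,
                                       model_a = "A", model_b = "B") {
  rs <- c(r_ae = r_ae, r_be = r_be, r_ab = r_ab)
  if (any(!is.finite(rs)) || any(abs(rs) >= 1)) {
    stop("dependent_correlation_test: correlations must lie strictly inside (-1, 1)")
  }
  if (n < 4) stop("dependent_correlation_test: need n >= 4")
  n <- as.integer(n)
  detR <- 1 - r_ae^2 - r_be^2 - r_ab^2 + 2 * r_ae * r_be * r_ab
  rbar <- (r_ae + r_be) / 2
  denom <- 2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r_ab)^3
  t_stat <- (r_ae - r_be) * sqrt((n - 1) * (1 + r_ab) / denom)
  df <- n - 2L
  structure(list(
    model_a = model_a, model_b = model_b,
    t_stat = t_stat, df = df, df_conventional = n - 3L,
    p = 2 * stats::pt(-abs(t_stat), df = df),
    delta_r = r_ae - r_be
  ), class = "correlation_difference")
}

#' @export
print.correlation_difference <- function(x, ...) {
  cat(sprintf("correlation_difference [%s vs %s]: t(%d) = %.3f, p = %.3g",
              x$model_a, x$model_b, x$df, x$t_stat, x$p))
  if (!is.null(x$delta_ci_low)) {
    cat(sprintf("; bootstrap 95%% CI of delta r: [%.3f, %.3f]%s",
                x$delta_ci_low, x$delta_ci_high,
                if (isTRUE(x$significant)) " *" else ""))
  }
  cat("\n")
  invisible(x)
}

#' Bootstrap contrast of two models' fit within one emotion category
#'
#' For one emotion column, stimuli are resampled with replacement; each
#' replicate records the difference `r_a - r_b` between the two models'
#' correlations with the empirical column. The 95% percentile interval of the
#' differences is returned, with the contrast called significant when the
#' interval excludes zero. Replicates in which either correlation is undefined
#' (zero variance after resampling) are redrawn and counted.
#'
#' @param empirical,model_a,model_b `probability_table`s with identical axes.
#' @param emotion Category to contrast.
#' @param B Bootstrap replicates (default 10000).
#' @param seed Integer seed.
#' @param model_names Labels for the two models in the report.
#' @return A `correlation_difference` with `delta_ci_low`, `delta_ci_high`,
#'   `significant`, `n_redrawn`, plus the observed `delta_r` and labels.
#' @export
per_emotion_bootstrap_difference <- function(empirical, model_a, model_b,
                                             emotion, B = 10000L, seed,
                                             model_names = c("A", "B")) {
  if (missing(seed)) stop("per_emotion_bootstrap_difference: a seed is required")
  pa <- flatten_pairs(empirical, model_a, emotion = emotion)
  pb <- flatten_pairs(empirical, model_b, emotion = emotion)
  e <- pa$empirical
  a <- pa$model
  b <- pb$model
  n <- length(e)
  if (n < 3L) stop("need at least 3 stimuli for a per-emotion contrast")
  set.seed(seed)
  diffs <- numeric(B)
  n_redrawn <- 0L
  filled <- 0L
  while (filled < B) {
    k <- min(500L, B - filled)
    idx <- matrix(sample.int(n, n * k, replace = TRUE), nrow = n)
    E <- matrix(e[idx], nrow = n)
    ra <- cor_rmse_cols(E, matrix(a[idx], nrow = n))$r
    rb <- cor_rmse_cols(E, matrix(b[idx], nrow = n))$r
    d <- ra - rb
    ok <- is.finite(d)
    n_redrawn <- n_redrawn + sum(!ok)
    d <- d[ok]
    take <- min(length(d), B - filled)
    diffs[filled + seq_len(take)] <- d[seq_len(take)]
    filled <- filled + take
  }
  ci <- stats::quantile(diffs, c(0.025, 0.975), names = FALSE)
  r_a <- stats::cor(e, a)
  r_b <- stats::cor(e, b)
  structure(list(
    model_a = model_names[1], model_b = model_names[2], emotion = emotion,
    delta_r = r_a - r_b,
    delta_ci_low = ci[1], delta_ci_high = ci[2],
    significant = ci[1] > 0 || ci[2] < 0,
    n_redrawn = n_redrawn, B = as.integer(B), seed = as.integer(seed),
    n_stimuli = n
  ), class = "correlation_difference")
}

#' Build the empirical table and the three model tables from a rating set
#'
#' Aggregates a cleaned three-condition rating set into the empirical
#' joint-cue table and the Situation-only, Face-only and cue-integration
#' model tables (the latter via [integrate_cues()] with the supplied prior).
#'
#' @param records Cleaned rating data frame covering the `situation_only`,
#'   `face_only` and `joint` conditions.
#' @param prior A `prior_vector` (e.g. from [prior_vector()]).
#' @param emotions Ordered category list.
#' @param flat_prior Use the flat-prior integration variant?
#' @return List with `empirical`, `situation`, `face` (`probability_table`s)
#'   and `integration` (an `integration_result`).
#' @export
group_model_tables <- function(records, prior,
                               emotions = emotion_categories(),
                               flat_prior = FALSE) {
  situation <- condition_probability_table(records, "situation_only", emotions)
  face <- condition_probability_table(records, "face_only", emotions)
  list(
    empirical = condition_probability_table(records, "joint", emotions),
    situation = situation,
    face = face,
    integration = integrate_cues(situation, face, prior,
                                 flat_prior = flat_prior)
  )
}

#' Compare the three candidate models against empirical joint-cue data
#'
#' Convenience wrapper running [fit_model()] for the Face-only,
#' Situation-only and cue-integration tables against the empirical joint-cue
#' table, plus all pairwise Hotelling--Williams contrasts.
#'
#' @param empirical Empirical joint-cue `probability_table`.
#' @param situation,face `probability_table`s for the single-cue models.
#' @param integration `probability_table` or `integration_result` for the
#'   cue-integration model.
#' @param B Bootstrap replicates per fit.
#' @param seed Integer seed.
#' @return List with `fits` (named list of `model_fit`) and `contrasts`
#'   (named list of `correlation_difference`).
#' @export
compare_models <- function(empirical, situation, face, integration,
                           B = 10000L, seed) {
  if (missing(seed)) stop("compare_models: a seed is required")
  models <- list(situation = as_prob_table(situation),
                 face = as_prob_table(face),
                 integration = as_prob_table(integration))
  fits <- Map(function(tab, nm) {
    fit_model(empirical, tab, B = B, seed = seed, model_name = nm)
  }, models, names(models))
  pairs <- utils::combn(names(models), 2, simplify = FALSE)
  contrasts <- lapply(pairs, function(pr) {
    a <- models[[pr[1]]]
    b <- models[[pr[2]]]
    r_ab <- stats::cor(as.numeric(unclass(a)), as.numeric(unclass(b)))
    dependent_correlation_test(fits[[pr[1]]]$r, fits[[pr[2]]]$r, r_ab,
                               n = fits[[pr[1]]]$n_pairs,
                               model_a = pr[1], model_b = pr[2])
  })
  names(contrasts) <- vapply(pairs, paste, "", collapse = "_vs_")
  list(fits = fits, contrasts = contrasts)
}
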