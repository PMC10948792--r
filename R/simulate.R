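#' Specify a synthetic stimulus space
#'
#' The generator emulates the generative structure the analysis assumes: each
#' stimulus has a situation-conditional emotion distribution (a Dirichlet
#' draw), and a face-conditional distribution that is a mixture of the
#' situation row (weight `face_informativeness`) and an independent Dirichlet
#' draw, so `face_informativeness = 1` makes the face cue a copy of the
#' situation cue and `0` makes it independent. An optional `category_boost`
#' injects extra, stimulus-varying diagnostic signal into the face cue for
#' named categories (the happiness analogue: a category whose facial
#' expressions carry information perceivers actually use).
#'
#' Defaults mirror the individual-difference study design: 44 stimuli, 13
#' emotion categories, concentration 0.7 (sparse, peaked consensus-like
#' rows), face informativeness 0.9.
#'
#' @param n_stimuli Number of stimulus pairs (default 44).
#' @param emotions Ordered category list.
#' @param concentration Dirichlet concentration for the rows (default 0.7).
#' @param face_informativeness Mixture weight in \[0, 1\] (default 0.9).
#' @param category_boost Named numeric vector: extra face diagnosticity per
#'   category (each value non-negative; `NULL` for none).
#' @param seed Integer seed (mandatory).
#' @return A `stimulus_space_spec` list.
#' @export
stimulus_space_spec <- function(n_stimuli = 44L,
                                emotions = emotion_categories(),
                                concentration = 0.7,
                                face_informativeness = 0.9,
                                category_boost = NULL,
                                seed) {
  if (missing(seed)) stop("stimulus_space_spec: a seed is required")
  if (n_stimuli < 1L) stop("n_stimuli must be positive")
  if (concentration <= 0) stop("concentration must be positive")
  if (face_informativeness < 0 || face_informativeness > 1) {
    stop("face_informativeness must lie in [0, 1]")
  }
  if (!is.null(category_boost)) {
    if (is.null(names(category_boost)) ||
        !all(names(category_boost) %in% emotions)) {
      stop("category_boost must be named with known emotion categories")
    }
    if (any(category_boost < 0)) stop("category_boost values must be >= 0")
  }
  structure(list(n_stimuli = as.integer(n_stimuli), emotions = emotions,
                 concentration = concentration,
                 face_informativeness = face_informativeness,
                 category_boost = category_boost, seed = as.integer(seed)),
            class = "stimulus_space_spec")
}

# Dirichlet draws via normalized gamma variates.
rdirichlet_rows <- function(n, alpha, k) {
  g <- matrix(stats::rgamma(n * k, shape = alpha, rate = 1), nrow = n)
  g / rowSums(g)
}

#' Simulate a stimulus space
#'
#' Draws the situation table, face table and global prior for a
#' [stimulus_space_spec()]. Fully reproducible: the same spec (including its
#' seed) always produces identical tables.
#'
#' @param spec A `stimulus_space_spec`.
#' @return List with `situation` and `face` (`probability_table`s), `prior`
#'   (a `prior_vector`), and the `spec`.
#' @export
simulate_stimulus_space <- function(spec) {
  stopifnot(inherits(spec, "stimulus_space_spec"))
  set.seed(spec$seed)
  k <- length(spec$emotions)
  n <- spec$n_stimuli
  ids <- sprintf("stim_%03d", seq_len(n))
  S <- rdirichlet_rows(n, spec$concentration, k)
  D <- rdirichlet_rows(n, spec$concentration, k)
  w <- spec$face_informativeness
  F_raw <- w * S + (1 - w) * D
  if (!is.null(spec$category_boost)) {
    for (cat in names(spec$category_boost)) {
      j <- match(cat, spec$emotions)
      beta <- spec$category_boost[[cat]]
      # independent, high-variance diagnostic signal in the face cue
      F_raw[, j] <- F_raw[, j] + beta * stats::rgamma(n, shape = 0.5, rate = 2)
    }
  }
  prior_raw <- as.numeric(rdirichlet_rows(1L, 2, k))
  list(
    situation = probability_table(S, stimulus_ids = ids,
                                  emotions = spec$emotions),
    face = probability_table(F_raw, stimulus_ids = ids,
                             emotions = spec$emotions),
    prior = new_prior_vector(prior_raw, emotions = spec$emotions),
    spec = spec
  )
}

#' Construct a synthetic rater profile
#'
#' A rater embodies one of the three competing accounts: a `situation` rater
#' whose joint-cue judgments track P(e|s), a `face` rater tracking P(e|f),
#' or an `integrator` tracking the Bayesian combination. `weight` blends the
#' type's target distribution with the uniform distribution (1 = pure type),
#' modelling how diagnostically the rater uses the cue; `noise_sd` is the
#' standard deviation of additive response noise on the 0--4 intensity scale;
#' `stability` governs how much of the rater's parameters persist across
#' retest sessions.
#'
#' @param rater_type One of `"face"`, `"situation"`, `"integrator"`.
#' @param noise_sd Non-negative response noise SD on the 0--4 scale.
#' @param weight Reliance weight in \[0, 1\] (default 1).
#' @param integration_weight Face-likelihood exponent in \[0, 1\] for
#'   integrator raters: the joint-cue target is proportional to
#'   `P(e|s) * (P(e|f)/P(e))^integration_weight`, so 1 is the full Bayesian
#'   combination and 0 collapses to the Situation-only account. Models
#'   conservative partial integration (default 1).
#' @param stability Across-session parameter persistence in \[0, 1\].
#' @param seed Integer seed for this rater's responses (mandatory).
#' @return A `rater_profile` list.
#' @export
rater_profile <- function(rater_type = c("situation", "face", "integrator"),
                          noise_sd = 0.5, weight = 1, integration_weight = 1,
                          stability = 1, seed) {
  rater_type <- match.arg(rater_type)
  if (missing(seed)) stop("rater_profile: a seed is required")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (weight < 0 || weight > 1) stop("weight must lie in [0, 1]")
  if (integration_weight < 0 || integration_weight > 1) {
    stop("integration_weight must lie in [0, 1]")
  }
  if (stability < 0 || stability > 1) stop("stability must lie in [0, 1]")
  structure(list(rater_type = rater_type, noise_sd = noise_sd,
                 weight = weight, integration_weight = integration_weight,
                 stability = stability, seed = as.integer(seed)),
            class = "rater_profile")
}

# The target probability row set for a profile in a given condition.
rater_targets <- function(space, profile, condition) {
  S <- unclass(space$situation)
  F_ <- unclass(space$face)
  base <- switch(condition,
    situation_only = S,
    face_only = F_,
    joint = switch(profile$rater_type,
      situation = S,
      face = F_,
      integrator = partial_integration(S, F_, as.numeric(space$prior),
                                       profile$integration_weight %||% 1)),
    stop(sprintf("unknown condition '%s'", condition)))
  w <- profile$weight
  w * base + (1 - w) / ncol(base)
}

# Row-normalized S * (F / prior)^g; g = 1 reproduces the full Bayesian
# cue-integration rule, g = 0 the Situation-only account.
partial_integration <- function(S, F_, prior, g) {
  raw <- S * sweep(F_, 2L, prior, "/")^g
  raw / rowSums(raw)
}

#' Simulate rating records from synthetic raters
#'
#' Each rater's target distribution per stimulus is the situation row, face
#' row, or their Bayesian combination depending on condition and rater type
#' (see [rater_profile()]). The expected intensity for each emotion is `4 *`
#' target probability; in the default `"gaussian"` mode this expectation is
#' perturbed by truncated Gaussian noise (SD `noise_sd`), truncated to
#' \[0, 4\] and rounded to the ordinal grid, and presence is intensity > 0. In
#' the alternative `"multinomial"` probability-matching mode the rater's
#' intensity budget of 4 points is allocated by a multinomial draw over the
#' target distribution.
#'
#' @param space Output of [simulate_stimulus_space()].
#' @param profiles List of [rater_profile()]s (one record set per profile and
#'   condition; participant ids are `r<index>`).
#' @param conditions Character subset of `"situation_only"`, `"face_only"`,
#'   `"joint"`.
#' @param mode `"gaussian"` (default) or `"multinomial"`.
#' @param session Optional session number stamped on the records.
#' @return Rating data frame with columns `participant_id`, `stimulus_id`,
#'   `condition`, `emotion`, `presence`, `intensity`, `session`, `quality`.
#' @export
simulate_raters <- function(space, profiles,
                            conditions = c("situation_only", "face_only",
                                           "joint"),
                            mode = c("gaussian", "multinomial"),
                            session = NA_integer_) {
  mode <- match.arg(mode)
  if (length(profiles) == 0L) stop("simulate_raters: empty profile list")
  if (inherits(profiles, "rater_profile")) profiles <- list(profiles)
  conditions <- match.arg(conditions, several.ok = TRUE)
  ids <- sprintf("r%03d", seq_along(profiles))
  out <- vector("list", length(profiles) * length(conditions))
  i <- 0L
  for (p in seq_along(profiles)) {
    prof <- profiles[[p]]
    set.seed(prof$seed)
    for (cond in conditions) {
      targets <- rater_targets(space, prof, cond)
      intensity <- draw_intensities(targets, prof$noise_sd, mode)
      i <- i + 1L
      out[[i]] <- data.frame(
        participant_id = ids[p],
        stimulus_id = rep(rownames(unclass(space$situation)),
                          times = ncol(targets)),
        condition = cond,
        emotion = rep(colnames(targets), each = nrow(targets)),
        presence = as.integer(intensity) > 0L,
        intensity = as.integer(intensity),
        session = session,
        quality = "valid",
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

draw_intensities <- function(targets, noise_sd, mode) {
  if (mode == "gaussian") {
    x <- 4 * targets
    if (noise_sd > 0) {
      x <- x + matrix(stats::rnorm(length(targets), sd = noise_sd),
                      nrow = nrow(targets))
    }
    matrix(as.integer(round(pmin(pmax(x, 0), 4))), nrow = nrow(targets))
  } else {
    t(apply(targets, 1L, function(p) {
      as.integer(stats::rmultinom(1L, size = 4L, prob = p))
    }))
  }
}

#' Simulate correlated retest sessions
#'
#' Draws a heterogeneous cohort of joint-cue raters and rates the same
#' stimulus space twice. Session-2 rater parameters are a stability-weighted
#' blend of the session-1 parameters and fresh draws: continuous parameters
#' (`noise_sd`, `weight`) are blended linearly, the rater type persists with
#' probability `stability`, and with `stability = 1` the session-1 response
#' seeds are reused so session 2 reproduces session 1 exactly.
#'
#' @param space Output of [simulate_stimulus_space()].
#' @param n_raters Cohort size.
#' @param stability Across-session persistence in \[0, 1\].
#' @param seed Integer seed (mandatory).
#' @param type_probs Probabilities of drawing each rater type
#'   (situation, face, integrator); default `c(0.55, 0.2, 0.25)` mirroring
#'   the observed predominance of situation reliance.
#' @param noise_range Range of per-rater `noise_sd` draws (uniform).
#' @param weight_range Range of per-rater reliance weights (uniform).
#' @param mode Response noise mode passed to [simulate_raters()].
#' @return List with `session1` and `session2` rating data frames (stamped
#'   `session = 1, 2`), and `profiles1`/`profiles2`.
#' @export
simulate_retest <- function(space, n_raters = 110L, stability, seed,
                            type_probs = c(situation = 0.55, face = 0.2,
                                           integrator = 0.25),
                            noise_range = c(0.3, 1.2),
                            weight_range = c(0.6, 1),
                            mode = "gaussian") {
  if (missing(seed)) stop("simulate_retest: a seed is required")
  if (missing(stability) || stability < 0 || stability > 1) {
    stop("simulate_retest: stability must lie in [0, 1]")
  }
  set.seed(seed)
  types <- c("situation", "face", "integrator")
  type1 <- sample(types, n_raters, replace = TRUE, prob = type_probs)
  noise1 <- stats::runif(n_raters, noise_range[1], noise_range[2])
  weight1 <- stats::runif(n_raters, weight_range[1], weight_range[2])
  seeds1 <- sample.int(.Machine$integer.max %/% 4L, n_raters)
  # fresh session-2 material, blended by stability
  type_new <- sample(types, n_raters, replace = TRUE, prob = type_probs)
  noise_new <- stats::runif(n_raters, noise_range[1], noise_range[2])
  weight_new <- stats::runif(n_raters, weight_range[1], weight_range[2])
  keep_type <- stats::runif(n_raters) < stability
  type2 <- ifelse(keep_type, type1, type_new)
  noise2 <- stability * noise1 + (1 - stability) * noise_new
  weight2 <- stability * weight1 + (1 - stability) * weight_new
  seeds2 <- if (stability >= 1) seeds1 else {
    sample.int(.Machine$integer.max %/% 4L, n_raters)
  }
  make_profiles <- function(type, noise, weight, seeds) {
    lapply(seq_len(n_raters), function(i) {
      rater_profile(type[i], noise_sd = noise[i], weight = weight[i],
                    stability = stability, seed = seeds[i])
    })
  }
  profiles1 <- make_profiles(type1, noise1, weight1, seeds1)
  profiles2 <- make_profiles(type2, noise2, weight2, seeds2)
  s1 <- simulate_raters(space, profiles1, conditions = "joint", mode = mode,
                        session = 1L)
  s2 <- simulate_raters(space, profiles2, conditions = "joint", mode = mode,
                        session = 2L)
  list(session1 = s1, session2 = s2,
       profiles1 = profiles1, profiles2 = profiles2)
}

#' Simulate a full three-condition study cohort
#'
#' Convenience wrapper generating independent rater cohorts for the
#' situation-only, face-only and joint conditions, mirroring the
#' between-subjects design in which separate participant groups rate each
#' condition. Default noise levels differ by condition: situation
#' descriptions are rated with little noise (0.5), facial portrayals are
#' ambiguous and rated noisily (1.25), and the joint condition -- where two
#' cues must be reconciled -- is noisiest (1.75). The default joint cohort
#' consists of conservative partial integrators (`integration_weight`
#' 0.5): perceivers combine the cues but discount the face likelihood, the
#' regime in which situation-only and cue-integration accounts fit group
#' data about equally well while face-only falls behind.
#'
#' @param space Output of [simulate_stimulus_space()].
#' @param n_per_condition Raters per condition (default 40, matching the
#'   roughly 40 ratings per stimulus in the archival design).
#' @param noise_sd Named numeric vector of response noise SDs per condition
#'   (`situation`, `face`, `joint`); a single number is recycled.
#' @param joint_type Rater type for the joint cohort: `"integrator"`
#'   (default), `"situation"`, `"face"`, or `"mixed"`, which draws each joint
#'   rater's type from `type_probs`.
#' @param integration_weight Face-likelihood exponent for integrator raters
#'   in the joint cohort (default 0.5; see [rater_profile()]).
#' @param type_probs Type mix for `joint_type = "mixed"`; default
#'   `c(situation = 0.55, face = 0.2, integrator = 0.25)`, mirroring the
#'   observed predominance of situation reliance.
#' @param seed Integer seed.
#' @param mode Response noise mode.
#' @return Rating data frame covering all three conditions (participant ids
#'   are prefixed by condition).
#' @export
simulate_study <- function(space, n_per_condition = 40L,
                           noise_sd = c(situation = 0.5, face = 1.25,
                                        joint = 1.75),
                           joint_type = "integrator",
                           integration_weight = 0.5,
                           type_probs = c(situation = 0.55, face = 0.2,
                                          integrator = 0.25),
                           seed, mode = "gaussian") {
  if (missing(seed)) stop("simulate_study: a seed is required")
  if (length(noise_sd) == 1L) {
    noise_sd <- c(situation = noise_sd, face = noise_sd, joint = noise_sd)
  }
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max %/% 4L,
                             3L * n_per_condition), nrow = 3L)
  joint_types <- if (joint_type == "mixed") {
    sample(c("situation", "face", "integrator"), n_per_condition,
           replace = TRUE, prob = type_probs)
  } else {
    rep(joint_type, n_per_condition)
  }
  cohort <- function(row, type, cond, nz, prefix, gw = 1) {
    type <- rep_len(type, n_per_condition)
    profiles <- lapply(seq_len(n_per_condition), function(i) {
      rater_profile(type[i], noise_sd = nz, integration_weight = gw,
                    seed = seeds[row, i])
    })
    rec <- simulate_raters(space, profiles, conditions = cond, mode = mode)
    rec$participant_id <- paste0(prefix, "_", rec$participant_id)
    rec
  }
  out <- rbind(
    cohort(1L, "situation", "situation_only", noise_sd[["situation"]], "s"),
    cohort(2L, "face", "face_only", noise_sd[["face"]], "f"),
    cohort(3L, joint_types, "joint", noise_sd[["joint"]], "j",
           gw = integration_weight)
  )
  rownames(out) <- NULL
  out
}
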