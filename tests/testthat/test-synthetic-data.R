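test_that("stimulus space simulation is deterministic under a fixed seed", {
  spec <- stimulus_space_spec(n_stimuli = 15, seed = 301)
  a <- simulate_stimulus_space(spec)
  b <- simulate_stimulus_space(spec)
  expect_identical(unclass(a$situation), unclass(b$situation))
  expect_identical(unclass(a$face), unclass(b$face))
  expect_identical(as.numeric(a$prior), as.numeric(b$prior))
  prof <- rater_profile("integrator", noise_sd = 0.4, seed = 17)
  r1 <- simulate_raters(a, list(prof), conditions = "joint")
  r2 <- simulate_raters(b, list(prof), conditions = "joint")
  expect_identical(r1, r2)
})

test_that("the generated tables satisfy the probability invariants", {
  space <- simulate_stimulus_space(stimulus_space_spec(seed = 302))
  expect_silent(emocue:::validate_probability_table(space$situation))
  expect_silent(emocue:::validate_probability_table(space$face))
  expect_equal(sum(space$prior), 1, tolerance = 1e-9)
  expect_true(all(space$prior > 0))
})

test_that("face_informativeness endpoints behave as specified", {
  full <- simulate_stimulus_space(stimulus_space_spec(
    n_stimuli = 30, seed = 303, face_informativeness = 1))
  expect_equal(unclass(full$face), unclass(full$situation), tolerance = 1e-12)
  none <- simulate_stimulus_space(stimulus_space_spec(
    n_stimuli = 500, seed = 304, face_informativeness = 0))
  rowcor <- sapply(seq_len(500), function(i) {
    cor(unclass(none$situation)[i, ], unclass(none$face)[i, ])
  })
  expect_lt(abs(mean(rowcor)), 0.1)
})

test_that("face-situation coupling increases with face_informativeness", {
  mean_rowcor <- function(w, seed) {
    sp <- simulate_stimulus_space(stimulus_space_spec(
      n_stimuli = 60, seed = seed, face_informativeness = w))
    mean(sapply(seq_len(60), function(i) {
      cor(unclass(sp$situation)[i, ], unclass(sp$face)[i, ])
    }))
  }
  for (seed in 311:315) {
    cors <- sapply(c(0.1, 0.5, 0.9), mean_rowcor, seed = seed)
    expect_true(all(diff(cors) > 0))
  }
})

test_that("spec validation rejects out-of-range parameters", {
  expect_error(stimulus_space_spec(seed = 1, concentration = 0),
               "concentration")
  expect_error(stimulus_space_spec(seed = 1, face_informativeness = 1.2),
               "face_informativeness")
  expect_error(stimulus_space_spec(seed = 1, category_boost = c(joy = 1)),
               "category_boost")
  expect_error(stimulus_space_spec(n_stimuli = 10), "seed")
  expect_error(rater_profile("situation", noise_sd = -1, seed = 1),
               "noise_sd")
  expect_error(rater_profile("situation"), "seed")
  expect_error(simulate_raters(simulate_stimulus_space(
    stimulus_space_spec(n_stimuli = 2, seed = 1)), list()), "empty")
})

test_that("a zero-noise integrator reproduces the integration table up to rounding", {
  space <- simulate_stimulus_space(stimulus_space_spec(seed = 321))
  target <- integrate_cues(space$situation, space$face, space$prior)$table
  recs <- simulate_raters(space,
                          list(rater_profile("integrator", noise_sd = 0,
                                             seed = 5)),
                          conditions = "joint")
  tab <- participant_probability_table(recs)
  keep <- setdiff(rownames(target), degenerate_rows(tab))
  expect_gt(cor(c(unclass(tab)[keep, ]), c(unclass(target)[keep, ])), 0.9)
  # without noise the table is exactly the row-normalized rounding of the
  # expected intensities 4 * P(e|s,f) onto the 0..4 grid
  grid <- round(4 * unclass(target))
  grid <- grid[keep, ] / rowSums(grid[keep, , drop = FALSE])
  expect_equal(unclass(tab)[keep, ], grid, tolerance = 1e-12)
})

test_that("a noisy cohort flows through the whole pipeline without error", {
  space <- simulate_stimulus_space(stimulus_space_spec(n_stimuli = 20,
                                                       seed = 322))
  recs <- simulate_study(space, n_per_condition = 8, noise_sd = 0.5,
                         seed = 323)
  cleaned <- correct_trials(recs)
  kept <- exclude_participants(cleaned$records, cleaned$report)
  tabs <- group_model_tables(kept$records, space$prior)
  for (tab in list(tabs$empirical, tabs$situation, tabs$face,
                   tabs$integration$table)) {
    expect_silent(emocue:::validate_probability_table(tab))
  }
  out <- compare_models(tabs$empirical, tabs$situation, tabs$face,
                        tabs$integration, B = 50, seed = 324)
  expect_true(all(sapply(out$fits, function(f) abs(f$r) <= 1)))
})

test_that("a pure situation-rater cohort is best fit by the Situation-only model", {
  wins <- sapply(1:5, function(s) {
    space <- simulate_stimulus_space(stimulus_space_spec(n_stimuli = 25,
                                                         seed = 330 + s))
    set.seed(340 + s)
    seeds <- matrix(sample.int(1e8, 60), nrow = 3)
    mk <- function(type, nz, row) lapply(1:20, function(i)
      rater_profile(type, noise_sd = nz, seed = seeds[row, i]))
    recs <- rbind(
      simulate_raters(space, mk("situation", 0.5, 1), "situation_only"),
      within(simulate_raters(space, mk("face", 0.5, 2), "face_only"),
             participant_id <- paste0("f", participant_id)),
      within(simulate_raters(space, mk("situation", 0.5, 3), "joint"),
             participant_id <- paste0("j", participant_id))
    )
    tabs <- group_model_tables(recs, space$prior)
    v <- function(x) c(unclass(x))
    rs <- c(situation = cor(v(tabs$empirical), v(tabs$situation)),
            face = cor(v(tabs$empirical), v(tabs$face)),
            integration = cor(v(tabs$empirical), v(tabs$integration$table)))
    names(which.max(rs)) == "situation"
  })
  expect_gte(sum(wins), 4)
})

test_that("probability-matching mode allocates the 4-point intensity budget", {
  space <- simulate_stimulus_space(stimulus_space_spec(n_stimuli = 10,
                                                       seed = 351))
  recs <- simulate_raters(space,
                          list(rater_profile("situation", seed = 6)),
                          conditions = "joint", mode = "multinomial")
  sums <- tapply(recs$intensity, recs$stimulus_id, sum)
  expect_true(all(sums == 4))
  expect_true(all(recs$presence == (recs$intensity > 0)))
})

test_that("retest sessions share parameters exactly at stability 1", {
  space <- simulate_stimulus_space(stimulus_space_spec(n_stimuli = 10,
                                                       seed = 361))
  rt <- simulate_retest(space, n_raters = 12, stability = 1, seed = 362)
  expect_identical(rt$session1$intensity, rt$session2$intensity)
  expect_identical(rt$session1$session, rep(1L, nrow(rt$session1)))
  expect_identical(rt$session2$session, rep(2L, nrow(rt$session2)))
  expect_error(simulate_retest(space, n_raters = 5, stability = 2, seed = 1),
               "stability")
  expect_error(simulate_retest(space, n_raters = 5, stability = 0.5),
               "seed")
})

test_that("parameter stability across sessions raises the reliability of estimates", {
  icc_of <- function(space, rt) {
    intg <- integrate_cues(space$situation, space$face, space$prior)$table
    e1 <- estimate_cohort(rt$session1, space$situation, space$face, intg)
    e2 <- estimate_cohort(rt$session2, space$situation, space$face, intg)
    icc_consistency(setNames(e1$z_situation, e1$participant_id),
                    setNames(e2$z_situation, e2$participant_id))$icc
  }
  res <- sapply(1:3, function(s) {
    space <- simulate_stimulus_space(stimulus_space_spec(seed = 370 + s))
    hi <- icc_of(space, simulate_retest(space, n_raters = 60, stability = 0.8,
                                        seed = 380 + s))
    lo <- icc_of(space, simulate_retest(space, n_raters = 60, stability = 0,
                                        seed = 380 + s))
    c(hi = hi, lo = lo)
  })
  expect_true(all(res["hi", ] > res["lo", ]))
  expect_gt(mean(res["hi", ]), 0.5)
})

test_that("cohorts of pure-type raters are recovered well above chance", {
  lab <- type_label
  acc <- sapply(c(0.1, 1.0), function(nz) {
    space <- simulate_stimulus_space(stimulus_space_spec(
      seed = 391, face_informativeness = 0.5))
    intg <- integrate_cues(space$situation, space$face, space$prior)$table
    set.seed(392)
    types <- rep(c("situation", "face", "integrator"), each = 10)
    profiles <- lapply(seq_along(types), function(i) {
      rater_profile(types[i], noise_sd = nz, seed = 1000 + i)
    })
    recs <- simulate_raters(space, profiles, conditions = "joint")
    est <- estimate_cohort(recs, space$situation, space$face, intg)
    truth <- lab[types[match(est$participant_id,
                             sprintf("r%03d", seq_along(types)))]]
    mean(est$best_model == truth)
  })
  expect_true(all(acc > 2 / 3))
})
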