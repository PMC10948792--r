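test_that("a participant's table is the normalized single-rater aggregate", {
  m <- matrix(c(2, 2, 0), 1, dimnames = list("sA", toy_emotions))
  tab <- participant_probability_table(records_from_matrix(m),
                                       emotions = toy_emotions)
  expect_equal(unname(tab["sA", ]), c(0.5, 0.5, 0))
  # all-absent stimulus: uniform fallback, flagged
  m2 <- rbind(m, sB = c(0, 0, 0))
  tab2 <- participant_probability_table(records_from_matrix(m2),
                                        emotions = toy_emotions)
  expect_equal(unname(tab2["sB", ]), rep(1 / 3, 3))
  expect_identical(degenerate_rows(tab2), "sB")
})

test_that("incomplete stimuli are dropped with a warning", {
  m <- matrix(c(2, 1, 0, 3, 0, 1), 2, byrow = TRUE,
              dimnames = list(c("sA", "sB"), toy_emotions))
  recs <- records_from_matrix(m)
  recs <- recs[!(recs$stimulus_id == "sB" & recs$emotion == "fear"), ]
  expect_warning(tab <- participant_probability_table(recs,
                                                      emotions = toy_emotions),
                 "sB")
  expect_identical(rownames(tab), "sA")
  multi <- rbind(records_from_matrix(m, participant_id = "p1"),
                 records_from_matrix(m, participant_id = "p2"))
  expect_error(participant_probability_table(multi), "several participants")
})

test_that("a participant matching a model table gets r = 1 for that model", {
  space <- simulate_stimulus_space(stimulus_space_spec(
    n_stimuli = 10, seed = 21, face_informativeness = 0.5))
  intg <- integrate_cues(space$situation, space$face, space$prior)$table
  est <- reliance_estimates(space$situation, space$situation, space$face,
                            intg, participant_id = "mirror")
  expect_equal(est$r_situation, 1)
  expect_identical(est$best_model, "situation")
  expect_identical(est$n_pairs, 130L)
  # Fisher z stays finite at r = 1
  expect_true(is.finite(est$z_situation))
})

test_that("a zero-noise integrator is classified as integrating", {
  space <- simulate_stimulus_space(stimulus_space_spec(
    seed = 22, face_informativeness = 0.5))
  intg <- integrate_cues(space$situation, space$face, space$prior)$table
  recs <- simulate_raters(space,
                          list(rater_profile("integrator", noise_sd = 0,
                                             seed = 9)),
                          conditions = "joint")
  tab <- participant_probability_table(recs)
  est <- reliance_estimates(tab, space$situation, space$face, intg,
                            participant_id = "pure")
  expect_identical(est$best_model, "integration")
  expect_gt(est$r_integration, 0.9)
  # 44 x 13 cells -> 572 pairs, downstream df 570
  expect_identical(est$n_pairs, 572L)
})

test_that("best-model classification uses the documented tie precedence", {
  expect_identical(classify_best_model(0.3, 0.7, 0.5), "situation")
  expect_identical(classify_best_model(0.2, 0.6, 0.6), "situation")
  expect_identical(classify_best_model(0.6, 0.2, 0.6), "integration")
  expect_identical(classify_best_model(NA, 0.5, 0.4), NA_character_)
  expect_identical(classify_best_model(c(0.9, 0.1), c(0.1, 0.9), c(0.5, 0.5)),
                   c("face", "situation"))
  shares <- best_model_shares(c("situation", "situation", "face", NA))
  expect_equal(sum(shares), 100)
  expect_equal(unname(shares["situation"]), 200 / 3, tolerance = 1e-12)
})

test_that("Mahalanobis screening flags a planted outlier and only that row", {
  set.seed(91)
  z <- matrix(rnorm(300), 100, 3,
              dimnames = list(sprintf("p%03d", 1:100), NULL))
  z[37, ] <- z[37, ] + 10
  out <- mahalanobis_outliers(z)
  expect_identical(as.character(out), "p037")
  # distances agree with a longhand computation
  d_brute <- apply(z, 1L, function(row) {
    dv <- row - colMeans(z)
    as.numeric(t(dv) %*% solve(cov(z)) %*% dv)
  })
  expect_equal(unname(attr(out, "distances")), unname(d_brute),
               tolerance = 1e-10)
  expect_equal(attr(out, "cutoff"), qchisq(0.999, 3))
})

test_that("Mahalanobis screening behaves under the null and rejects bad input", {
  set.seed(92)
  flags <- sapply(1:10, function(i) {
    z <- matrix(rnorm(300), 100, 3)
    length(mahalanobis_outliers(z))
  })
  expect_lte(max(flags), 2)  # alpha 0.001, n = 100: expected 0.1 per run
  expect_error(mahalanobis_outliers(matrix(rnorm(6), 2, 3)), "more rows")
  sing <- cbind(rnorm(50), rnorm(50))
  sing <- cbind(sing, sing[, 1] + sing[, 2])
  expect_error(mahalanobis_outliers(sing), "singular")
})

test_that("covariate associations match the closed-form t and cor.test", {
  set.seed(93)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    x <- rnorm(n); y <- 0.4 * x + rnorm(n)
    out <- covariate_association(x, y, n_tests = 3)
    ct <- cor.test(x, y)
    expect_equal(out$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(out$t_stat, unname(ct$statistic), tolerance = 1e-10)
    expect_equal(out$p_adjusted, min(1, ct$p.value * 3), tolerance = 1e-10)
    expect_equal(c(out$ci_low, out$ci_high),
                 tanh(atanh(out$r) + c(-1, 1) * qnorm(0.975) / sqrt(n - 3)),
                 tolerance = 1e-12)
  }
  # r = 0.5, n = 30: t = 0.5 * sqrt(28 / 0.75)
  expect_equal(0.5 * sqrt(28 / 0.75), 3.05505, tolerance = 1e-5)
  # Bonferroni never lowers p and caps at 1
  hi <- covariate_association(rnorm(20), rnorm(20), n_tests = 50)
  expect_gte(hi$p_adjusted, hi$p_raw)
  expect_lte(hi$p_adjusted, 1)
  expect_error(covariate_association(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(covariate_association(rnorm(3), rnorm(3)), "4 complete pairs")
})

test_that("a perfectly linear covariate gives r = 1 with CI upper bound at 1", {
  x <- seq_len(20) / 10
  out <- covariate_association(x, 2 * x + 1)
  expect_equal(out$r, 1)
  expect_gt(out$ci_high, 0.999)
})

test_that("the consistency ICC matches an aov-based oracle and its F interval", {
  set.seed(94)
  n <- 40L
  s1 <- rnorm(n)
  s2 <- 0.7 * s1 + rnorm(n, sd = 0.5)
  out <- icc_consistency(s1, s2)
  # oracle: two-way ANOVA mean squares
  d <- data.frame(y = c(s1, s2),
                  subj = factor(rep(1:n, 2)),
                  sess = factor(rep(1:2, each = n)))
  ms <- anova(lm(y ~ subj + sess, data = d))[["Mean Sq"]]
  msr <- ms[1]; mse <- ms[3]
  expect_equal(out$icc, (msr - mse) / (msr + mse), tolerance = 1e-10)
  expect_equal(out$f_stat, msr / mse, tolerance = 1e-10)
  expect_identical(c(out$df1, out$df2), c(n - 1L, n - 1L))
  fl <- out$f_stat / qf(0.975, n - 1, n - 1)
  fu <- out$f_stat * qf(0.975, n - 1, n - 1)
  expect_equal(out$ci_low, (fl - 1) / (fl + 1), tolerance = 1e-10)
  expect_equal(out$ci_high, (fu - 1) / (fu + 1), tolerance = 1e-10)
})

test_that("ICC edge cases: identical sessions, printed df, mismatched ids", {
  x <- rnorm(110)
  perfect <- icc_consistency(x, x)
  expect_equal(perfect$icc, 1)
  expect_identical(c(perfect$df1, perfect$df2), c(109L, 109L))
  expect_equal(c(perfect$ci_low, perfect$ci_high), c(1, 1))
  s1 <- setNames(rnorm(6), paste0("p", 1:6))
  s2 <- setNames(rnorm(6), paste0("p", c(1:5, 7)))
  expect_error(icc_consistency(s1, s2), "p6")
  expect_error(icc_consistency(rnorm(4), rnorm(4)), "at least 5")
})

test_that("independent sessions give an ICC near zero", {
  set.seed(95)
  out <- icc_consistency(rnorm(200), rnorm(200))
  expect_lt(abs(out$icc), 0.15)
})

test_that("Fisher transform round-trips, is monotone, and clamps at |r| = 1", {
  r <- seq(-0.999, 0.999, length.out = 201)
  expect_equal(tanh(fisher_z(r)), r, tolerance = 1e-12)
  expect_identical(fisher_z(0), 0)
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_true(is.finite(fisher_z(1)))
  expect_true(is.finite(fisher_z(-1)))
})

test_that("reliance estimates are invariant to common stimulus reordering", {
  space <- simulate_stimulus_space(stimulus_space_spec(
    n_stimuli = 12, seed = 25, face_informativeness = 0.5))
  intg <- integrate_cues(space$situation, space$face, space$prior)$table
  recs <- simulate_raters(space,
                          list(rater_profile("situation", noise_sd = 0.3,
                                             seed = 2)),
                          conditions = "joint")
  tab <- participant_probability_table(recs)
  est1 <- reliance_estimates(tab, space$situation, space$face, intg)
  ord <- sample(nrow(tab))
  perm <- function(x) {
    probability_table(unclass(x)[ord, , drop = FALSE],
                      rownames(x)[ord], colnames(x))
  }
  est2 <- reliance_estimates(perm(tab), perm(space$situation),
                             perm(space$face), perm(intg))
  expect_equal(est2$r_situation, est1$r_situation, tolerance = 1e-12)
  expect_equal(est2$r_face, est1$r_face, tolerance = 1e-12)
  expect_equal(est2$r_integration, est1$r_integration, tolerance = 1e-12)
})
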