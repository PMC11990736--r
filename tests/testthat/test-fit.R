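test_that("near-noiseless cohorts are recovered exactly", {
  m <- small_model(sigma = 0.01)
  d <- small_design(seed = 21L, n_missing = 0L)
  cohort <- generate_cohort(d, m)
  fit <- fit_trajectories(cohort, trajectory_spec(3, 2), n_starts = 4,
                          seed = 21L, se = FALSE)
  expect_monotone_trace(fit)
  expect_true(fit$converged)
  expect_equal(fit$params$pi, c(3, 6, 3)/12, tolerance = 1e-6)
  for (j in 1:3) {
    # the group curves over the observed days are pinned down by the data
    expect_equal(trajectory_mean(fit$params$beta[[j]], d$observation_days),
                 trajectory_mean(m$coefficients[[j]], d$observation_days),
                 tolerance = 0.02)
  }
  # classification recovers the generating partition
  truth <- cohort$latent_group[!duplicated(cohort$subject_id)]
  expect_identical(unname(fit$assignment), truth)
})

test_that("k = 1 fit agrees with direct censored-regression optimization", {
  cohort <- generate_cohort(small_design(seed = 31L), small_model())
  fit <- fit_trajectories(cohort, trajectory_spec(1, 2), seed = 31L, se = FALSE)
  expect_monotone_trace(fit)
  oracle <- oracle_direct_cnorm_fit(cohort, order = 2L)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-6)
  expect_equal(fit$params$beta[[1]], unname(oracle$beta), tolerance = 1e-3)
  expect_equal(fit$params$sigma, oracle$sigma, tolerance = 1e-3)
})

test_that("k = 1 fit agrees with a Tobit fit from survreg", {
  skip_if_not_installed("survival")
  cohort <- generate_cohort(small_design(seed = 41L), small_model())
  fit <- fit_trajectories(cohort, trajectory_spec(1, 2), seed = 41L, se = FALSE)
  sr <- survival::survreg(
    survival::Surv(value, value > 0, type = "left") ~ day + I(day^2),
    data = cohort, dist = "gaussian"
  )
  expect_equal(fit$params$beta[[1]], unname(coef(sr)), tolerance = 2e-3)
  expect_equal(fit$params$sigma, sr$scale, tolerance = 1e-3)
})

test_that("label permutations leave the likelihood unchanged and reporting canonical", {
  cohort <- generate_cohort(small_design(seed = 51L), small_model())
  spec <- trajectory_spec(3, 2)
  params <- trajectory_params(small_model()$coefficients, 1.2, c(0.25, 0.5, 0.25))
  perm <- trajectory_params(small_model()$coefficients[c(3, 1, 2)], 1.2,
                            c(0.25, 0.25, 0.5))
  expect_equal(mixture_loglik(cohort, spec, params),
               mixture_loglik(cohort, spec, perm), tolerance = 1e-12)

  fit <- fit_trajectories(cohort, spec, n_starts = 4, seed = 51L, se = FALSE)
  intercepts <- vapply(fit$params$beta, `[[`, numeric(1), 1)
  expect_true(!is.unsorted(intercepts))
})

test_that("estimation never consumes the ground-truth group column", {
  cohort <- generate_cohort(small_design(seed = 61L), small_model())
  blinded <- cohort[, c("subject_id", "day", "value")]
  f1 <- fit_trajectories(cohort, trajectory_spec(2, 2), n_starts = 3,
                         seed = 61L, se = FALSE)
  f2 <- fit_trajectories(blinded, trajectory_spec(2, 2), n_starts = 3,
                         seed = 61L, se = FALSE)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-12)
  expect_equal(f1$params$beta, f2$params$beta, tolerance = 1e-12)
})

test_that("fit validates its inputs", {
  cohort <- generate_cohort(small_design(seed = 71L), small_model())
  expect_error(fit_trajectories(cohort, trajectory_spec(13, 2), se = FALSE),
               "number of subjects")
  expect_error(fit_trajectories(cohort[0, ], trajectory_spec(2, 2), se = FALSE),
               "no rows")
  expect_error(trajectory_spec(0), "k must be")
  expect_error(trajectory_spec(2, order = 5), "order")
})

test_that("reference-scale cohorts recover sigma and memberships", {
  cohort <- generate_cohort(study_design(seed = 303L), generating_model())
  fit <- fit_trajectories(cohort, trajectory_spec(3, 2), seed = 303L)
  expect_monotone_trace(fit)
  ref <- reference_params()
  se <- reference_standard_errors()
  expect_lt(abs(fit$params$sigma - ref$sigma), 3 * se$sigma_se)
  expect_equal(100 * fit$params$pi, c(11.42857, 74.28571, 14.28571),
               tolerance = 0.05)
  expect_equal(unname(table(fit$assignment)), c(4L, 26L, 5L), ignore_attr = TRUE)
})
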