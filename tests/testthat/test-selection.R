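# Candidate rows can be replayed from stored summaries (flags + BIC), which
# is how the published scan is exercised without its raw data.
stored_candidates <- function(rows) {
  structure(lapply(rows, function(r) r), class = "traj_candidates")
}

reference_candidates <- function() {
  tab <- reference_scan_table()
  stored_candidates(lapply(seq_len(nrow(tab)), function(i) {
    list(k = tab$k[i], memberships_ok = tab$memberships_ok[i],
         pvalues_ok = tab$pvalues_ok[i], bpp_ok = tab$bpp_ok[i],
         bic_obs = tab$bic_obs[i])
  }))
}

test_that("the published scan selects three groups and rejects homogeneity", {
  sel <- select_most_parsimonious(reference_candidates())
  expect_identical(sel$selected_k, 3L)
  expect_equal(sel$delta_bic_vs_k1, 693.8, tolerance = 1e-9)
  expect_true(sel$homogeneity_rejected)
  # k = 4 is excluded despite the largest BIC: a membership flag failed
  expect_false(sel$candidates$memberships_ok[4])
})

test_that("selection is invariant to candidate order and handles edge cases", {
  cand <- reference_candidates()
  shuffled <- structure(cand[c(3, 1, 4, 2)], class = "traj_candidates")
  expect_identical(select_most_parsimonious(shuffled)$selected_k, 3L)
  expect_equal(select_most_parsimonious(shuffled)$delta_bic_vs_k1,
               select_most_parsimonious(cand)$delta_bic_vs_k1)

  # single k = 1 candidate: criteria not applicable, no rejection
  only1 <- stored_candidates(list(list(k = 1L, memberships_ok = NA,
                                       pvalues_ok = NA, bpp_ok = NA,
                                       bic_obs = -100)))
  sel1 <- select_most_parsimonious(only1)
  expect_identical(sel1$selected_k, 1L)
  expect_false(sel1$homogeneity_rejected)

  # all multi-group candidates failing falls back to k = 1 with a warning
  failing <- stored_candidates(list(
    list(k = 1L, memberships_ok = NA, pvalues_ok = NA, bpp_ok = NA, bic_obs = -100),
    list(k = 2L, memberships_ok = FALSE, pvalues_ok = TRUE, bpp_ok = TRUE,
         bic_obs = -50)
  ))
  sel2 <- select_most_parsimonious(failing)
  expect_identical(sel2$selected_k, 1L)

  # a BIC gain of 9.9 does not reject homogeneity (strict > 10)
  close_call <- stored_candidates(list(
    list(k = 1L, memberships_ok = NA, pvalues_ok = NA, bpp_ok = NA, bic_obs = -100),
    list(k = 2L, memberships_ok = TRUE, pvalues_ok = TRUE, bpp_ok = TRUE,
         bic_obs = -90.1)
  ))
  sel3 <- select_most_parsimonious(close_call)
  expect_identical(sel3$selected_k, 2L)
  expect_false(sel3$homogeneity_rejected)
})

fake_fit <- function(pi, pvals, bpp_rows) {
  k <- length(pi)
  post <- do.call(rbind, bpp_rows)
  structure(list(
    spec = trajectory_spec(k, 0),
    params = trajectory_params(as.list(seq_len(k)), 1, pi),
    posterior = post,
    estimates = data.frame(group = seq_len(k),
                           parameter = rep("Membership(%)", k),
                           estimate = 100 * pi, se = 1, t = 1, p = pvals)
  ), class = "traj_fit")
}

test_that("parsimony criteria are strict inequalities on the printed thresholds", {
  ok <- fake_fit(c(0.1142857, 0.7428571, 0.1428572),
                 c(0.0343, 0.0000, 0.0161),
                 list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  flags <- apply_parsimony_criteria(ok)
  expect_true(flags$memberships_ok && flags$pvalues_ok && flags$bpp_ok)

  # membership exactly at 10% fails
  at_bound <- fake_fit(c(0.10, 0.90), c(0.01, 0.01),
                       list(c(1, 0), c(0, 1)))
  expect_false(apply_parsimony_criteria(at_bound)$memberships_ok)

  # any subject with max BPP at 0.94 fails the posterior criterion
  weak_bpp <- fake_fit(c(0.4, 0.6), c(0.01, 0.01),
                       list(c(0.94, 0.06), c(0, 1)))
  expect_false(apply_parsimony_criteria(weak_bpp)$bpp_ok)

  # p-value at the 0.1 boundary fails (strict <)
  at_p <- fake_fit(c(0.4, 0.6), c(0.1, 0.01), list(c(1, 0), c(0, 1)))
  expect_false(apply_parsimony_criteria(at_p)$pvalues_ok)

  # k = 1 baseline: not applicable
  cohort <- generate_cohort(small_design(seed = 11L), small_model())
  f1 <- fit_trajectories(cohort, trajectory_spec(1, 2), seed = 11L, se = FALSE)
  flags1 <- apply_parsimony_criteria(f1)
  expect_true(is.na(flags1$memberships_ok))
  expect_equal(flags1$min_max_bpp, 1)
})

test_that("scan validates inputs and flags candidates per k", {
  cohort <- generate_cohort(small_design(seed = 13L), small_model(sigma = 0.4))
  expect_error(scan_candidates(cohort, integer(0)), "k_values")
  sc <- scan_candidates(cohort, 1:2, n_starts = 3, seed = 13L)
  expect_length(sc, 2L)
  expect_identical(vapply(sc, `[[`, integer(1), "k"), 1:2)
  expect_true(all(vapply(sc, function(x) is.finite(x$bic_obs), logical(1))))
})
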