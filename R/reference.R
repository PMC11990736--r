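#' Reference trajectory parameters from the motivating cohort
#'
#' Maximum-likelihood estimates of the three-group quadratic censored-normal
#' model fitted to the reference 35-mouse two-bottle free-choice cohort:
#' per-group polynomial coefficients (intercept, linear, quadratic, in
#' g/kg/day over study days), the shared residual standard deviation sigma,
#' and the group membership proportions. Group 1 is the "late drinker" group
#' (n = 4), group 2 the "non-drinker" group (n = 26), group 3 the "early
#' drinker" group (n = 5); groups are ordered by ascending intercept.
#'
#' These estimates are the canonical generating truth of the synthetic-cohort
#' module, so simulation studies probe the regime the reference analysis
#' operated in.
#'
#' @return A list with elements `beta` (list of 3 coefficient vectors),
#'   `sigma` (scalar), `pi` (membership proportions summing to 1) and
#'   `group_sizes` (4, 26, 5).
#' @export
#' @examples
#' p <- reference_params()
#' trajectory_mean(p$beta[[3]], 57) # early drinkers at the last study day
reference_params <- function() {
  list(
    beta = list(
      c(1.39009, -0.05619, 0.00262),
      c(1.61339, -0.06100, 0.00109),
      c(2.47550,  0.19721, -0.00225)
    ),
    sigma = 1.60771,
    pi = c(4, 26, 5) / 35,
    group_sizes = c(4L, 26L, 5L)
  )
}

#' Reference standard errors of the fitted parameters
#'
#' Printed standard errors accompanying [reference_params()], used in
#' simulation studies to scale recovery tolerances (an estimate is deemed
#' recovered when it falls within a few reference SEs of the generating
#' value).
#'
#' @return A list with `beta_se` (list of 3 vectors), `sigma_se`, and
#'   `membership_pct_se` (SEs of the membership percentages).
#' @export
reference_standard_errors <- function() {
  list(
    beta_se = list(
      c(0.49984, 0.03587, 0.00056),
      c(0.19591, 0.01406, 0.00022),
      c(0.44686, 0.03207, 0.00050)
    ),
    sigma_se = 0.02684,
    membership_pct_se = c(5.39440, 7.41040, 5.93294)
  )
}

#' Reference subject-to-group assignment
#'
#' The published hard classification of the 35 reference subjects: mice 1, 18,
#' 29 and 31 in group 1 (late drinkers), mice 7, 13, 14, 24 and 30 in group 3
#' (early drinkers), all others in group 2 (non-drinkers). Used as the default
#' latent-group layout of the synthetic cohort so descriptive summaries (for
#' example the regimen cross-tab) line up with the reference study.
#'
#' @return Integer vector of length 35; element i is the group of subject i.
#' @export
reference_assignment <- function() {
  g <- rep(2L, 35L)
  g[c(1L, 18L, 29L, 31L)] <- 1L
  g[c(7L, 13L, 14L, 24L, 30L)] <- 3L
  g
}

#' Reference Bayesian posterior probability matrix
#'
#' The published per-subject posterior probabilities of the three-group model
#' on the reference cohort. Every subject is classified with near certainty:
#' all rows are one-hot except subject 29, whose probabilities are
#' (0.999473, 0.000527, 0).
#'
#' @return A `posterior_matrix` object (see [posterior_probs()]) with 35 rows,
#'   rows named by subject id.
#' @export
reference_posteriors <- function() {
  g <- reference_assignment()
  bpp <- matrix(0, nrow = 35L, ncol = 3L,
                dimnames = list(as.character(1:35), paste0("group", 1:3)))
  bpp[cbind(seq_len(35L), g)] <- 1
  bpp["29", ] <- c(0.999473, 0.000527, 0)
  new_posterior_matrix(bpp)
}

#' Reference group-number scan summary
#'
#' The published parsimony scan of the reference cohort: candidate group
#' numbers k = 1..4, whether each passed the membership-size, membership
#' p-value and posterior-probability criteria, and its BIC on the
#' all-observations convention. k = 4 fails because one membership percentage
#' is not significantly different from zero.
#'
#' @return A data frame with columns `k`, `memberships_ok`, `pvalues_ok`,
#'   `bpp_ok` (logical, `NA` for the k = 1 baseline) and `bic_obs`.
#' @export
reference_scan_table <- function() {
  data.frame(
    k = 1:4,
    memberships_ok = c(NA, TRUE, TRUE, FALSE),
    pvalues_ok = c(NA, TRUE, TRUE, FALSE),
    bpp_ok = c(NA, TRUE, TRUE, TRUE),
    bic_obs = c(-4183.1, -3628.8, -3489.3, -3449.94)
  )
}
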