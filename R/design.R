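#' Study design of a synthetic longitudinal cohort
#'
#' Describes the observation scheme the generator emulates: cohort size,
#' latent group sizes, the study days on which the outcome is recorded, the
#' number of (subject, day) cells removed at random, and the regimen labels.
#' The defaults reproduce the reference study: 35 subjects split 4/26/5 over
#' three latent groups, daily observations on study days 6-57 (the days on
#' which alcohol was available to every subject), and 15 missing cells, giving
#' 35 x 52 - 15 = 1805 retained observations. Subjects 1-18 carry the "5pct"
#' regimen label, subjects 19-35 the "10pct" label; the label is metadata only
#' and never enters the likelihood.
#'
#' @param n_subjects Number of subjects.
#' @param group_sizes Integer vector of latent group sizes; must sum to
#'   `n_subjects`.
#' @param observation_days Strictly increasing integer study days (all >= 1).
#' @param n_missing Number of (subject, day) cells removed uniformly at
#'   random; must be < `n_subjects * length(observation_days)`.
#' @param group_assignment Optional integer vector mapping subject index to
#'   latent group. Defaults to the reference layout ([reference_assignment()])
#'   when the design matches the reference cohort, otherwise to contiguous
#'   blocks of `group_sizes`.
#' @param regimen Optional character vector of per-subject regimen labels;
#'   defaults to "5pct" for subjects 1-18 and "10pct" beyond.
#' @param seed Integer seed controlling group noise and missingness.
#' @return A `study_design` list.
#' @export
#' @examples
#' d <- study_design()
#' d$n_subjects * length(d$observation_days) - d$n_missing # 1805
study_design <- function(n_subjects = 35L,
                         group_sizes = c(4L, 26L, 5L),
                         observation_days = 6:57,
                         n_missing = 15L,
                         group_assignment = NULL,
                         regimen = NULL,
                         seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  group_sizes <- as.integer(group_sizes)
  observation_days <- as.integer(observation_days)
  if (sum(group_sizes) != n_subjects) {
    stop("invalid study design: sum(group_sizes) must equal n_subjects",
         call. = FALSE)
  }
  if (any(observation_days < 1L) || is.unsorted(observation_days, strictly = TRUE)) {
    stop("invalid study design: observation_days must be strictly increasing and >= 1",
         call. = FALSE)
  }
  if (n_missing >= n_subjects * length(observation_days)) {
    stop("invalid study design: n_missing must be < n_subjects * n_days",
         call. = FALSE)
  }
  if (is.null(group_assignment)) {
    if (n_subjects == 35L && identical(group_sizes, c(4L, 26L, 5L))) {
      group_assignment <- reference_assignment()
    } else {
      group_assignment <- rep.int(seq_along(group_sizes), group_sizes)
    }
  }
  group_assignment <- as.integer(group_assignment)
  if (length(group_assignment) != n_subjects ||
      !identical(as.integer(tabulate(group_assignment, length(group_sizes))),
                 group_sizes)) {
    stop("invalid study design: group_assignment must realize group_sizes",
         call. = FALSE)
  }
  if (is.null(regimen)) {
    regimen <- ifelse(seq_len(n_subjects) <= 18L, "5pct", "10pct")
  }
  if (length(regimen) != n_subjects) {
    stop("invalid study design: regimen must have one label per subject",
         call. = FALSE)
  }
  structure(
    list(n_subjects = n_subjects, group_sizes = group_sizes,
         observation_days = observation_days, n_missing = as.integer(n_missing),
         group_assignment = group_assignment, regimen = regimen,
         seed = as.integer(seed)),
    class = "study_design"
  )
}

#' Generating model of the synthetic cohort
#'
#' The latent data-generating process: one polynomial mean trajectory per
#' group (coefficients in g/kg/day over the study-day time axis, day 1 = first
#' study day, so the intercept is the extrapolated day-0 level), a shared
#' residual standard deviation, and censoring bounds. Draws falling outside
#' the bounds are recorded exactly at the bound, matching the censored-normal
#' outcome model. Defaults are the reference-cohort estimates
#' ([reference_params()]) with left-censoring at 0 and no upper bound.
#'
#' @param coefficients List of per-group polynomial coefficient vectors
#'   (intercept first).
#' @param sigma Residual standard deviation, > 0 (g/kg/day).
#' @param lower_bound,upper_bound Censoring limits, `lower_bound < upper_bound`.
#' @return A `generating_model` list.
#' @export
generating_model <- function(coefficients = reference_params()$beta,
                             sigma = reference_params()$sigma,
                             lower_bound = 0,
                             upper_bound = Inf) {
  if (!is.list(coefficients) || !length(coefficients) ||
      !all(vapply(coefficients, is.numeric, logical(1L)))) {
    stop("invalid generating model: coefficients must be a non-empty list of numeric vectors",
         call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    stop("invalid generating model: sigma must be a single value >= 0",
         call. = FALSE)
  }
  if (!(lower_bound < upper_bound)) {
    stop("invalid generating model: lower_bound must be < upper_bound",
         call. = FALSE)
  }
  structure(
    list(coefficients = coefficients, sigma = sigma,
         lower_bound = lower_bound, upper_bound = upper_bound),
    class = "generating_model"
  )
}

#' Homogeneous (single-group) generating model
#'
#' Convenience scenario for testing the selection procedure under the null of
#' no heterogeneity: every subject follows the non-drinker (group 2) curve of
#' the reference estimates with the shared sigma.
#'
#' @inheritParams generating_model
#' @return A `generating_model` with a single trajectory group.
#' @export
homogeneous_model <- function(sigma = reference_params()$sigma) {
  generating_model(coefficients = reference_params()$beta[2],
                   sigma = sigma)
}
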