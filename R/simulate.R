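#' Generate a synthetic longitudinal cohort
#'
#' Draws one value per retained (subject, day) cell from the censored-normal
#' trajectory model: `value = max(lower, min(upper, mu_g(day) + sigma * eps))`
#' with `eps` standard normal and `mu_g` the polynomial mean of the subject's
#' latent group. Exactly `design$n_missing` cells are removed uniformly at
#' random. The draw is deterministic given `design$seed`.
#'
#' The `latent_group` column is ground truth retained for recovery studies
#' only; every estimation function in the package ignores it.
#'
#' @param design A [study_design()].
#' @param model A [generating_model()]; must have one coefficient vector per
#'   latent group of the design.
#' @return A data frame with columns `subject_id`, `latent_group`, `day`,
#'   `value`, `regimen`, one row per retained observation.
#' @export
#' @examples
#' cohort <- generate_cohort(study_design(seed = 7), generating_model())
#' nrow(cohort) # 1805
generate_cohort <- function(design, model) {
  stopifnot(inherits(design, "study_design"), inherits(model, "generating_model"))
  if (length(model$coefficients) != length(design$group_sizes)) {
    stop("generating model must supply one coefficient vector per latent group",
         call. = FALSE)
  }
  days <- design$observation_days
  n_days <- length(days)
  grid <- data.frame(
    subject_id = rep(seq_len(design$n_subjects), each = n_days),
    day = rep(days, times = design$n_subjects)
  )
  grid$latent_group <- design$group_assignment[grid$subject_id]
  grid$regimen <- design$regimen[grid$subject_id]

  set.seed(design$seed)
  mu <- vapply(seq_len(nrow(grid)), function(i) {
    trajectory_mean(model$coefficients[[grid$latent_group[i]]], grid$day[i])
  }, numeric(1L))
  latent <- mu + model$sigma * stats::rnorm(nrow(grid))
  grid$value <- pmin(pmax(latent, model$lower_bound), model$upper_bound)
  if (design$n_missing > 0L) {
    drop <- sample.int(nrow(grid), design$n_missing)
    grid <- grid[-drop, , drop = FALSE]
  }
  rownames(grid) <- NULL
  grid[, c("subject_id", "latent_group", "day", "value", "regimen")]
}

#' Average a longitudinal table into fixed-width day bins
#'
#' Bins are non-overlapping windows anchored at study day 1 (days 1-w in bin
#' 1, w+1-2w in bin 2, ...). The bin mean is taken over the subject's
#' non-missing days inside the bin; (subject, bin) cells with no observations
#' are absent from the output. This is the 5-day averaging used to display
#' consumption timelines.
#'
#' @param data Data frame with `subject_id`, `day`, `value`.
#' @param bin_width_days Bin width in days, >= 1.
#' @return Data frame with columns `subject_id`, `bin`, `value` (bin mean),
#'   plus any constant per-subject metadata columns present in the input
#'   (`latent_group`, `regimen`).
#' @export
bin_average <- function(data, bin_width_days = 5L) {
  if (bin_width_days < 1L) stop("bin_width_days must be >= 1", call. = FALSE)
  if (nrow(data) == 0L) {
    return(data.frame(subject_id = integer(), bin = integer(), value = numeric()))
  }
  bin <- (data$day - 1L) %/% as.integer(bin_width_days) + 1L
  agg <- stats::aggregate(
    list(value = data$value),
    by = list(subject_id = data$subject_id, bin = bin),
    FUN = mean
  )
  agg <- agg[order(agg$subject_id, agg$bin), , drop = FALSE]
  for (meta in intersect(c("latent_group", "regimen"), names(data))) {
    lookup <- data[[meta]][!duplicated(data$subject_id)]
    names(lookup) <- data$subject_id[!duplicated(data$subject_id)]
    agg[[meta]] <- lookup[as.character(agg$subject_id)]
  }
  rownames(agg) <- NULL
  agg
}

#' Generate auxiliary phenotype channels for a cohort
#'
#' Produces per-(subject, day) values for channels such as body weight, food
#' intake or water intake, as a group-specific mean (constant, or a function
#' of day) plus Gaussian noise. Used to emulate the secondary comparisons of
#' the reference study (for example, a lower water-intake mean for the
#' early-drinker group).
#'
#' @param design A [study_design()].
#' @param group_means Named list: one element per channel, each a numeric
#'   vector with one constant per latent group, or a function `f(day, group)`.
#' @param noise_sd Residual SD applied to every channel (0 gives the means
#'   exactly).
#' @return Data frame with `subject_id`, `latent_group`, `day`, one column per
#'   channel.
#' @export
generate_covariate_channels <- function(design, group_means, noise_sd = 1) {
  stopifnot(inherits(design, "study_design"))
  days <- design$observation_days
  out <- data.frame(
    subject_id = rep(seq_len(design$n_subjects), each = length(days)),
    day = rep(days, times = design$n_subjects)
  )
  out$latent_group <- design$group_assignment[out$subject_id]
  set.seed(design$seed + 104729L) # offset so channels are independent of the outcome draw
  for (ch in names(group_means)) {
    spec <- group_means[[ch]]
    mu <- if (is.function(spec)) {
      mapply(spec, out$day, out$latent_group)
    } else {
      spec[out$latent_group]
    }
    out[[ch]] <- mu + noise_sd * stats::rnorm(nrow(out))
  }
  out
}
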