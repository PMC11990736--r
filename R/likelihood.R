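#' Trajectory mixture model specification
#'
#' Defines the model family to fit: number of latent groups, per-group
#' polynomial order (0-4), and the censoring bounds of the outcome.
#'
#' @param k Number of groups, >= 1.
#' @param order Per-group polynomial order(s), recycled to length `k`.
#' @param lower_bound,upper_bound Censoring limits, `lower_bound < upper_bound`.
#' @return A `trajectory_spec` list.
#' @export
#' @examples
#' trajectory_spec(k = 3, order = 2) # the three-group quadratic CNORM family
trajectory_spec <- function(k, order = 2L, lower_bound = 0, upper_bound = Inf) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1", call. = FALSE)
  order <- rep_len(as.integer(order), k)
  if (any(is.na(order)) || any(order < 0L) || any(order > 4L)) {
    stop("polynomial order must be between 0 and 4", call. = FALSE)
  }
  if (!(lower_bound < upper_bound)) {
    stop("lower_bound must be < upper_bound", call. = FALSE)
  }
  structure(list(k = k, order = order,
                 lower_bound = lower_bound, upper_bound = upper_bound),
            class = "trajectory_spec")
}

#' Parameter set of a trajectory mixture
#'
#' Bundles per-group polynomial coefficients, the shared residual SD and the
#' membership proportions, validating the simplex and positivity constraints.
#'
#' @param beta List of per-group coefficient vectors (intercept first).
#' @param sigma Shared residual SD, > 0.
#' @param pi Membership proportions; must be positive and sum to 1 (within
#'   1e-8).
#' @return A `trajectory_params` list.
#' @export
trajectory_params <- function(beta, sigma, pi) {
  if (!is.list(beta)) beta <- list(beta)
  if (length(pi) != length(beta)) {
    stop("pi must have one proportion per group", call. = FALSE)
  }
  if (any(pi <= 0) || abs(sum(pi) - 1) > 1e-8) {
    stop("membership proportions must be positive and sum to 1", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("sigma must be > 0", call. = FALSE)
  }
  structure(list(beta = beta, sigma = sigma, pi = as.numeric(pi)),
            class = "trajectory_params")
}

#' Number of free parameters of a trajectory model
#'
#' Coefficients (`order + 1` per group) plus the shared sigma plus `k - 1`
#' free membership proportions. For the three-group quadratic model this is
#' 3 x 3 + 1 + 2 = 12, the count under which the reference information
#' criteria identities hold.
#'
#' @param spec A [trajectory_spec()].
#' @return Integer parameter count.
#' @export
n_free_params <- function(spec) {
  sum(spec$order + 1L) + 1L + (spec$k - 1L)
}

# Internal: validate a long table and pre-compute the pieces the likelihood
# needs (subject factor, per-order design matrices). latent_group, if present,
# is deliberately dropped here so no estimation path can touch it.
prepare_data <- function(data, spec) {
  need <- c("subject_id", "day", "value")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("data is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) == 0L) stop("data has no rows", call. = FALSE)
  subj <- factor(data$subject_id, levels = unique(data$subject_id))
  X <- lapply(seq_len(spec$k), function(j) {
    m <- design_row(data$day, spec$order[j])
    if (!is.matrix(m)) m <- matrix(m, nrow = length(data$day))
    m
  })
  list(y = as.numeric(data$value), subj = subj,
       n_subj = nlevels(subj), n_obs = nrow(data), X = X,
       subject_ids = levels(subj))
}

# Internal: n_subj x k matrix of per-subject, per-group log-likelihoods l_ij
# (sum of censored-normal log densities over the subject's observations at
# the group-j means).
subject_loglik_matrix <- function(prep, spec, params) {
  k <- spec$k
  lmat <- matrix(0, nrow = prep$n_subj, ncol = k)
  for (j in seq_len(k)) {
    mu <- drop(prep$X[[j]] %*% params$beta[[j]])
    ld <- cnorm_logdensity(prep$y, mu, params$sigma,
                           spec$lower_bound, spec$upper_bound)
    lmat[, j] <- rowsum(ld, prep$subj, reorder = FALSE)[, 1L]
  }
  lmat
}

#' Per-subject, per-group log-likelihood
#'
#' Sum of censored-normal log densities of one subject's series under one
#' group's trajectory, the `l_ij` of the mixture likelihood (repeated
#' measures are conditionally independent given group membership, the
#' standard trajectory-model assumption).
#'
#' @param days,values The subject's observation days and values.
#' @param beta Group coefficient vector.
#' @param sigma Residual SD.
#' @param lower_bound,upper_bound Censoring limits.
#' @return Scalar log-likelihood.
#' @export
subject_group_loglik <- function(days, values, beta, sigma,
                                 lower_bound = 0, upper_bound = Inf) {
  if (!length(days)) stop("subject series must be non-empty", call. = FALSE)
  mu <- trajectory_mean(beta, days)
  sum(cnorm_logdensity(values, mu, sigma, lower_bound, upper_bound))
}

#' Total mixture log-likelihood
#'
#' `L = sum_i log sum_j pi_j exp(l_ij)` over subjects, computed with
#' log-sum-exp stabilization.
#'
#' @param data Long table with `subject_id`, `day`, `value`.
#' @param spec A [trajectory_spec()].
#' @param params A [trajectory_params()] consistent with `spec`.
#' @return Scalar log-likelihood.
#' @export
mixture_loglik <- function(data, spec, params) {
  check_params_spec(params, spec)
  prep <- prepare_data(data, spec)
  lmat <- subject_loglik_matrix(prep, spec, params)
  sum(log_row_sum_exp(sweep(lmat, 2L, log(params$pi), `+`)))
}

check_params_spec <- function(params, spec) {
  if (length(params$beta) != spec$k ||
      any(lengths(params$beta) != spec$order + 1L)) {
    stop("parameter set is inconsistent with the model specification",
         call. = FALSE)
  }
  if (abs(sum(params$pi) - 1) > 1e-8) {
    stop("membership proportions must sum to 1", call. = FALSE)
  }
  invisible(TRUE)
}

# Internal: stable log(sum(exp(x))) by row.
log_row_sum_exp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

new_posterior_matrix <- function(bpp) {
  structure(bpp, class = c("posterior_matrix", class(bpp)))
}

#' Bayesian posterior probabilities of group membership
#'
#' `BPP_ij = pi_j exp(l_ij) / sum_m pi_m exp(l_im)`, evaluated on the log
#' scale so extreme likelihood gaps neither overflow nor underflow. Rows sum
#' to 1.
#'
#' @inheritParams mixture_loglik
#' @return A `posterior_matrix`: numeric matrix, one row per subject (row
#'   names are subject ids), one column per group.
#' @export
posterior_probs <- function(data, spec, params) {
  check_params_spec(params, spec)
  prep <- prepare_data(data, spec)
  lmat <- subject_loglik_matrix(prep, spec, params)
  bpp <- posterior_from_loglik(lmat, params$pi)
  dimnames(bpp) <- list(prep$subject_ids, paste0("group", seq_len(spec$k)))
  new_posterior_matrix(bpp)
}

# Internal: posterior weights from an l_ij matrix and prior proportions.
posterior_from_loglik <- function(lmat, pi) {
  a <- sweep(lmat, 2L, log(pi), `+`)
  exp(a - log_row_sum_exp(a))
}

#' Hard classification from a posterior matrix
#'
#' Assigns each subject to the group with the largest posterior probability;
#' ties break toward the lowest group index.
#'
#' @param post A `posterior_matrix` (or plain matrix of row-normalized
#'   probabilities).
#' @return Named integer vector of group assignments.
#' @export
#' @examples
#' classify(reference_posteriors())
classify <- function(post) {
  g <- apply(unclass(post), 1L, which.max) # which.max takes the first maximum
  stats::setNames(as.integer(g), rownames(post))
}
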