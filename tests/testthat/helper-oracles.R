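# Independent oracles and small fixtures used across the suite.
# Oracle code deliberately avoids the package's likelihood path: polynomial
# means via a plain loop, censored densities written out directly.

# A compact cohort (12 subjects, 3 groups, 11 observation days) for unit
# tests where the full reference-size cohort would be wasteful.
small_design <- function(seed = 1L, n_missing = 5L) {
  study_design(n_subjects = 12L, group_sizes = c(3L, 6L, 3L),
               observation_days = seq(6L, 36L, by = 3L),
               n_missing = n_missing, seed = seed)
}

small_model <- function(sigma = 1.2) {
  generating_model(
    coefficients = list(c(1.0, -0.05, 0.003),
                        c(1.6, -0.06, 0.001),
                        c(2.5, 0.20, -0.002)),
    sigma = sigma
  )
}

oracle_poly <- function(beta, t) {
  out <- 0
  for (d in seq_along(beta)) out <- out + beta[d] * t^(d - 1)
  out
}

oracle_subject_loglik <- function(days, values, beta, sigma, lower, upper) {
  ll <- 0
  for (i in seq_along(days)) {
    mu <- oracle_poly(beta, days[i])
    ll <- ll + if (is.finite(lower) && values[i] <= lower) {
      log(stats::pnorm((lower - mu)/sigma))
    } else if (is.finite(upper) && values[i] >= upper) {
      log(1 - stats::pnorm((upper - mu)/sigma))
    } else {
      stats::dnorm(values[i], mu, sigma, log = TRUE)
    }
  }
  ll
}

# Mixture log-likelihood by explicit enumeration over all k^n_subjects
# group-assignment vectors: L = sum_i log sum_j pi_j e^{l_ij} equals
# log sum_a prod_i pi_{a_i} e^{l_i,a_i}... summed subject-wise, so compare
# sum over subjects of the log of the per-subject mixture obtained from the
# assignment enumeration restricted to that subject. The enumeration below
# computes the joint sum over assignment vectors directly.
oracle_mixture_loglik_enum <- function(data, spec, params) {
  subs <- unique(data$subject_id)
  n <- length(subs)
  k <- spec$k
  lmat <- matrix(0, n, k)
  for (i in seq_len(n)) {
    rows <- data$subject_id == subs[i]
    for (j in seq_len(k)) {
      lmat[i, j] <- oracle_subject_loglik(data$day[rows], data$value[rows],
                                          params$beta[[j]], params$sigma,
                                          spec$lower_bound, spec$upper_bound)
    }
  }
  assignments <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  total <- 0
  for (r in seq_len(nrow(assignments))) {
    a <- assignments[r, ]
    total <- total + prod(params$pi[a]) * exp(sum(lmat[cbind(seq_len(n), a)]))
  }
  log(total)
}

# Direct (non-EM) maximum-likelihood censored regression: optimizes the
# plain censored-normal log-likelihood over (beta, log sigma) from a least
# squares start with a derivative-free polish.
oracle_direct_cnorm_fit <- function(data, order = 2L, lower = 0, upper = Inf) {
  t_pow <- sapply(0:order, function(d) data$day^d)
  ols <- stats::lm.fit(t_pow, data$value)
  nll <- function(th) {
    beta <- th[1:(order + 1L)]
    sigma <- exp(th[order + 2L])
    mu <- drop(t_pow %*% beta)
    cens <- is.finite(lower) & data$value <= lower
    ll <- numeric(length(mu))
    ll[cens] <- stats::pnorm((lower - mu[cens])/sigma, log.p = TRUE)
    ll[!cens] <- stats::dnorm(data$value[!cens], mu[!cens], sigma, log = TRUE)
    -sum(ll)
  }
  th0 <- c(unname(ols$coefficients), log(max(sd(ols$residuals), 1e-2)))
  opt <- stats::optim(th0, nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  opt <- stats::optim(opt$par, nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  list(beta = opt$par[1:(order + 1L)], sigma = exp(opt$par[order + 2L]),
       loglik = -opt$value)
}

# Match fitted groups to generating groups by classification overlap with
# the retained ground-truth labels (ascending-intercept labels can swap when
# two generating intercepts overlap within sampling noise). Returns, for each
# generating group, the fitted group holding most of its subjects.
match_groups_to_truth <- function(fit, cohort) {
  truth <- cohort$latent_group[!duplicated(cohort$subject_id)]
  assign <- unname(fit$assignment)
  vapply(sort(unique(truth)), function(g) {
    as.integer(names(which.max(table(assign[truth == g]))))
  }, integer(1))
}

# Trace monotonicity guard applied to every fit the suite produces.
expect_monotone_trace <- function(fit, tol = 1e-6) {
  testthat::expect_true(all(diff(fit$trace) >= -tol),
                        label = sprintf("EM log-likelihood trace non-decreasing (min step %.3g)",
                                        min(diff(fit$trace))))
}
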