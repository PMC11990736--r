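# EM machinery for the censored-normal trajectory mixture.
#
# The M-step has no closed form under censoring, so it maximizes the
# posterior-weighted complete-data log-likelihood Q(beta, log sigma) with a
# warm-started quasi-Newton step (analytic gradient). Running BFGS for a
# bounded number of inner iterations from the previous optimum never
# decreases Q, so the observed log-likelihood is non-decreasing across EM
# iterations (generalized EM).

pack_theta <- function(params) {
  c(unlist(params$beta), log(params$sigma))
}

# keep exp(log sigma) strictly positive and finite for the optimizer
clamp_logsigma <- function(ls) min(max(ls, -20), 20)

unpack_theta <- function(theta, spec, pi) {
  sizes <- spec$order + 1L
  beta <- vector("list", spec$k)
  off <- 0L
  for (j in seq_len(spec$k)) {
    beta[[j]] <- theta[(off + 1L):(off + sizes[j])]
    off <- off + sizes[j]
  }
  trajectory_params(beta, exp(clamp_logsigma(theta[off + 1L])), pi)
}

# Weighted complete-data log-likelihood and gradient. w_obs is the n_obs x k
# matrix of posterior weights expanded to observations.
q_objective <- function(theta, prep, spec, w_obs) {
  sizes <- spec$order + 1L
  sigma <- exp(clamp_logsigma(theta[sum(sizes) + 1L]))
  q <- 0
  off <- 0L
  for (j in seq_len(spec$k)) {
    beta_j <- theta[(off + 1L):(off + sizes[j])]
    mu <- drop(prep$X[[j]] %*% beta_j)
    q <- q + sum(w_obs[, j] * cnorm_logdensity(prep$y, mu, sigma,
                                               spec$lower_bound,
                                               spec$upper_bound))
    off <- off + sizes[j]
  }
  q
}

q_gradient <- function(theta, prep, spec, w_obs) {
  sizes <- spec$order + 1L
  sigma <- exp(clamp_logsigma(theta[sum(sizes) + 1L]))
  grad <- numeric(length(theta))
  dlogsigma <- 0
  off <- 0L
  for (j in seq_len(spec$k)) {
    beta_j <- theta[(off + 1L):(off + sizes[j])]
    mu <- drop(prep$X[[j]] %*% beta_j)
    sc <- cnorm_score(prep$y, mu, sigma, spec$lower_bound, spec$upper_bound)
    grad[(off + 1L):(off + sizes[j])] <- drop(crossprod(prep$X[[j]],
                                                        w_obs[, j] * sc$dmu))
    dlogsigma <- dlogsigma + sigma * sum(w_obs[, j] * sc$dsigma)
    off <- off + sizes[j]
  }
  grad[off + 1L] <- dlogsigma
  grad
}

m_step <- function(theta, prep, spec, w, inner_maxit, inner_tol) {
  w_obs <- w[as.integer(prep$subj), , drop = FALSE]
  # the raw polynomial basis is badly scaled (1, t, t^2, ... up to t^4);
  # scale each coefficient by its column magnitude so BFGS steps are sane
  parscale <- c(unlist(lapply(prep$X, function(X) {
    1/pmax(apply(abs(X), 2L, max), 1)
  })), 1)
  opt <- stats::optim(
    theta, fn = q_objective, gr = q_gradient,
    prep = prep, spec = spec, w_obs = w_obs,
    method = "BFGS",
    control = list(fnscale = -1, maxit = inner_maxit, reltol = inner_tol,
                   parscale = parscale)
  )
  if (opt$value >= q_objective(theta, prep, spec, w_obs)) opt$par else theta
}

# One EM run from a parameter set; returns params, loglik, trace, converged.
em_run <- function(prep, spec, params, tol, max_iter, inner_maxit, inner_tol) {
  theta <- pack_theta(params)
  pi <- params$pi
  trace <- numeric(0L)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    params <- unpack_theta(theta, spec, pi)
    lmat <- subject_loglik_matrix(prep, spec, params)
    ll <- sum(log_row_sum_exp(sweep(lmat, 2L, log(pi), `+`)))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    w <- posterior_from_loglik(lmat, pi)
    pi_new <- colMeans(w)
    # keep a collapsing group's parameters estimable
    pi <- pmax(pi_new, 1e-10)
    pi <- pi/sum(pi)
    theta <- m_step(theta, prep, spec, w, inner_maxit, inner_tol)
  }
  if (!converged) {
    # score the post-M-step parameters so the reported L matches them
    params <- unpack_theta(theta, spec, pi)
    lmat <- subject_loglik_matrix(prep, spec, params)
    trace <- c(trace, sum(log_row_sum_exp(sweep(lmat, 2L, log(pi), `+`))))
  } else {
    params <- unpack_theta(theta, spec, pi)
  }
  list(params = params, loglik = trace[length(trace)],
       trace = trace, converged = converged, n_iter = length(trace))
}

# Quasi-Newton polish of the observed mixture log-likelihood from the EM
# solution. EM converges linearly and can stall along the near-flat ridge of
# the collinear polynomial basis with the log-likelihood essentially at its
# maximum but coefficients still displaced; BFGS on the observed L (gradient
# via the Fisher identity: the posterior-weighted complete-data score) pulls
# the estimate onto the optimum. Membership proportions ride along on the
# multinomial-logit scale.
polish_fit <- function(prep, spec, params, maxit = 200L) {
  k <- spec$k
  n_beta <- sum(spec$order + 1L)
  th0 <- c(pack_theta(params),
           if (k > 1L) log(params$pi[-1L]/params$pi[1L]) else numeric(0L))
  split_par <- function(th) {
    alpha <- if (k > 1L) th[(n_beta + 2L):(n_beta + k)] else numeric(0L)
    a <- pmin(pmax(c(0, alpha), -30), 30)
    pi <- exp(a - max(a))
    list(theta = th[seq_len(n_beta + 1L)], pi = pi/sum(pi))
  }
  fn <- function(th) {
    sp <- split_par(th)
    params <- unpack_theta(sp$theta, spec, sp$pi)
    lmat <- subject_loglik_matrix(prep, spec, params)
    sum(log_row_sum_exp(sweep(lmat, 2L, log(sp$pi), `+`)))
  }
  gr <- function(th) {
    sp <- split_par(th)
    params <- unpack_theta(sp$theta, spec, sp$pi)
    lmat <- subject_loglik_matrix(prep, spec, params)
    w <- posterior_from_loglik(lmat, sp$pi)
    w_obs <- w[as.integer(prep$subj), , drop = FALSE]
    g_theta <- q_gradient(sp$theta, prep, spec, w_obs)
    g_alpha <- if (k > 1L) colSums(w)[-1L] - prep$n_subj * sp$pi[-1L]
               else numeric(0L)
    c(g_theta, g_alpha)
  }
  parscale <- c(unlist(lapply(prep$X, function(X) {
    1/pmax(apply(abs(X), 2L, max), 1)
  })), 1, rep(1, k - 1L))
  opt <- stats::optim(th0, fn = fn, gr = gr, method = "BFGS",
                      control = list(fnscale = -1, maxit = maxit,
                                     reltol = 1e-12, parscale = parscale))
  sp <- split_par(opt$par)
  list(params = unpack_theta(sp$theta, spec, sp$pi), loglik = opt$value)
}

# Hard-assignment starting values: per-group least-squares polynomial plus
# pooled residual SD; pi from group sizes.
init_from_assignment <- function(prep, spec, groups) {
  k <- spec$k
  g_obs <- groups[as.integer(prep$subj)]
  beta <- vector("list", k)
  rss <- 0
  for (j in seq_len(k)) {
    sel <- g_obs == j
    Xj <- prep$X[[j]][sel, , drop = FALSE]
    yj <- prep$y[sel]
    fit <- stats::lm.fit(Xj, yj)
    beta[[j]] <- unname(fit$coefficients)
    beta[[j]][is.na(beta[[j]])] <- 0
    rss <- rss + sum(fit$residuals^2)
  }
  sigma <- sqrt(rss/max(prep$n_obs - sum(spec$order + 1L), 1L))
  pi <- tabulate(groups, k)/length(groups)
  trajectory_params(beta, max(sigma, 1e-3), pmax(pi, 1e-6)/sum(pmax(pi, 1e-6)))
}

quantile_split <- function(prep, k) {
  if (k == 1L) return(rep(1L, prep$n_subj))
  means <- rowsum(prep$y, prep$subj, reorder = FALSE)[, 1L] /
    as.integer(table(prep$subj)[levels(prep$subj)])
  r <- rank(means, ties.method = "first")
  as.integer(cut(r, breaks = k, labels = FALSE))
}

random_split <- function(n_subj, k) {
  repeat {
    g <- sample.int(k, n_subj, replace = TRUE)
    if (length(unique(g)) == k) return(g)
  }
}

#' Fit a censored-normal trajectory mixture by maximum likelihood
#'
#' Runs the EM algorithm with multi-start initialization: one start from a
#' k-quantile split of the per-subject mean levels plus `n_starts - 1` random
#' partitions. Each start is advanced for `burn_iter` EM iterations, then the
#' best start (by current log-likelihood) is run to convergence. The E-step
#' computes posterior membership weights; the M-step updates the proportions
#' in closed form and the coefficients plus shared sigma by warm-started
#' quasi-Newton (see [cnorm_logdensity()] for the outcome model). Groups in
#' the result are relabeled in ascending order of intercept, so group 1 is
#' the lowest-starting trajectory.
#'
#' A `latent_group` column in `data`, if present, is ignored.
#'
#' @param data Long table with `subject_id`, `day`, `value`.
#' @param spec A [trajectory_spec()].
#' @param n_starts Number of EM starts (>= 1).
#' @param burn_iter EM iterations given to every start before the best one is
#'   continued.
#' @param tol Relative log-likelihood change declaring convergence.
#' @param max_iter Maximum EM iterations for the continued run.
#' @param inner_maxit,inner_tol Quasi-Newton budget of each M-step.
#' @param seed Integer seed for the random starts.
#' @param se Compute standard errors / Wald tests ([wald_tests()]) on the
#'   fitted model (skipped when `FALSE` to save time in large scans).
#' @return A `traj_fit` object: `params`, `loglik`, `trace` (per-iteration
#'   log-likelihood of the winning run), `converged`, `n_starts_used`,
#'   information criteria (`bic_obs`, `bic_subj`, `aic`), `posterior`,
#'   `assignment`, `n_obs`, `n_subj`, and (if `se`) an `estimates` table with
#'   SEs, t statistics and p-values.
#' @export
#' @examples
#' cohort <- generate_cohort(study_design(seed = 3), generating_model())
#' fit <- fit_trajectories(cohort, trajectory_spec(3), n_starts = 4, se = FALSE)
#' fit$params$sigma
fit_trajectories <- function(data, spec, n_starts = 20L, burn_iter = 6L,
                             tol = 1e-8, max_iter = 500L,
                             inner_maxit = 30L, inner_tol = 1e-10,
                             seed = 1L, se = TRUE) {
  stopifnot(inherits(spec, "trajectory_spec"))
  data <- as.data.frame(data)
  data$latent_group <- NULL
  prep <- prepare_data(data, spec)
  if (spec$k > prep$n_subj) {
    stop("k must not exceed the number of subjects", call. = FALSE)
  }

  set.seed(seed)
  starts <- list(quantile_split(prep, spec$k))
  if (spec$k == 1L) n_starts <- 1L # all starts coincide for one group
  if (n_starts > 1L) {
    starts <- c(starts, replicate(n_starts - 1L,
                                  random_split(prep$n_subj, spec$k),
                                  simplify = FALSE))
  }
  burns <- lapply(starts, function(g) {
    init <- init_from_assignment(prep, spec, g)
    # exploratory short runs rank the starting basins; the winner gets the
    # full optimizer budget below
    em_run(prep, spec, init, tol = tol, max_iter = burn_iter,
           inner_maxit = min(inner_maxit, 12L), inner_tol = inner_tol)
  })
  best <- burns[[which.max(vapply(burns, `[[`, numeric(1L), "loglik"))]]
  run <- if (best$converged) best else {
    cont <- em_run(prep, spec, best$params, tol = tol, max_iter = max_iter,
                   inner_maxit = inner_maxit, inner_tol = inner_tol)
    cont$trace <- c(best$trace, cont$trace[-1L])
    cont
  }
  if (!run$converged) {
    warning("EM did not converge within max_iter; result flagged converged = FALSE",
            call. = FALSE)
  }

  pol <- polish_fit(prep, spec, run$params)
  if (pol$loglik >= run$loglik) {
    run$params <- pol$params
    run$loglik <- pol$loglik
    run$trace <- c(run$trace, pol$loglik)
  }

  params <- canonicalize_params(run$params)
  post <- posterior_probs(data, spec, params)
  p <- n_free_params(spec)
  ic <- information_criteria(run$loglik, p, prep$n_obs, prep$n_subj)

  fit <- structure(
    list(spec = spec, params = params, loglik = run$loglik, trace = run$trace,
         converged = run$converged, n_iter = run$n_iter,
         n_starts_used = length(starts), n_params = p,
         n_obs = prep$n_obs, n_subj = prep$n_subj,
         bic_obs = ic[["bic_obs"]], bic_subj = ic[["bic_subj"]],
         aic = ic[["aic"]],
         posterior = post, assignment = classify(post),
         data = data),
    class = "traj_fit"
  )
  if (se) fit$estimates <- wald_tests(fit)
  fit
}

# Relabel groups by ascending intercept (reporting convention; the
# likelihood is invariant to label permutations).
canonicalize_params <- function(params) {
  ord <- order(vapply(params$beta, `[[`, numeric(1L), 1L))
  trajectory_params(params$beta[ord], params$sigma, params$pi[ord])
}

#' @export
print.traj_fit <- function(x, ...) {
  cat(sprintf("Censored-normal trajectory mixture: k = %d, orders %s\n",
              x$spec$k, paste(x$spec$order, collapse = "/")))
  cat(sprintf("  subjects %d, observations %d, free parameters %d\n",
              x$n_subj, x$n_obs, x$n_params))
  cat(sprintf("  logLik %.2f | BIC(N=obs) %.2f | BIC(N=subj) %.2f | AIC %.2f\n",
              x$loglik, x$bic_obs, x$bic_subj, x$aic))
  cat(sprintf("  membership %%: %s | sigma %.4f | converged: %s\n",
              paste(sprintf("%.2f", 100 * x$params$pi), collapse = ", "),
              x$params$sigma, x$converged))
  invisible(x)
}
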