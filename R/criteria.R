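#' Penalized information criteria (larger is better)
#'
#' BIC and AIC in the penalized log-likelihood form used throughout the
#' selection procedure: `BIC = L - (p/2) ln N` and `AIC = L - p`, with the
#' sample size `N` counted either as total observations or as subjects (both
#' conventions are reported).
#'
#' @param loglik Maximized log-likelihood `L`.
#' @param p Number of free parameters (see [n_free_params()]).
#' @param n_obs Total observation count.
#' @param n_subj Subject count.
#' @return Named numeric vector `bic_obs`, `bic_subj`, `aic`.
#' @export
#' @examples
#' information_criteria(-3444.35, 12, 1805, 35)
information_criteria <- function(loglik, p, n_obs, n_subj) {
  if (p < 0 || n_obs < n_subj || n_subj < 1) {
    stop("require p >= 0 and n_obs >= n_subj >= 1", call. = FALSE)
  }
  c(bic_obs = loglik - (p/2) * log(n_obs),
    bic_subj = loglik - (p/2) * log(n_subj),
    aic = loglik - p)
}

# Mixture log-likelihood as a function of the free parameter vector
# (beta_1, ..., beta_k, sigma, alpha_2, ..., alpha_k), membership on the
# multinomial-logit scale with group 1 as reference.
full_loglik_fn <- function(prep, spec) {
  sizes <- spec$order + 1L
  n_beta <- sum(sizes)
  k <- spec$k
  function(th) {
    sigma <- th[n_beta + 1L]
    if (sigma <= 0) return(-Inf)
    alpha <- if (k > 1L) th[(n_beta + 2L):(n_beta + k)] else numeric(0L)
    a <- c(0, alpha)
    pi <- exp(a - max(a))
    pi <- pi/sum(pi)
    beta <- vector("list", k)
    off <- 0L
    for (j in seq_len(k)) {
      beta[[j]] <- th[(off + 1L):(off + sizes[j])]
      off <- off + sizes[j]
    }
    lmat <- subject_loglik_matrix(prep, spec,
                                  list(beta = beta, sigma = sigma, pi = pi))
    sum(log_row_sum_exp(sweep(lmat, 2L, log(pi), `+`)))
  }
}

poly_term_names <- c("Intercept", "Linear", "Quadratic", "Cubic", "Quartic")

#' Wald tests of the fitted parameters
#'
#' Standard errors from the inverse observed information (numerical Hessian
#' of the mixture log-likelihood at the optimum, with membership proportions
#' on the multinomial-logit scale and a delta-method back-transform to the
#' percentage scale), t statistics for H0: parameter = 0, and two-sided
#' p-values from the standard normal reference. If the Hessian is singular
#' the SEs are reported as `NA` with a warning rather than fabricated.
#'
#' @param fit A `traj_fit` from [fit_trajectories()].
#' @return Data frame with columns `group` (`NA` for sigma), `parameter`,
#'   `estimate`, `se`, `t`, `p`. Membership rows are on the percentage scale.
#' @export
wald_tests <- function(fit) {
  stopifnot(inherits(fit, "traj_fit"))
  spec <- fit$spec
  prep <- prepare_data(fit$data, spec)
  k <- spec$k
  pi <- fit$params$pi
  alpha <- if (k > 1L) log(pi[-1L]/pi[1L]) else numeric(0L)
  th <- c(unlist(fit$params$beta), fit$params$sigma, alpha)

  ll <- full_loglik_fn(prep, spec)
  H <- pracma::hessian(ll, th)
  V <- tryCatch(solve(-H), error = function(e) NULL)
  ok <- !is.null(V) && all(is.finite(diag(V))) && all(diag(V) > 0)
  if (!ok) {
    warning("observed information is singular; standard errors undefined",
            call. = FALSE)
  }

  sizes <- spec$order + 1L
  n_beta <- sum(sizes)
  est <- c(unlist(fit$params$beta), fit$params$sigma)
  se <- if (ok) sqrt(diag(V)[seq_len(n_beta + 1L)]) else rep(NA_real_, n_beta + 1L)
  group <- c(rep(seq_len(k), times = sizes), NA_integer_)
  parameter <- c(unlist(lapply(sizes, function(s) poly_term_names[seq_len(s)])),
                 "Sigma")

  # membership percentages via the delta method from the logit block
  if (k > 1L) {
    J <- matrix(0, nrow = k, ncol = k - 1L) # d pi / d alpha
    for (j in seq_len(k)) {
      for (m in 2L:k) {
        J[j, m - 1L] <- pi[j] * ((j == m) - pi[m])
      }
    }
    se_pct <- if (ok) {
      Va <- V[(n_beta + 2L):(n_beta + k), (n_beta + 2L):(n_beta + k), drop = FALSE]
      100 * sqrt(pmax(diag(J %*% Va %*% t(J)), 0))
    } else rep(NA_real_, k)
    group <- c(group, seq_len(k))
    parameter <- c(parameter, rep("Membership(%)", k))
    est <- c(est, 100 * pi)
    se <- c(se, se_pct)
  }

  tstat <- est/se
  data.frame(group = group, parameter = parameter, estimate = est, se = se,
             t = tstat, p = 2 * stats::pnorm(-abs(tstat)),
             row.names = NULL)
}
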