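#' Polynomial design row for a study day
#'
#' Basis vector `(1, t, t^2, ..., t^order)` used by every trajectory mean.
#' Orders 0 through 4 are supported.
#'
#' @param t Study day (numeric, vectorized).
#' @param order Polynomial order, 0-4.
#' @return For scalar `t`, a numeric vector of length `order + 1`; for vector
#'   `t`, a matrix with one row per day.
#' @export
#' @examples
#' design_row(57, 2) # c(1, 57, 3249)
design_row <- function(t, order) {
  if (length(order) != 1L || is.na(order) || order < 0L || order > 4L) {
    stop("polynomial order must be between 0 and 4", call. = FALSE)
  }
  m <- outer(as.numeric(t), 0:order, `^`)
  if (length(t) == 1L) drop(m) else m
}

#' Expected trajectory value at a study day
#'
#' Evaluates the polynomial mean `beta %*% (1, t, ..., t^order)` on the
#' latent (pre-censoring) scale, in outcome units (g/kg/day).
#'
#' @param beta Coefficient vector, intercept first; its length fixes the
#'   order.
#' @param t Study day(s).
#' @return Numeric vector of latent means.
#' @export
#' @examples
#' p <- reference_params()
#' trajectory_mean(p$beta[[3]], c(0, 57)) # 2.4755 and ~6.41
trajectory_mean <- function(beta, t) {
  X <- design_row(t, length(beta) - 1L)
  if (is.matrix(X)) drop(X %*% beta) else sum(X * beta)
}

#' Censored-normal log density
#'
#' Log-likelihood contribution of one observation under the censored normal
#' (Tobit) outcome model: Gaussian log density for interior values, the
#' cumulative log mass `log Phi((lower - mu)/sigma)` for values at the lower
#' bound, and the upper-tail log mass for values at the upper bound.
#' Evaluated through `pnorm(log.p = TRUE)`, so it is stable far into the
#' tails (|z| of order 37 and beyond).
#'
#' @param y Observed value(s), within `[lower, upper]`.
#' @param mu Latent mean(s).
#' @param sigma Residual SD, > 0.
#' @param lower,upper Censoring bounds.
#' @return Vector of log densities / log masses.
#' @export
cnorm_logdensity <- function(y, mu, sigma, lower = 0, upper = Inf) {
  if (!is.numeric(sigma) || any(sigma <= 0)) {
    stop("sigma must be > 0", call. = FALSE)
  }
  n <- max(length(y), length(mu))
  y <- rep_len(y, n)
  mu <- rep_len(mu, n)
  at_lower <- is.finite(lower) & y <= lower
  at_upper <- is.finite(upper) & y >= upper
  out <- stats::dnorm(y, mean = mu, sd = sigma, log = TRUE)
  if (any(at_lower)) {
    out[at_lower] <- stats::pnorm((lower - mu[at_lower])/sigma, log.p = TRUE)
  }
  if (any(at_upper)) {
    out[at_upper] <- stats::pnorm((upper - mu[at_upper])/sigma,
                                  lower.tail = FALSE, log.p = TRUE)
  }
  out
}

# Score of the censored-normal log density with respect to mu and sigma.
# Interior:  d/dmu = r/sigma^2,  d/dsigma = (r^2/sigma^2 - 1)/sigma, r = y - mu.
# Left-censored (z = (lower-mu)/sigma): d/dmu = -lambda(z)/sigma,
#   d/dsigma = -z*lambda(z)/sigma with lambda the inverse Mills ratio
#   phi(z)/Phi(z), computed on the log scale for stability.
# Right-censored analogous with the upper tail.
cnorm_score <- function(y, mu, sigma, lower = 0, upper = Inf) {
  at_lower <- is.finite(lower) & y <= lower
  at_upper <- is.finite(upper) & y >= upper
  interior <- !at_lower & !at_upper
  dmu <- numeric(length(y))
  dsigma <- numeric(length(y))
  if (any(interior)) {
    r <- y[interior] - mu[interior]
    dmu[interior] <- r/sigma^2
    dsigma[interior] <- (r^2/sigma^2 - 1)/sigma
  }
  if (any(at_lower)) {
    z <- (lower - mu[at_lower])/sigma
    lam <- exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
    dmu[at_lower] <- -lam/sigma
    dsigma[at_lower] <- -z * lam/sigma
  }
  if (any(at_upper)) {
    z <- (upper - mu[at_upper])/sigma
    lam <- exp(stats::dnorm(z, log = TRUE) -
                 stats::pnorm(z, lower.tail = FALSE, log.p = TRUE))
    dmu[at_upper] <- lam/sigma
    dsigma[at_upper] <- z * lam/sigma
  }
  list(dmu = dmu, dsigma = dsigma)
}
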