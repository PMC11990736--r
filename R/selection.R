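#' Default thresholds of the parsimony criteria
#'
#' Strict thresholds used to accept a candidate group number: every estimated
#' membership proportion must exceed `membership_min`, every membership
#' p-value must fall below `pvalue_max`, and every subject's maximum
#' posterior probability must exceed `bpp_min`. Homogeneity (k = 1) is
#' rejected only when the selected model beats the single-group BIC by more
#' than `delta_bic_min`.
#'
#' @return Named list of the four thresholds.
#' @export
parsimony_thresholds <- function() {
  list(membership_min = 0.10, pvalue_max = 0.1, bpp_min = 0.95,
       delta_bic_min = 10)
}

#' Apply the parsimony criteria to a fitted candidate
#'
#' Evaluates the three acceptance flags for one candidate: membership sizes,
#' membership p-values (trajectory-coefficient p-values are deliberately not
#' part of the rule), and per-subject maximum posterior probability. All
#' comparisons are strict inequalities. For the k = 1 baseline the flags are
#' not applicable (`NA`): membership is 100% with no p-value and every
#' posterior is 1.
#'
#' @param fit A `traj_fit`.
#' @param thresholds Threshold list as from [parsimony_thresholds()].
#' @return List with logical `memberships_ok`, `pvalues_ok`, `bpp_ok` and the
#'   underlying quantities (`min_membership`, `max_membership_p`, `min_max_bpp`).
#' @export
apply_parsimony_criteria <- function(fit, thresholds = parsimony_thresholds()) {
  stopifnot(inherits(fit, "traj_fit"))
  min_max_bpp <- min(apply(unclass(fit$posterior), 1L, max))
  if (fit$spec$k == 1L) {
    return(list(memberships_ok = NA, pvalues_ok = NA, bpp_ok = NA,
                min_membership = 1, max_membership_p = NA_real_,
                min_max_bpp = min_max_bpp))
  }
  est <- fit$estimates
  if (is.null(est)) est <- wald_tests(fit)
  mem <- est[est$parameter == "Membership(%)", , drop = FALSE]
  max_p <- suppressWarnings(max(mem$p))
  list(
    memberships_ok = all(fit$params$pi > thresholds$membership_min),
    pvalues_ok = all(is.finite(mem$p)) && max_p < thresholds$pvalue_max,
    bpp_ok = min_max_bpp > thresholds$bpp_min,
    min_membership = min(fit$params$pi),
    max_membership_p = max_p,
    min_max_bpp = min_max_bpp
  )
}

#' Fit and flag a range of candidate group numbers
#'
#' Fits one trajectory mixture per requested `k` (same polynomial order and
#' fitting options for all candidates) and evaluates the parsimony criteria
#' on each. Non-convergent candidates are flagged and later excluded from
#' selection.
#'
#' @param data Long table with `subject_id`, `day`, `value`.
#' @param k_values Candidate group counts, each >= 1.
#' @param order Polynomial order shared by all groups.
#' @param thresholds Criteria thresholds.
#' @param lower_bound,upper_bound Censoring limits of the outcome.
#' @param ... Passed to [fit_trajectories()] (e.g. `n_starts`, `seed`).
#' @return List of candidate summaries (class `traj_candidates`); each
#'   element holds `k`, the flags, `bic_obs`, `converged` and the full `fit`.
#' @export
scan_candidates <- function(data, k_values = 1:4, order = 2L,
                            thresholds = parsimony_thresholds(),
                            lower_bound = 0, upper_bound = Inf, ...) {
  if (!length(k_values) || any(k_values < 1L)) {
    stop("k_values must be a non-empty set of counts >= 1", call. = FALSE)
  }
  out <- lapply(k_values, function(k) {
    spec <- trajectory_spec(k, order, lower_bound, upper_bound)
    fit <- withCallingHandlers(
      fit_trajectories(data, spec, ...),
      warning = function(w) {
        if (grepl("did not converge", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    crit <- apply_parsimony_criteria(fit, thresholds)
    c(list(k = as.integer(k), bic_obs = fit$bic_obs,
           converged = fit$converged, fit = fit), crit)
  })
  structure(out, class = "traj_candidates")
}

#' Select the most parsimonious group number
#'
#' Among candidates passing all three criteria (the k = 1 baseline is always
#' eligible; non-convergent candidates never are), selects the one with the
#' largest BIC on the all-observations convention. Homogeneity is rejected
#' when the selected k exceeds 1 and its BIC beats the k = 1 BIC by more than
#' `delta_bic_min` (strictly). If no candidate passes, the report falls back
#' to k = 1 with a warning. The result does not depend on the order in which
#' candidates are supplied.
#'
#' @param candidates A `traj_candidates` list from [scan_candidates()].
#' @param thresholds Threshold list (only `delta_bic_min` is used here).
#' @return A `selection_report`: `candidates` (summary data frame),
#'   `selected_k`, `delta_bic_vs_k1`, `homogeneity_rejected`, and the
#'   selected fit.
#' @export
select_most_parsimonious <- function(candidates,
                                     thresholds = parsimony_thresholds()) {
  stopifnot(length(candidates) >= 1L)
  tab <- do.call(rbind, lapply(candidates, function(cc) {
    data.frame(k = cc$k, memberships_ok = cc$memberships_ok,
               pvalues_ok = cc$pvalues_ok, bpp_ok = cc$bpp_ok,
               bic_obs = cc$bic_obs,
               converged = if (is.null(cc$converged)) TRUE else cc$converged,
               min_max_bpp = if (is.null(cc$min_max_bpp)) NA_real_ else cc$min_max_bpp)
  }))
  tab <- tab[order(tab$k), , drop = FALSE]
  rownames(tab) <- NULL

  passes <- vapply(candidates, function(cc) {
    (is.null(cc$converged) || isTRUE(cc$converged)) &&
      (cc$k == 1L || (isTRUE(cc$memberships_ok) && isTRUE(cc$pvalues_ok) &&
                        isTRUE(cc$bpp_ok)))
  }, logical(1L))
  ks <- vapply(candidates, `[[`, integer(1L), "k")
  bics <- vapply(candidates, `[[`, numeric(1L), "bic_obs")

  if (!any(passes)) {
    warning("no candidate passed the parsimony criteria; falling back to k = 1",
            call. = FALSE)
    selected_k <- 1L
    sel_fit <- if (any(ks == 1L)) candidates[[which(ks == 1L)[1L]]]$fit else NULL
  } else {
    eligible <- which(passes)
    best <- eligible[which.max(bics[eligible])]
    selected_k <- ks[best]
    sel_fit <- candidates[[best]]$fit
  }

  bic_k1 <- if (any(ks == 1L)) bics[which(ks == 1L)[1L]] else NA_real_
  delta <- if (selected_k > 1L && is.finite(bic_k1)) {
    bics[which(ks == selected_k)[1L]] - bic_k1
  } else if (selected_k == 1L) 0 else NA_real_
  rejected <- isTRUE(selected_k > 1L && is.finite(delta) &&
                       delta > thresholds$delta_bic_min)

  structure(
    list(candidates = tab, selected_k = selected_k,
         delta_bic_vs_k1 = delta, homogeneity_rejected = rejected,
         fit = sel_fit),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Group-number selection (parsimony procedure)\n")
  print(x$candidates, row.names = FALSE)
  cat(sprintf("selected k = %d; BIC gain over k = 1: %s; homogeneity rejected: %s\n",
              x$selected_k,
              ifelse(is.na(x$delta_bic_vs_k1), "NA",
                     sprintf("%.1f", x$delta_bic_vs_k1)),
              x$homogeneity_rejected))
  invisible(x)
}
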