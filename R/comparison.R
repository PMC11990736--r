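#' Subject-level bin means with group labels
#'
#' Collapses a long table to one value per (subject, bin) via [bin_average()]
#' and attaches each subject's assigned trajectory group. This is the
#' subject-level unit of analysis for the group comparisons.
#'
#' @param data Long table with `subject_id`, `day`, `value`.
#' @param assignments Named vector (names = subject ids) or vector indexed by
#'   subject of hard group assignments, e.g. from [classify()].
#' @param bin_width Bin width in days.
#' @return Data frame `subject_id`, `group`, `bin`, `value`.
#' @export
subject_bin_means <- function(data, assignments, bin_width = 5L) {
  binned <- bin_average(data, bin_width)
  ids <- as.character(binned$subject_id)
  g <- if (!is.null(names(assignments))) assignments[ids]
       else assignments[binned$subject_id]
  if (anyNA(g)) {
    stop("every subject must have a group assignment; missing: ",
         paste(unique(ids[is.na(g)]), collapse = ", "), call. = FALSE)
  }
  data.frame(subject_id = binned$subject_id, group = as.integer(g),
             bin = binned$bin, value = binned$value)
}

#' Group mean +/- SEM per time bin
#'
#' Per (group, bin): mean and standard error of the mean over the subject
#' -level bin means, and the number of contributing subjects. A cell with a
#' single subject has an undefined SEM, reported as `NA`.
#'
#' @inheritParams subject_bin_means
#' @return Data frame `group`, `bin`, `mean`, `sem`, `n`.
#' @export
summarize_groups <- function(data, assignments, bin_width = 5L) {
  sb <- subject_bin_means(data, assignments, bin_width)
  out <- do.call(rbind, lapply(split(sb, list(sb$group, sb$bin), drop = TRUE),
                               function(cell) {
    n <- nrow(cell)
    data.frame(group = cell$group[1L], bin = cell$bin[1L],
               mean = mean(cell$value),
               sem = if (n > 1L) stats::sd(cell$value)/sqrt(n) else NA_real_,
               n = n)
  }))
  out <- out[order(out$group, out$bin), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-way ANOVA with per-bin Tukey post hoc comparisons
#'
#' Group x time factorial ANOVA on the subject-level bin means (subject as
#' the observational unit), followed by Tukey honest-significant-difference
#' comparisons among groups within each bin. The Tukey adjusted p-value uses
#' the studentized-range distribution on the within-bin error; the unadjusted
#' pairwise p (same statistic, t reference) is reported alongside.
#'
#' @param binned Subject-level table from [subject_bin_means()] (columns
#'   `group`, `bin`, `value`).
#' @param alpha Significance level for the `significant` flag.
#' @return A `comparison_result`: `anova` (F and p for group, time,
#'   interaction), `tukey` (per bin and group pair: difference, SE,
#'   unadjusted and adjusted p, significance), `group_means` (per bin and
#'   group), `alpha`.
#' @export
two_way_anova_tukey <- function(binned, alpha = 0.05) {
  g <- factor(binned$group)
  b <- factor(binned$bin)
  if (nlevels(g) < 2L || nlevels(b) < 2L) {
    stop("need at least 2 groups and 2 bins", call. = FALSE)
  }
  cells <- table(g, b)
  if (any(cells == 0L)) {
    bad <- which(cells == 0L, arr.ind = TRUE)[1L, ]
    stop(sprintf("empty cell: group %s, bin %s",
                 rownames(cells)[bad[1L]], colnames(cells)[bad[2L]]),
         call. = FALSE)
  }

  fit <- stats::aov(value ~ g * b, data = data.frame(value = binned$value,
                                                     g = g, b = b))
  tab <- summary(fit)[[1L]]
  anova <- data.frame(
    term = c("group", "time", "interaction"),
    df = tab[1:3, "Df"],
    F = tab[1:3, "F value"],
    p = tab[1:3, "Pr(>F)"]
  )

  tukey <- do.call(rbind, lapply(levels(b), function(bi) {
    sub <- binned[b == bi, , drop = FALSE]
    gi <- factor(sub$group)
    m <- tapply(sub$value, gi, mean)
    n <- tapply(sub$value, gi, length)
    k <- nlevels(gi)
    df <- nrow(sub) - k
    mse <- sum(stats::resid(stats::lm(value ~ gi, data = sub))^2)/df
    pairs <- utils::combn(levels(gi), 2L)
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(pp) {
      a <- pairs[1L, pp]; bb <- pairs[2L, pp]
      diff <- m[[bb]] - m[[a]]
      se <- sqrt(mse * (1/n[[a]] + 1/n[[bb]]))
      tstat <- diff/se
      data.frame(bin = as.integer(bi), group1 = as.integer(a),
                 group2 = as.integer(bb), diff = diff, se = se,
                 p_unadj = 2 * stats::pt(-abs(tstat), df),
                 p_adj = stats::ptukey(sqrt(2) * abs(tstat), nmeans = k,
                                       df = df, lower.tail = FALSE))
    }))
  }))
  # the range-based p dominates the pairwise p; guard against rounding at k=2
  tukey$p_adj <- pmax(tukey$p_adj, tukey$p_unadj)
  tukey$significant <- tukey$p_adj < alpha
  rownames(tukey) <- NULL

  gm <- stats::aggregate(list(mean = binned$value),
                         by = list(group = binned$group, bin = binned$bin),
                         FUN = mean)

  structure(list(anova = anova, tukey = tukey, group_means = gm,
                 alpha = alpha),
            class = "comparison_result")
}

#' Label each bin's significance pattern as a study phase
#'
#' For a three-group comparison, classifies each time bin by its Tukey
#' pattern, ranking groups by their bin mean: "early" when the lowest two
#' groups are indistinguishable and both differ from the top group,
#' "transition" when all pairs differ, "end" when the top two groups are
#' indistinguishable and both differ from the lowest, and "other" for any
#' remaining pattern.
#'
#' @param comparison A `comparison_result` from [two_way_anova_tukey()].
#' @return Data frame `bin`, `phase`.
#' @export
label_phases <- function(comparison) {
  stopifnot(inherits(comparison, "comparison_result"))
  groups <- sort(unique(comparison$group_means$group))
  if (length(groups) < 3L) {
    stop("phase labeling requires at least 3 groups", call. = FALSE)
  }
  do.call(rbind, lapply(sort(unique(comparison$tukey$bin)), function(bi) {
    gm <- comparison$group_means[comparison$group_means$bin == bi, ]
    ord <- gm$group[order(gm$mean)] # low, mid, top by bin mean
    tk <- comparison$tukey[comparison$tukey$bin == bi, ]
    sig <- function(a, b) {
      row <- tk[(tk$group1 == a & tk$group2 == b) |
                  (tk$group1 == b & tk$group2 == a), ]
      isTRUE(row$significant[1L])
    }
    low <- ord[1L]; mid <- ord[2L]; top <- ord[3L]
    phase <- if (!sig(low, mid) && sig(low, top) && sig(mid, top)) {
      "early"
    } else if (sig(low, mid) && sig(low, top) && sig(mid, top)) {
      "transition"
    } else if (sig(low, mid) && sig(low, top) && !sig(mid, top)) {
      "end"
    } else "other"
    data.frame(bin = bi, phase = phase)
  }))
}

#' Group-by-regimen contingency table
#'
#' Counts classified subjects per (trajectory group, regimen). Reported
#' descriptively, with no test attached, mirroring how the reference study
#' read the regimen balance of its drinking groups.
#'
#' @param assignments Hard group assignments (named by subject id or indexed
#'   by subject).
#' @param regimen Per-subject regimen labels, aligned with `assignments`.
#' @return Integer matrix, one row per group, one column per regimen level.
#' @export
#' @examples
#' regimen_crosstab(classify(reference_posteriors()),
#'                  ifelse(1:35 <= 18, "5pct", "10pct"))
regimen_crosstab <- function(assignments, regimen) {
  if (length(regimen) != length(assignments) || anyNA(regimen)) {
    stop("every subject needs a regimen label", call. = FALSE)
  }
  tab <- table(group = assignments, regimen = regimen)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(group = rownames(tab),
                              regimen = colnames(tab)))
  m
}
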