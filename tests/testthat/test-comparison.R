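make_binned <- function(n_per_group = 6L, bins = 1:4, group_shift = c(0, 0, 0),
                        sd = 1, seed = 1L) {
  set.seed(seed)
  grid <- expand.grid(subject = seq_len(3L * n_per_group), bin = bins)
  grid$group <- (grid$subject - 1L) %/% n_per_group + 1L
  data.frame(subject_id = grid$subject, group = grid$group, bin = grid$bin,
             value = group_shift[grid$group] + rnorm(nrow(grid), sd = sd))
}

test_that("group summaries compute mean, SEM and subject counts per bin", {
  df <- data.frame(subject_id = rep(1:4, each = 10),
                   day = rep(1:10, times = 4), value = 2)
  assign <- setNames(c(1L, 1L, 2L, 2L), 1:4)
  s <- summarize_groups(df, assign, bin_width = 5L)
  expect_true(all(s$mean == 2))
  expect_true(all(s$sem == 0))
  expect_true(all(s$n == 2L))

  # single bin, two subjects with values 1 and 3: mean 2, SEM 1
  df2 <- data.frame(subject_id = c(1L, 2L), day = c(1L, 1L), value = c(1, 3))
  s2 <- summarize_groups(df2, setNames(c(1L, 1L), 1:2), bin_width = 5L)
  expect_equal(s2$mean, 2)
  expect_equal(s2$sem, 1)

  # a one-subject group has undefined SEM
  s3 <- summarize_groups(df2, setNames(c(1L, 2L), 1:2), bin_width = 5L)
  expect_true(all(is.na(s3$sem)))

  expect_error(summarize_groups(df2, setNames(1L, "1"), 5L), "assignment")
})

test_that("default cohort summaries carry the reference group sizes", {
  cohort <- generate_cohort(study_design(seed = 2L), generating_model())
  truth <- cohort$latent_group[!duplicated(cohort$subject_id)]
  names(truth) <- cohort$subject_id[!duplicated(cohort$subject_id)]
  s <- summarize_groups(cohort, truth, bin_width = 5L)
  sizes <- tapply(s$n, s$group, max)
  expect_equal(unname(sizes), c(4L, 26L, 5L), ignore_attr = TRUE)
})

test_that("two-way ANOVA reports the factorial terms and catches empty cells", {
  b <- make_binned(group_shift = c(0, 0, 3), seed = 3L)
  res <- two_way_anova_tukey(b)
  expect_identical(res$anova$term, c("group", "time", "interaction"))
  expect_lt(res$anova$p[1], 0.001)

  bad <- b[!(b$group == 2 & b$bin == 3), ]
  expect_error(two_way_anova_tukey(bad), "empty cell: group 2, bin 3")
  expect_error(two_way_anova_tukey(b[b$group == 1, , drop = FALSE]), "2 groups")
})

test_that("identical groups are not separated by Tukey", {
  b <- make_binned(group_shift = c(0, 0, 0), seed = 4L)
  res <- two_way_anova_tukey(b)
  expect_true(all(res$tukey$p_adj > res$alpha))
})

test_that("Tukey adjusted p dominates the unadjusted pairwise p", {
  b <- make_binned(group_shift = c(0, 1, 2), seed = 5L)
  res <- two_way_anova_tukey(b)
  expect_true(all(res$tukey$p_adj >= res$tukey$p_unadj - 1e-12))
})

test_that("per-bin Tukey p-values agree with stats::TukeyHSD", {
  b <- make_binned(group_shift = c(0, 0.8, 2), bins = 1:2, seed = 6L)
  res <- two_way_anova_tukey(b)
  one_bin <- b[b$bin == 1L, ]
  hsd <- TukeyHSD(aov(value ~ factor(group), data = one_bin))[[1]]
  mine <- res$tukey[res$tukey$bin == 1L, ]
  # rows of TukeyHSD are 2-1, 3-1, 3-2; match on the pair labels
  key <- paste(mine$group2, mine$group1, sep = "-")
  expect_equal(mine$p_adj[match(rownames(hsd), key)], unname(hsd[, "p adj"]),
               tolerance = 1e-8)
})

test_that("interaction p-values are uniform under the null", {
  pvals <- vapply(1:200, function(s) {
    b <- make_binned(n_per_group = 5L, bins = 1:3, seed = 1000L + s)
    two_way_anova_tukey(b)$anova$p[3]
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

fake_comparison <- function(sig, means) {
  # sig: named logical for pairs "1-2", "1-3", "2-3"; means: per group
  tukey <- data.frame(bin = 1L, group1 = c(1L, 1L, 2L), group2 = c(2L, 3L, 3L),
                      diff = 0, se = 1, p_unadj = 0.5, p_adj = 0.5,
                      significant = unname(sig[c("1-2", "1-3", "2-3")]))
  structure(list(anova = NULL, tukey = tukey,
                 group_means = data.frame(group = 1:3, bin = 1L, mean = means),
                 alpha = 0.05),
            class = "comparison_result")
}

test_that("phase labels encode the published significance patterns", {
  # early phase: late (1) and non (2) drinkers low and indistinguishable,
  # both below the early drinkers (3)
  early <- fake_comparison(c(`1-2` = FALSE, `1-3` = TRUE, `2-3` = TRUE),
                           means = c(1.0, 1.1, 4.0))
  expect_identical(label_phases(early)$phase, "early")

  # transition: all pairwise distinct
  trans <- fake_comparison(c(`1-2` = TRUE, `1-3` = TRUE, `2-3` = TRUE),
                           means = c(3.0, 1.2, 5.0))
  expect_identical(label_phases(trans)$phase, "transition")

  # end phase: late (1) and early (3) drinkers high and indistinguishable,
  # both above the non-drinkers (2)
  end <- fake_comparison(c(`1-2` = TRUE, `1-3` = FALSE, `2-3` = TRUE),
                         means = c(5.5, 1.3, 5.8))
  expect_identical(label_phases(end)$phase, "end")

  # anything else is "other"
  odd <- fake_comparison(c(`1-2` = FALSE, `1-3` = FALSE, `2-3` = TRUE),
                         means = c(1, 2, 3))
  expect_identical(label_phases(odd)$phase, "other")
})

test_that("regimen cross-tab reproduces the reference counts", {
  assign <- classify(reference_posteriors())
  regimen <- ifelse(1:35 <= 18, "5pct", "10pct")
  ct <- regimen_crosstab(assign, regimen)
  expect_equal(ct["1", "5pct"], 2L, ignore_attr = TRUE)
  expect_equal(ct["1", "10pct"], 2L, ignore_attr = TRUE)
  expect_equal(ct["3", "5pct"], 3L, ignore_attr = TRUE)
  expect_equal(ct["3", "10pct"], 2L, ignore_attr = TRUE)
  # row sums equal group sizes, grand total the cohort size
  expect_equal(unname(rowSums(ct)), c(4, 26, 5))
  expect_equal(sum(ct), 35)

  one <- regimen_crosstab(assign, rep("10pct", 35))
  expect_identical(ncol(one), 1L)
  expect_error(regimen_crosstab(assign, regimen[1:10]), "regimen")
})
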