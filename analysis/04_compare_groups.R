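#!/usr/bin/env Rscript
# Stage 4: phenotype comparison of the classified trajectory groups.
#
# 5-day-binned group means +/- SEM, two-way (group x time) ANOVA on the
# subject-level bin means with per-bin Tukey post hoc comparisons, phase
# labels from the per-bin significance patterns (early / transition / end),
# and the group-by-regimen cross-tabulation.

suppressPackageStartupMessages(library(trajmix))

cohort <- read_long_csv("results/cohort.csv")
post <- read.delim("results/posteriors.tsv")
assignments <- setNames(as.integer(post$assignment),
                        as.character(post$subject_id))

summary_tab <- summarize_groups(cohort, assignments, bin_width = 5L)
write.table(summary_tab, "results/binned_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

sb <- subject_bin_means(cohort, assignments, bin_width = 5L)
comparison <- two_way_anova_tukey(sb, alpha = 0.05)
write.table(comparison$tukey, "results/anova_tukey.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("two-way ANOVA:\n")
print(comparison$anova, digits = 4)

phases <- label_phases(comparison)
write.table(phases, "results/phases.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat("\nper-bin phase labels (bins are 5-day windows):\n")
print(phases, row.names = FALSE)

reg <- cohort$regimen[!duplicated(cohort$subject_id)]
names(reg) <- cohort$subject_id[!duplicated(cohort$subject_id)]
ct <- regimen_crosstab(assignments, reg[names(assignments)])
cat("\ngroup x regimen counts:\n")
print(ct)
write.table(data.frame(group = rownames(ct), unclass(ct)),
            "results/crosstab.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
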