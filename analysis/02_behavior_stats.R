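#!/usr/bin/env Rscript
# Behavioral statistics on the simulated cohort: per-cell accuracy and RT,
# signal-detection sensitivity (d') and criterion (c) per payoff condition,
# the paired comparisons across run types, TOST equivalence tests on the
# sensitivity difference, and the Item x Run repeated-measures ANOVA.
# Run 01_simulate_behavior.R first.

suppressPackageStartupMessages(library(plsmem))
out <- "results/behavior"
responses <- read.table(file.path(out, "responses.tsv"), header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)

rates <- score_responses(responses)
write.table(rates, file.path(out, "rates.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

cell_means <- aggregate(rate ~ run_type + item_type, rates, mean)
cat("Group mean accuracy rates:\n")
print(cell_means, row.names = FALSE)

sdt <- sdt_summary(rates)
write.table(sdt, file.path(out, "sdt_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
g <- aggregate(cbind(d_prime, c) ~ run_type, sdt, mean)
cat("\nGroup mean SDT measures (per-subject averages):\n")
print(g, row.names = FALSE)

c_old <- sdt$c[sdt$run_type == "incentivize-old"]
c_new <- sdt$c[sdt$run_type == "incentivize-new"]
d_old <- sdt$d_prime[sdt$run_type == "incentivize-old"]
d_new <- sdt$d_prime[sdt$run_type == "incentivize-new"]
tc <- paired_t(c_old, c_new)
td <- paired_t(d_old, d_new)
cat(sprintf("\nCriterion shift: t(%d) = %.2f, p = %.2g (liberal when old rewarded)\n",
            tc$df, tc$t, tc$p))
cat(sprintf("Sensitivity difference: t(%d) = %.2f, p = %.2g, dz = %.2f\n",
            td$df, td$t, td$p, td$dz))

tost_med <- tost_paired(td$dz, length(d_old), bound = 0.50)
tost_lrg <- tost_paired(td$dz, length(d_old), bound = 0.80)
cat(sprintf("TOST medium bound (0.50): binding t(%d) = %.2f, p = %.3f -> %s\n",
            tost_med$df, tost_med$t_binding, tost_med$p_binding,
            if (tost_med$equivalent) "equivalent" else "not equivalent"))
cat(sprintf("TOST large bound (0.80): binding t(%d) = %.2f, p = %.3f -> %s\n",
            tost_lrg$df, tost_lrg$t_binding, tost_lrg$p_binding,
            if (tost_lrg$equivalent) "equivalent" else "not equivalent"))

acc <- rates
acc$value <- acc$rate
aov_tab <- rm_anova_2way(acc)
write.table(aov_tab, file.path(out, "anova.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nItem x Run repeated-measures ANOVA on accuracy:\n")
print(aov_tab, row.names = FALSE)

stats_json <- list(
  criterion_t = tc[c("t", "df", "p", "dz")],
  sensitivity_t = td[c("t", "df", "p", "dz")],
  tost_medium = tost_med[c("bound", "t_binding", "p_binding", "equivalent")],
  tost_large = tost_lrg[c("bound", "t_binding", "p_binding", "equivalent")])
jsonlite::write_json(stats_json, file.path(out, "behavior_stats.json"),
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)
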