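#!/usr/bin/env Rscript
# Simulate the behavioral experiment: a 14-subject cohort, 8 test runs of
# 64 words (16 once-studied, 16 thrice-studied, 32 new) plus 4 null events,
# with the payoff manipulation (incentivize-old vs incentivize-new runs)
# shifting the response criterion. Writes the design events and the
# trial-level response table.

suppressPackageStartupMessages(library(plsmem))
out <- "results/behavior"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

params <- design_params()
pool <- generate_word_pool(params, seed = 1001)
design <- generate_design(pool, params, counterbalance_id = 1, seed = 1002)
write_events_tsv(design, file.path(out, "events"))

responses <- simulate_responses(sdt = sdt_params(), params = params,
                                seed = 1003)
write.table(responses, file.path(out, "responses.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Design: ", length(design$runs), "runs x",
    params$words_per_run, "words +", params$n_null, "nulls;",
    nrow(design$study_list), "studied words\n")
cat("Responses:", nrow(responses), "trials from",
    params$n_subjects, "subjects ->", file.path(out, "responses.tsv"), "\n")
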