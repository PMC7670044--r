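#!/usr/bin/env Rscript
# Event-related GLM demonstration: simulate one subject's BOLD run from the
# generated design and a canonical double-gamma HRF, then recover the
# per-condition betas by least squares and report recovery fidelity.

suppressPackageStartupMessages(library(plsmem))
out <- "results/glm"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

params <- design_params()
pool <- generate_word_pool(params, seed = 2001)
design <- generate_design(pool, params, counterbalance_id = 1, seed = 2002)

hrf <- canonical_hrf(TR = 2)
n_vox <- 200
set.seed(2003)

runs <- list(); designs <- list(); truth <- list()
for (r in 1:4) {
  ev <- design$runs[[r]]
  n_scans <- ceiling((max(ev$onset_ms) / 1000 + 30) / 2)
  X <- build_design_matrix(ev, n_scans, hrf)
  B <- matrix(rnorm(ncol(X$X) * n_vox, sd = 1), ncol(X$X), n_vox,
              dimnames = list(X$regressor_names, NULL))
  runs[[r]] <- simulate_bold(X, B, noise_sd = 1)
  designs[[r]] <- X
  truth[[r]] <- B
}
betas <- glm_condition_betas(runs, designs, conditions = c("1x", "3x", "new"))
true_avg <- Reduce(`+`, lapply(truth, function(B)
  B[c("1x", "3x", "new"), ])) / length(truth)

rho <- cor(as.numeric(true_avg), as.numeric(betas))
cat(sprintf("Recovered condition betas over %d voxels x 4 runs at SNR 1: r = %.4f\n",
            n_vox, rho))
write.table(data.frame(condition = rownames(betas),
                       mean_beta = rowMeans(betas),
                       recovery_r = rho),
            file.path(out, "beta_recovery.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("HRF peaks at", hrf$fine_times[which.max(hrf$fine_kernel)],
    "s post onset; undershoot depth",
    sprintf("%.2f", min(hrf$fine_kernel)), "\n")
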