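#!/usr/bin/env Rscript
## Stage 6 — multivariate marker-panel classification.
##
## RBF-kernel SVM over panels of 5, 10 and 50 markers chosen by a
## stepwise-forward significance filter inside every training fold,
## evaluated by 10 repetitions of stratified 10-fold cross-validation,
## with a random-label permutation null to expose overtraining.

suppressPackageStartupMessages(library(mirct))
seed <- as.integer(Sys.getenv("MIRCT_SEED", "1"))

delta <- as.matrix(read.delim("results/delta_ct.tsv", row.names = 1,
                              check.names = FALSE))
samples <- read_samples("results/data/samples.tsv")

cfg <- classifier_config(panel_sizes = c(5L, 10L, 50L), n_repetitions = 10L,
                         n_folds = 10L, n_permutations = 10L,
                         seed = seed + 2L)

rows <- list()
for (cn in list(c("NSCLC", "control"), c("NSCLC", "COPD"))) {
  key <- paste0(cn[1], "_vs_", cn[2])
  cat(sprintf("--- %s ---\n", key))
  res <- cross_validate(delta, samples, cn, cfg)
  print(res)
  pn <- permutation_null(delta, samples, cn, cfg, observed = res)
  for (k in names(res$panels)) {
    m <- res$panels[[k]]$metrics
    null_acc <- mean(pn$panels[[k]]$null$accuracy)
    cat(sprintf("  k=%s: permutation-null accuracy %.1f%%, empirical p = %.3f\n",
                k, null_acc, pn$panels[[k]]$p_empirical))
    top <- head(res$panels[[k]]$selection_freq, 5)
    cat(sprintf("  consensus markers: %s\n",
                paste(sprintf("%s (%.0f%%)", names(top), 100 * top),
                      collapse = ", ")))
    rows[[paste(key, k)]] <- cbind(contrast = key, panel_size = as.integer(k),
                                   m, null_accuracy = null_acc,
                                   p_permutation = pn$panels[[k]]$p_empirical)
  }
}
write_tsv(do.call(rbind, rows), "results/classification.tsv")
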