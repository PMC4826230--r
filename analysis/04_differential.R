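#!/usr/bin/env Rscript
## Stage 4 — per-marker differential statistics.
##
## For each pairwise contrast: Welch t and Wilcoxon rank-sum p-values with
## Benjamini-Hochberg adjustment across the expressed panel, and the
## Mann-Whitney AUC (disease group positive; AUC < 0.5 = higher expression
## in disease). Adds the three-group one-way ANOVA and the Venn partition
## of up/down-regulated marker sets across the two contrasts.

suppressPackageStartupMessages(library(mirct))

delta <- as.matrix(read.delim("results/delta_ct.tsv", row.names = 1,
                              check.names = FALSE))
samples <- read_samples("results/data/samples.tsv")

contrasts <- list(c("NSCLC", "control"), c("NSCLC", "COPD"))
stats <- list()
for (cn in contrasts) {
  key <- paste0(cn[1], "_vs_", cn[2])
  st <- two_group_stats(delta, samples, cn)
  stats[[key]] <- st
  cat(sprintf("%s: %d markers significant raw (t), %d after BH\n",
              key, sum(st$p_t < 0.05), sum(st$q_t < 0.05)))
  write_tsv(as.data.frame(st), sprintf("results/diff_%s.tsv", key))
}

av <- anova_three_group(delta, samples)
cat(sprintf("three-group ANOVA: %d significant raw, %d after BH\n",
            sum(av$p < 0.05), sum(av$q < 0.05)))
top <- av[order(av$p)[1:5], ]
cat("top ANOVA markers:", paste(sprintf("%s (p=%.2g)", top$assay_id, top$p),
                                collapse = ", "), "\n")
write_tsv(av, "results/anova.tsv")

vp <- venn_partition(stats[[1]], stats[[2]], alpha = 0.05)
print(vp)
write_tsv(vp$overlaps, "results/venn_overlaps.tsv")
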