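#!/usr/bin/env Rscript
## Stage 3 — evaluate endogenous controls and normalize to delta-Ct.
##
## Scores the five candidate controls by mean/SD, CV on the Ct and
## linearized (2^-Ct) scales, NormFinder-style variance-component
## stability, and concordance of the resulting validation AUCs with the
## screening study (including the raw-Ct "none" variant). Normalizes the
## expressed panel to delta-Ct with respect to RNU44.

suppressPackageStartupMessages(library(mirct))

cur_m <- as.matrix(read.delim("results/curated_matrix.tsv", row.names = 1,
                              check.names = FALSE))
cur <- structure(list(values = cur_m,
                      dropped_assays = read.delim("results/dropped_assays.tsv")),
                 class = "curated_ct")
samples <- read_samples("results/data/samples.tsv")
screening <- read_screening("results/data/screening.tsv")

cand <- intersect(default_control_profiles()$name, rownames(cur_m))
report <- rank_controls(cur, samples, cand, screening = screening,
                        contrast = c("NSCLC", "control"))
print(report)
best <- report$control[which.min(report$rank_stability)]
cat(sprintf("most stable control: %s; reference used downstream: RNU44\n", best))

d <- delta_ct(cur, "RNU44")
panel <- readLines("results/expressed_panel.txt")
dpanel <- d$values[intersect(panel, rownames(d$values)), , drop = FALSE]
write_tsv(as.data.frame(report), "results/control_stability.tsv")
write_tsv(dpanel, "results/delta_ct.tsv", rownames_as = "assay_id")
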