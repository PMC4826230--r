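#!/usr/bin/env Rscript
## Stage 1 — simulate the validation cohort.
##
## Generates the default synthetic Fluidigm-style study: 120 blood samples
## (74 NSCLC / 26 COPD / 20 controls), 235 target miRNA assays plus five
## endogenous controls, all in triplicate, with planted group effects and
## Ct-dependent well dropout; plus a matching simulated microarray
## screening table. Writes the raw tables under results/data/.

suppressPackageStartupMessages(library(mirct))
seed <- as.integer(Sys.getenv("MIRCT_SEED", "1"))
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = seed)
study <- generate_study(cfg)
print(study)
screening <- generate_screening_stats(study$truth, noise_sd = 0.05,
                                      seed = seed + 1L)

write_tsv(study$wells, file.path(out, "wells.tsv"))
write_tsv(study$samples, file.path(out, "samples.tsv"))
write_tsv(study$truth, file.path(out, "truth.tsv"))
write_tsv(screening, file.path(out, "screening.tsv"))

cat(sprintf("planted markers: %d per contrast at +/- %.1f cycles\n",
            cfg$n_planted, cfg$effect_size))
cat(sprintf("wrote %s/{wells,samples,truth,screening}.tsv\n", out))
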