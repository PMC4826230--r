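#!/usr/bin/env Rscript
## Stage 2 — curate well-level measurements into the final Ct matrix.
##
## Applies the platform quality protocol: replicates outside the 25-cycle
## linear range of detection or below the 0.65 amplification-curve quality
## score are omitted; surviving replicates are merged to their median; a
## sample x assay cell with no survivor is NA; assays with more than 10
## NAs are dropped; remaining NAs are imputed with the assay's global
## average. Reports the "expressed panel" of reliably detected miRNAs.

suppressPackageStartupMessages(library(mirct))
dir.create("results", showWarnings = FALSE)

wells <- read_wells("results/data/wells.tsv")
cur <- curate_matrix(wells, na_limit = 10, ct_limit = 25, quality_min = 0.65)
print(cur)

controls <- default_control_profiles()$name
panel <- expressed_panel(cur, controls)
cat(sprintf("expressed panel: %d of %d target assays reliably detected\n",
            length(panel), length(unique(wells$assay_id)) - length(controls)))
cat(sprintf("endogenous controls retained: %s\n",
            paste(intersect(controls, rownames(cur$values)), collapse = ", ")))

write_tsv(cur$values, "results/curated_matrix.tsv", rownames_as = "assay_id")
write_tsv(cur$dropped_assays, "results/dropped_assays.tsv")
writeLines(panel, "results/expressed_panel.txt")
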