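#!/usr/bin/env Rscript
## Stage 5 — concordance between screening and validation platforms.
##
## Restricts to markers significant in the screening study (unadjusted
## p < 0.05) and scores directional agreement of the AUCs, with an exact
## binomial test against chance and the 2x2 Fisher variant; reports the
## Pearson correlation of the matched AUC vectors; and quantifies the
## agreement of the two RNA-extraction-kit sample subsets.

suppressPackageStartupMessages(library(mirct))

screening <- read_screening("results/data/screening.tsv")
valid <- read.delim("results/diff_NSCLC_vs_control.tsv")
class(valid) <- c("marker_stats", "data.frame")
samples <- read_samples("results/data/samples.tsv")

m <- match_identifiers(screening, valid$assay_id)
cat(sprintf("identifier matching: %d matched, %d unmatched\n",
            nrow(m$matched), length(m$unmatched)))

conc <- directional_concordance(screening, valid, alpha = 0.05)
print(conc)
ac <- auc_correlation(screening, valid)
cat(sprintf("AUC correlation screening vs validation: r = %.3f (p = %.2g, n = %d)\n",
            ac$r, ac$p, ac$n))
write_tsv(ac$pairs, "results/auc_pairs.tsv")
write_tsv(data.frame(n_matched = conc$n_matched,
                     n_significant = conc$n_significant,
                     n_concordant = conc$n_concordant,
                     percent_concordant = conc$percent_concordant,
                     binom_p = conc$binom_p, fisher_p = conc$fisher_p,
                     auc_cor_r = ac$r, auc_cor_p = ac$p),
          "results/concordance.tsv")

## extraction-kit comparison on the samples measured with each kit
wells <- read_wells("results/data/wells.tsv")
pax <- samples$sample_id[samples$kit == "PAXgene"]
cur_a <- curate_matrix(wells[wells$sample_id %in% pax, ])
cur_b <- curate_matrix(wells[!wells$sample_id %in% pax, ])
kit <- subset_comparison(cur_a, cur_b, samples, samples,
                         c("NSCLC", "control"))
cat(sprintf("kit agreement: Ct correlation %.2f; AUC correlation %.2f\n",
            kit$ct_cor$r, kit$auc_cor$r))
write_tsv(data.frame(ct_cor = kit$ct_cor$r, ct_cor_p = kit$ct_cor$p,
                     auc_cor = kit$auc_cor$r, auc_cor_p = kit$auc_cor$p),
          "results/kit_comparison.tsv")
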