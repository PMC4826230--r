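---
title: "Validating blood miRNA biomarker panels by qRT-PCR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating blood miRNA biomarker panels by qRT-PCR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A biomarker discovery study — typically a genome-wide microarray screen —
proposes a panel of blood-borne miRNAs that separates patients with
non-small cell lung cancer (NSCLC) from patients with chronic obstructive
pulmonary disease (COPD) and from unaffected controls. Before such a panel
can move toward clinical use it must be validated on an independent
platform and cohort, here high-throughput qRT-PCR (Fluidigm-style dynamic
arrays measuring each sample x assay combination in triplicate). `mirct`
implements that validation analysis end to end: well-level curation,
endogenous-control selection, delta-Ct normalization, per-marker
statistics, cross-platform concordance scoring, and multivariate panel
classification — together with a seeded generator of synthetic well-level
data with known ground truth, so that every stage is testable without
access to patient measurements.

All quantities live on the Ct scale: the PCR cycle at which fluorescence
crosses threshold. Ct is a log2-scale abundance measure and *lower Ct
means higher expression*; `2^-Ct` linearizes it.

# Curation of well-level measurements

A replicate well passes when all three hold: it amplified (a Ct exists),
its Ct lies within the 25-cycle linear range of detection, and its
amplification-curve quality score is at least 0.65. Both thresholds are
inclusive for passing: "failing the 0.65 threshold" is read as strictly
below it, and the 25-cycle bound is read as an upper detection limit (high
Ct = low abundance = unreliable), not as a window. Surviving replicates
are merged to their median — with two survivors this is their midpoint;
with none the cell is `NA`. Assays with more than 10 `NA` cells (counted
across all samples, groups pooled) are omitted; the remaining `NA` cells
are imputed with the assay's global average across all samples.

Two consequences of this protocol are worth knowing. Pooled-mean
imputation shrinks group differences for the imputed cells, and the
detection ceiling censors high-Ct values. Both act asymmetrically on
markers whose disease shift points *toward* the ceiling: in simulations,
planted shifts that raise Ct in the large NSCLC group lose noticeably more
power than shifts of the same magnitude in the opposite direction. This is
a property of the curation protocol itself, faithfully reproduced, not a
bug of the implementation.

# Endogenous-control selection

Candidate reference genes (RNU6B, RNU24, RNU44, RNU48, RPL21) are scored
four ways:

* **mean and SD** of the final Ct across samples;
* **CV on the Ct scale** (SD/mean of Ct) and **CV on the linearized
  scale** (SD/mean of `2^-Ct`) — the latter is invariant to a global Ct
  offset, the former is not, so the two can disagree;
* **model-based stability**, a re-implementation of the NormFinder
  variance-decomposition approach (Andersen et al. 2004). Candidate
  values are sample-centered by the mean over the *candidate set only*
  (full-panel centering would leak disease signal into the reference
  estimate), then gene-centered. Per candidate $i$ and group $g$ the
  intragroup variance $\sigma^2_{ig}$ is estimated from the centered
  residuals — solving out the noise that centering mixes in from the
  other candidates, which requires at least three candidates — and the
  intergroup bias $d_{ig}$ is shrunk toward zero in proportion to its
  sampling variance via the method-of-moments intergroup variance
  $\gamma^2$. The stability value is
  $\rho_i = \mathrm{mean}_g\left(|\tilde d_{ig}| +
  \sqrt{\sigma^2_{ig}/n_g}\right)$, lower = more stable. When all group
  biases are indistinguishable from zero ($\gamma^2 = 0$) the measure
  degrades gracefully to the intragroup term. With no group labels the
  measure is the SD of the sample-centered values.
* **concordance with the screening platform**: for each candidate, the
  validation AUC of every panel marker is recomputed on that candidate's
  delta-Ct values and Pearson-correlated with the screening AUCs; a
  `none` variant uses raw Ct, mirroring the question of whether
  normalization helps at all.

Whether the original analysis ran the stability estimator with or without
group labels is not stated anywhere; both modes are exposed
(`groups = NULL` selects the ungrouped estimator), with the grouped
variant as default. Downstream stages default to RNU44 as reference — a
mid-abundance compromise between stability and screening concordance —
overridable everywhere.

Delta-Ct is `dCt(a, s) = Ct(a, s) - Ct(ref, s)`; per-sample additive
effects (RNA input, global efficiency) cancel exactly, and *higher*
delta-Ct means *lower* expression relative to the reference.

# Per-marker statistics

For a two-group contrast written "(A versus B)", A — the disease group —
is the positive class throughout. Per marker:

* Welch's unequal-variance t-test, two-sided (the groups are as unbalanced
  as 74 vs 20, so the equal-variance assumption is not defensible; the
  Student variant is also reported);
* Wilcoxon rank-sum, two-sided, normal approximation with continuity
  correction (imputed cells produce exact ties, which the exact test
  cannot handle);
* Benjamini-Hochberg adjustment, applied separately per test family
  across all markers of the expressed panel within one contrast;
* the Mann-Whitney AUC, ties counted one half: the probability that a
  random A-sample has *larger* delta-Ct than a random B-sample. Under
  this orientation AUC < 0.5 means lower delta-Ct, i.e. *higher*
  expression, in the disease group (`direction = up_in_A`). An AUC of
  exactly 0.5 has no direction.

The three-group comparison is a per-marker one-way fixed-effects ANOVA
with BH adjustment, also reporting which group has the highest mean
delta-Ct (lowest expression). The Venn partition splits each contrast's
significant markers by direction and reports all pairwise overlaps,
including discordant-direction ones.

# Screening-versus-validation concordance

Screening identifiers may predate the validation nomenclature (miRBase
versions); reconciliation is *data* — a user-supplied old-to-new mapping
table applied before an exact join — never sequence computation. Unmatched
identifiers are logged and counted, not dropped silently.

Concordance restricts to markers significant in the screening study at
unadjusted p < 0.05 (adjusted p-values would import the two platforms'
different family sizes into the comparison). A marker is concordant when
`sign(AUC_screen - 0.5) == sign(AUC_valid - 0.5)`; markers with either
AUC exactly 0.5 are excluded from numerator and denominator and counted
separately. The headline significance statement is a two-sided exact
binomial test of the concordant count against chance (p = 0.5). The
original report names "Fisher's exact test" for this step but never
defines the 2x2 table, and its printed p-values cannot be reconstructed
from the printed counts; a 2x2 Fisher variant (significant-in-validation
x concordant) is therefore emitted *alongside* the binomial test, clearly
labelled, rather than pretending to reproduce an unspecified table.

The extraction-kit comparison treats the two kit subsets as independent
mini-studies: per-assay mean Ct and per-assay AUC are computed within
each subset and Pearson-correlated across assays.

# Panel classification

A radial-basis-function C-SVM is evaluated by 10 independent repetitions
of stratified 10-fold cross-validation for panels of 5, 10 and 50
markers. Because no SVM package is available in the target environment,
the classifier is implemented here by solving the soft-margin dual QP
with `quadprog` (Goldfarb-Idnani); the implementation agrees with
scikit-learn's SVC to solver tolerance on shared fixtures.

Design choices, each a convention the original report leaves open:

* **Feature selection inside every training fold.** Markers are ranked
  by Welch-t significance (ties: |AUC - 0.5| descending, then assay id)
  and the top k taken — a stepwise-forward filter. Whether the original
  selection preceded cross-validation is unstated; whole-dataset
  pre-selection inflates accuracy, so the unbiased variant is the
  default, with `preselect = TRUE` reproducing the optimistic protocol.
  The no-leakage property is asserted by a test in which a marker carries
  the class labels only in held-out samples and accuracy must stay at
  chance.
* **Hyperparameters**: cost 1 and kernel width `1/(k * var(values))`, no
  inner tuning loop (none is reported). Overridable.
* **Metrics**: per repetition, pooled fold predictions give accuracy,
  sensitivity and specificity (positive class = disease group); AUC from
  pooled decision values. Reported as the mean over the 10 repetitions
  with a 95% CI of `mean +/- 1.96 * SD` of the repetition-level values —
  matching the symmetric two-point intervals of the original report; this
  is a descriptive convention, not a coverage guarantee.
* **Permutation null**: the *entire* procedure, selection included, is
  re-run with labels permuted once per permutation (default 10); the
  empirical p for the observed accuracy uses the add-one rule
  `(1 + #{null >= obs}) / (n_perm + 1)`. With unbalanced groups the null
  accuracy concentrates at the majority-class proportion (78.7% for 74
  vs 20), not at 50% — the boxes of a permutation figure sit high for
  purely structural reasons.
* **Consensus signature**: the printed signatures of the original figures
  are single lists, but fold-wise selection yields varying subsets; the
  selection frequency of each marker across all training folds is this
  package's answer, flagged as a convention.

# The synthetic cohort

`simulation_config()` states the world once; its defaults are the study's
design wherever that design is printed, and a single documented choice
elsewhere:

| parameter | default | source |
|---|---|---|
| cohort | 74 NSCLC / 26 COPD / 20 controls | printed design |
| assays | 235 targets + 5 controls, triplicate | printed design |
| RNU48, RNU44, RNU6B | (8, 1.4), (12, 2.1), (20.9, 2.0) cycles | printed moments |
| RNU24, RPL21 | (20.5, 1.5), (21.2, 1.6) cycles | "low abundant"/"low expressed"; placed near RNU6B with enough ceiling margin to survive curation, as all five controls did in the real study |
| detection ceiling | 25 cycles | printed threshold |
| quality threshold | 0.65 | printed threshold |
| target baselines | Uniform(12, 27) | chosen so a realistic fraction (roughly a quarter to a third) of the panel fails curation, echoing the 235-to-128 attrition |
| marker noise (`sample_sd`) | 1.0 cycles | typical whole-blood qRT-PCR variability; also the noise level at which recovery properties are stated |
| shared loading (`loading_sd`) | 0.5 cycles | per-sample offset that delta-Ct removes; control profile SDs are observed totals, so each control's intrinsic noise is reduced accordingly |
| triplicate SD | 0.25 cycles | typical microfluidic qRT-PCR replicate agreement |
| planted effects | 30 markers per contrast at +/- 1.5 cycles | the effect size at which recovery is specified; signs alternate |
| dropout | base 0.01, logistic in Ct reaching 1/2 at the ceiling | low-abundance wells fail more often; `dropout_base = 0` models an ideal instrument with no failures at all |
| quality scores | good wells Beta(9, 1.8), failed wells Beta(2.6, 4) | free knobs — no quality-score distribution is reported anywhere; peaks near 0.9 and 0.4 put mass on both sides of the 0.65 threshold |

The generator's measurement model is additive on the Ct scale
(`baseline + group effect + loading + marker noise`, replicates = merged
value + triplicate noise). The matching screening table gives every
marker an AUC of `pnorm(shift/sqrt(2))` plus reporting noise and a
p-value from a unit-variance z-statistic centred on the scaled shift —
so unplanted markers have uniform p-values and exactly-0.5 AUCs in the
noiseless limit.

What the generator does *not* emulate: plate-position effects,
pre-amplification chemistry, microarray intensity distributions,
miRNA-family correlation structure, or any relation between abundance and
effect size. A green simulation-based test therefore establishes that the
*procedures* behave as specified on data obeying the stated model — not
that the original cohort's numbers are reproduced. The headline cohort
results (94.5% accuracy, AUC correlation 0.704, the printed marker
tables) depend on the unavailable patient data; the two statistics that
*are* recomputable from printed counts — the 90.3% and 71.7% directional
concordance rates — are recomputed exactly by the concordance operation
in the test suite.

# Numerical conventions and degenerate inputs

* Threshold boundaries: Ct <= 25 passes, quality >= 0.65 passes.
* An assay whose every cell is `NA` but which survives the NA rule (only
  possible in tiny designs) cannot be imputed and is a named error.
* CV of values with zero mean, correlations of zero-variance vectors, and
  contrasts with an absent group are errors, not NaNs.
* The BH implementation is the step-up definition with cumulative-minimum
  enforcement; ties share one q-value.
* The SVM dual adds a 1e-8 ridge to keep the QP strictly convex; the bias
  is recovered from margin support vectors (fallback: all support
  vectors).
* Cross-validation folds with fewer than two training samples of a class
  raise an error advising fewer folds.
* Every stage that draws random numbers takes a seed; the pipeline
  spawns per-stage seeds from one master seed, so adding a stage never
  perturbs earlier stages' randomness, and identical configurations give
  byte-identical artifacts (the manifest records an md5 of the
  configuration with the output location excluded).

# Known limitations

* Inter-plate calibration against a standard control sample is mentioned
  in the source protocol but not described numerically; it is not
  implemented, and plates appear only as annotation.
* The printed Fisher p-values (4e-11 and 4e-4) are not reproducible from
  printed counts and are not targets.
* The ungrouped stability estimator and the grouped one are not
  comparable on one scale; rankings, not values, are the interface.
* Sensitivity and specificity inherit the class imbalance of the design:
  with 74 vs 20 samples and weak markers, an SVM without class weighting
  drifts toward the majority class. This matches the stated procedure; no
  class weighting is applied because none is reported.
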