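---
title: "Models and methods behind embryosplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind embryosplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`embryosplice` implements a pipeline for studying how cancers re-express
exon-skipping programs of embryonic development. The analysis proceeds in
stages:

1. **Pathway activity over development.** Pathway activity at a timepoint
   is the median of log2(TPM+1) over the pathway's genes. A PCA-space
   smoothing step replaces each activity value with the cosine similarity
   between the pathway's loading vector and the timepoint's score vector
   over the first five principal components, and Ward clustering of the
   smoothed rows at k = 2 splits pathways into an *embryonic-positive*
   (prenatally active) and an *embryonic-negative* class.
2. **EP/EN exon calling.** Each exon-skip event's PSI profile is
   Pearson-correlated with every pathway's activity across timepoints; BH
   adjustment is applied per exon across its tested pathways. An exon is
   EP when at least 10% of the embryonic-positive pathways are
   significantly positively correlated with it while at most 5% are
   significantly negatively correlated; EN mirrors the rule.
3. **Tumor reactivation.** An event is frequently increased (decreased)
   in a tumor cohort when at least 15% of tumors sit more than 2 normal
   SDs above (below) the normal-cohort mean PSI. Overlap of these calls
   with the EP/EN sets is tested by Fisher's exact test with a
   cross-product odds ratio (Haldane +0.5 on zero cells only).
4. **Protein domains.** Domain intervals are merged per domain
   (book-ended intervals merge), intersected with exon coordinates
   (0-based half-open, any overlap counts, strand ignored), and tested
   per domain and class against the background alternative exons
   (enriched when OR > 1 and BH q < 0.1, corrected within class).
5. **Critical splicing factors.** Median EP inclusion per sample is
   regressed on splicing-factor expression by PLS1 (NIPALS), with
   leave-one-out CV choosing the component count and a jackknife over the
   CV segments giving per-factor significance. CSFs are factors with a
   positive coefficient and BH q < 0.05; the top 100 by coefficient form
   the foreground for the regulator analysis.
6. **Causal validation.** Expression-matched mutation effects
   (10 nearest never-mutated tumors per mutant by Euclidean distance over
   z-scored splicing-factor expression; 5% relative change threshold;
   backgrounds discarded above SD 0.1), shRNA knockdown response
   (factor kept only at >= 50% expression knockdown; an EP event responds
   when delta-PSI < -0.1 in both replicates; one-sided rank-sum CSF vs
   non-CSF), and CNV stratification (tertiles by each CSF's expression,
   mean CNV per stratum, rank-sum across CSFs between extreme strata).
7. **Transcription-factor regulators.** A cascade of four filters:
   promoter-binding enrichment (OR > 2, q < 0.05; strict gate), knockdown
   downregulation enrichment (any cell line with OR > 1, q < 0.25),
   inferred-network target enrichment (OR > 2, q < 0.2) and an
   expression-correlation contrast (r with median CSF expression minus r
   with median nCSF expression > 0.2). A TF passes overall when it passes
   the gate and either the knockdown filter or both computational
   filters.

Every Fisher-based test routes through one shared primitive
(`fisher_2x2()`), which the test suite checks against brute-force
hypergeometric summation.

# The synthetic world

All pipeline stages are exercised end to end on a generator with planted
ground truth (`sim_config()`, `simulate_all()`). The generator emulates:

- A developmental time course (12 prenatal + 20 postnatal timepoints) in
  which two mutually exclusive transcriptional programs exchange via a
  logistic switch at the pre/postnatal boundary. Each pathway switches at
  a slightly staggered time (offset SD 2 timepoints, steepness jitter
  30%) and carries its own smooth AR(1) temporal component — without
  this pathway-specific structure all pathway activities would be copies
  of one curve, the per-exon BH family would be perfectly dependent, and
  spurious null-exon calls would track the unadjusted 5% level rather
  than the corrected one. Real pathway sets differ in timing and
  dynamics, so the staggered world is also the more faithful one.
- 442 annotated splicing factors of which 100 (the CSFs) track the
  prenatal program; exon inclusion follows an inverse-logit link on a
  weighted sum of CSF log-expression. Five designated CSFs — the later
  mutation targets — carry 90% of the splicing drive; biologically these
  play the role of master splicing regulators, and statistically a
  concentrated drive is what makes single-factor nonsense mutations
  detectable at the fixed 5% threshold.
- Each exon has its own regulator sensitivity (slope multiplier
  U(0.2, 1.8)). This graded penetrance is what makes tumor reactivation
  stage-dependent in the frequent-event caller: weakly sensitive exons
  deviate only in strongly reactivated tumors, so late-stage strata call
  more EP events and their enrichment odds ratios exceed early-stage
  ones. With uniform penetrance every stratum saturates and the ordering
  is a coin flip.
- A tumor cohort (150 samples) re-expressing the prenatal program with
  per-tumor strength Beta(8m, 8(1-m)) around the mean `m =
  reactivation_strength` (default 0.5), matched normals at the postnatal
  state, nonsense mutations that decouple a CSF from the program in
  carrier samples (replacing its contribution by baseline-level
  fluctuation, so a zero-reactivation cohort remains distributionally
  identical to normals and a noiseless fully-mutated sample reverts
  exactly to the normal median), effect-increasing decoy mutations in
  non-CSFs, CNV gains biased to CSFs in strongly reactivated tumors, and
  tumor stage assigned by reactivation tertile.
- A toy genome (one locus per gene, exons nested in their hosts, one
  inclusion and one exclusion transcript per event), one protein domain
  planted on 50% of EP exons against a 5% background, and decoy domains.
- A regulatory layer: one planted TF binding 85% of CSFs and 5% of
  non-CSFs, 19 decoys with random target sets of the same size, matching
  knockdown signatures, TF expression tracking the reactivated program,
  and per-factor shRNA-style knockdown PSI matrices (two replicates,
  shared controls, delta-PSI -0.2 on EP events for CSF knockdowns).

## Parameters that matter

| parameter | default | units / meaning |
|---|---|---|
| `noise_sd` | 0.5 | SD of Gaussian noise on log2(TPM+1) |
| `psi_noise_sd` | 0.5 | SD of Gaussian noise on logit(PSI) |
| `expr_amp` | 3 | log2 swing of program genes (8-fold) |
| `psi_beta` | 2.5 | logit-PSI swing per unit of splicing drive |
| `reactivation_strength` | 0.5 | mean fraction of prenatal program in tumors |
| `ep_base_psi` / `en_base_psi` | 0.2 / 0.8 | postnatal baseline inclusion |
| `pathway_dynamics_scale` | 2 | pathway-specific AR(1) SD, x `noise_sd` |
| `event_slope_jitter` | 0.8 | per-exon sensitivity range U(0.2, 1.8) |

The amplitude and noise choices put planted developmental correlations
near r = 0.9 and tumor median-EP spread near SD 0.08–0.12 — comparable to
cohort-level inclusion spreads and, importantly, compatible with the
fixed SD > 0.1 background-variability discard of the mutation analysis
(with a 4-logit swing that rule would discard essentially every factor).
The pathway-specific dynamics scale with `noise_sd` so that a noiseless
configuration is fully deterministic, which several construction
identities in the test suite rely on.

## What a green test does and does not establish

The generator plants clean monotone links, Gaussian noise on convenient
scales, a single chromosome, one transcript pair per event and
independent samples. Green recovery tests establish that the
implementation detects the signals it is pointed at, at the stated
thresholds, under this idealized world. They do not establish robustness
to batch effects, correlated noise across events, isoform complexity,
read-level quantification error, or population structure — none of which
the generator emulates.

# Numerical and design choices

- **Log transform.** log2(x+1) throughout; the pseudocount bounds
  activities at 0 for silent genes.
- **PCA orientation and scaling.** Timepoints are observations and
  pathways variables (timepoints have scores, pathways loadings); pathway
  rows are z-scored before PCA (`scale_pathways = TRUE`) so loadings
  reflect temporal shape, not magnitude. Cosine similarity with a zero
  operand is defined as 0.
- **Clustering.** Ward linkage (`ward.D2`) on Euclidean distances, cut at
  two clusters; the cluster with the higher mean smoothed activity over
  prenatal timepoints is embryonic-positive, an exact tie going to the
  smaller cluster (logged).
- **EP/EN rule variants.** The two published phrasings of the "at most
  5%" guard differ in which pathway class carries it; both are
  implemented (`rule = "positive_only"`, the default, evaluates both
  fractions on embryonic-positive pathways; `rule = "cross_class"` moves
  the guard to the embryonic-negative class) and raw counts for both
  readings are emitted for audit.
- **Missing PSI.** Values are missing below `min_total_tpm = 1` total
  transcript TPM and are never imputed; correlations use
  pairwise-complete observations with `min_pairs = 6`, and pairs below
  the floor are excluded from the per-exon BH family rather than given
  p = 1 (assigning p = 1 would deflate the q-values of tested pairs).
- **Odds ratios.** The unconditional cross-product estimate, not the
  conditional MLE; Haldane +0.5 applied to the OR and its normal CI only
  when a cell is zero, never to the exact p-value.
- **PLSR significance.** Jackknife variance of per-factor coefficients
  over the leave-one-out segments, t statistic with df = n - 1. The
  component count minimizes LOO RMSEP (capped at 10); ties take the
  smaller rank.
- **Mutation-effect contrast.** Each mutant sample is compared with the
  median EP of its own 10 nearest never-mutated samples, and the
  per-factor effect is the median of these matched-pair differences,
  relative to the median background level. A pooled-background contrast
  (medians of all mutants vs all matched samples pooled) was implemented
  first and rejected: pooling discards the pairing the matching exists
  to create, so carrier-composition noise swamps the effect whenever
  carriers span a range of reactivation strengths. The SD > 0.1 discard
  is evaluated within each mutant's matched set (mean across sets). The
  5% threshold is read as relative change by default
  (`mode = "absolute"` gives absolute PSI points).
- **"Three quartiles".** Read as tertiles: three equal-frequency strata
  by each CSF's expression, ties broken by stable sample order.
- **BH families.** Per exon across pathways; per class (EP, EN) across
  domains; across TFs for the binding and network filters; across all
  tested (TF, cell line) pairs for the knockdown filter; across gene sets
  for signature correlations.
- **Determinism.** One master seed; each generator draws from a fixed,
  labeled sub-stream so adding a generator never perturbs the draws of
  existing ones. Identical configuration and seed reproduce identical
  output files, which the pipeline manifest checksums verify.

# Known limitations

- The mutation-effect recovery property is marginal in the default
  world: planted effects scale with the carrier's reactivation strength,
  so mutations carried mostly by weakly reactivated tumors fall below
  the fixed 5% threshold and are (correctly) reported untestable. In
  repeated runs roughly 78–80% of mutated CSFs are classified decreased.
- Cross-cohort prediction carries the calibration of the training
  cohort; predictions are deliberately not clipped to [0, 1] and samples
  outside the range are only flagged.
- The pipeline orchestrator runs on simulated inputs; analysis of
  external data goes through the module functions and the file readers
  (`read_matrix_tsv()`, `read_gmt()`, `read_bed()`, `read_events()`)
  rather than `run_pipeline()`.
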