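---
title: "Methods: classifying the tumor origin of individual long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying the tumor origin of individual long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the methods implemented in `readorigin` and the
design of the desk-scale experiments shipped in the test suite. Chunks are
not evaluated at build time; every command runs as shown against the
installed package.

## 1. Problem

A bulk tumor biopsy mixes tumor and non-tumor cells. Long sequencing reads
carry dozens to hundreds of CpG methylation calls each, and methylation is
strongly cell-type specific, so a single read's methylation profile holds
enough signal to assign the read's cell of origin. `readorigin` trains a
per-read binary classifier (tumor vs non-tumor origin) from labels that can
be derived without any methylation information, then uses the classifier
genome-wide.

## 2. Ground-truth labels from genetics alone

Labels come from somatic variants, copy number, purity and haplotype
phasing — never from methylation — so the classifier's input and its
supervision are independent.

**Tumor labels.** A read is labeled tumor when it carries the alternate
allele of a somatic SNV that survives all of:

1. canonical autosome/sex contigs only;
2. long-read caller PASS; short-read caller PASS (strict mode) or merely
   not-germline (relaxed mode);
3. located in a phase block spanning at least 500 kb;
4. at least 3 supporting reads, all on one haplotype, with both haplotypes
   covered at the locus;
5. maximum-likelihood cancer-cell-fraction cluster assignment with
   CCF < 1.1 (clonal or subclonal, not artifactual);
6. a two-tailed binomial test (p ≥ 0.1) that the phase block's
   haplotype-1/haplotype-2 read counts are consistent with the expected
   minor-allele read fraction
   `expected_minor_fraction(rho, n_minor, n_total, n_normal)`.

**Non-tumor labels** come from two independent sources:

* *All-copies variants*: clonal variants (CCF within [0.9, 1.1], from a
  cluster holding ≥ 30% of variants) whose multiplicity is at least their
  allele's copy number sit on every tumor copy of that haplotype. A
  haplotype-matched read covering the locus *without* the variant cannot be
  tumor. A binomial test against
  `expected_allcopies_read_fraction(rho, n_allele)` guards the multiplicity
  assignment.
* *Loss of heterozygosity*: in segments of at least 1 Mb with minor copy
  number 0, major copy number 1–4, at least 20 covering reads, both
  haplotypes present, and an observed lost-haplotype read fraction within
  0.05 of `expected_lost_allele_fraction(rho, n_total)` (also re-checked on
  ~100 kb sub-intervals), reads on the lost haplotype must be non-tumor.

Reads with conflicting evidence are excluded and counted.
`derive_labels()` wraps the full pipeline.

## 3. Per-read features

`build_feature_sets()` attaches, per CpG: the methylation probability
(`(raw + 0.5)/256` from `MM`/`ML` tags), the read-relative position scaled
by a 20 kb denominator and centered (`normalize_positions()`), the 19
sample-wide percentiles (5%…95%) of that site's methylation across all
reads (`compute_site_distribution()`), and the cell-type atlas methylation
values with a missing mask.

## 4. Transformer classifier

`fit_read_classifier()` trains an encoder-only transformer written
natively in R:

* two embedding MLPs — one for the 21 per-CpG scalars, one for the atlas
  vector, with a learned embedding substituted at atlas-missing positions —
  summed with a learned CLS token and scaled (0.05) learned position
  embeddings;
* pre-LayerNorm blocks (gain-only LN), bias-free linear maps, exact GELU,
  per-read multi-head self-attention (no padding: reads are processed as
  variable-length slices of a flattened batch);
* CLS readout to a single logit; weighted binary cross-entropy with
  `positive_weight()` equal to the non-tumor/tumor count ratio;
* AdamW with linear warmup, Gaussian input noise, per-epoch re-subsampling
  of reads above the CpG cap, early stopping on validation AUC (patience
  5) with best-weight restoration.

The full-scale defaults are embed 384, 6 heads, 3 blocks, feed-forward
1536, 511-CpG cap, lr 1e-4, warmup 100. The backward pass is hand-written
and verified against central finite differences to ~1e-10 relative error
(see `test-classifier.R`), including the input-methylation gradient that
the perturbation engine consumes.

Chromosome-held-out splits (`chromosome_split()`: validation chr4+chr21,
test chr5+chr22) prevent position memorization.

### Desk-scale recipe

The test suite trains a reduced model chosen to fit a CPU-minute budget:
embed 64, 2 heads, 2 blocks, feed-forward 128, 112-CpG cap, lr 1e-3,
warmup 20, batch 128, ≤ 10 epochs, on a 2,500-read subsample of the
default synthetic biopsy. These are *our* desk-scale training choices, not
tuned properties of the data generator; the simulator's defaults are fixed
study conditions. This recipe reaches held-out-chromosome test AUC ≈ 0.997
in about five minutes on one CPU.

## 5. XGBoost baseline

`extract_gbt_features()` reduces each read to 38 + K fixed values: 19
percentiles of its own methylation, K Pearson correlations against the
atlas cell types, and 19 percentiles of per-CpG sample ranks.
`sweep_and_train()` sweeps the 320-point grid (depth {5,7,9,11}, eta 0.01,
subsample {0.25,0.5,0.6,0.8,1}, min child weight {3,5,10,25}, column
subsample {0.25,0.5,0.75,1}; 15,000 rounds with early stopping on a 10%
holdout) or a seeded subset, and keeps the best validation-AUC model.

## 6. Counterfactual perturbation

`perturb_batch()` freezes the model and optimizes one delta per CpG per
read toward the inverted prediction, minimizing

* binary cross-entropy toward the flipped label, plus
* `gamma/N` times the clipping penalty `ReLU(-x̃) + ReLU(x̃ - 1)`, plus
* `lambda(t)/N` times the smooth-L0 penalty `δ²/(δ² + ε(t)²)`,

with `ε` annealed 0.5 → 0.01 and `λ` ramped 0 → λ_max after 25 free steps
(defaults: 1000 Adam steps, lr 0.01). Deltas below 0.1 in magnitude are
zeroed post hoc; a read converts when it crosses from one confidence
region (p ≤ 0.2 or p ≥ 0.8) to the other. `clustering_coefficient()`
scores the spatial clustering of perturbed CpGs against a permutation
null, and `cell_type_concordance()` asks whether perturbations move marker
CpGs toward specific cell-type profiles.

## 7. Downstream analyses

* `observed_vs_expected()` compares per-segment fractions of tumor-called
  reads (p ≥ 0.5) with
  `expected_tumor_fraction(rho, n_total, n_normal)`.
* `build_rescue_cohort()` + `compare_cohorts()` test whether short-read
  SNV candidates that are invisible to the long-read caller are supported
  by tumor-origin reads: candidates need ≥ 10 supporting tumor-biopsy
  reads, zero supporting adjacent-normal reads, and > 100 bp distance from
  any long-read PASS call; short-read PASS candidates (test cohort) are
  compared with rejected candidates (control) by a two-sided Mann–Whitney
  test on per-variant tumor-called proportions.
* `flag_suspect_somatic_calls()` flags long-read PASS calls whose
  supporting reads average a low tumor probability.

## 8. Synthetic biopsies

`simulate_biopsy()` generates a bulk biopsy with known per-read origins:
a small multi-chromosome genome with a fixed CpG grid, 13 copy-number
segments (including LOH), beta-distributed site methylation propensities
with tumor-shifted and cell-type-specific sites, purity-weighted read
sampling with haplotypes and phase blocks, clonal/subclonal SNVs placed on
haplotypes with realistic multiplicities, caller noise, sequencing errors
on variant observations, a partially missing atlas, and an adjacent-normal
read set. Planted rescue candidates come in two flavors: `rescue_true`
variants behave like clonal tumor SNVs, while `artifact` variants model
biopsy-specific artifacts carried only by the tumor biopsy's non-tumor
reads and never by matched-normal reads (so both cohorts pass the
zero-normal-support filter, as in the real pipeline). Reads and calls
round-trip through standard formats (SAM, VCF,
TSV) via `write_biopsy()`/`load_reads()`. Simulator defaults are study
conditions and are never adjusted to make tests pass; experiments vary
only documented experiment-level knobs (seeds, read counts, planted rescue
variants).
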