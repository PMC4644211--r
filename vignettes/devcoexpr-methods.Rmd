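---
title: "Stage-resolved co-expression analysis: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-resolved co-expression analysis: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devcoexpr)
```

devcoexpr analyses how gene–gene co-expression in a developmental brain
atlas changes across developmental stages. This vignette is the package's
own account of the statistical procedure, the parameters that matter, the
synthetic data used for validation, and the design decisions that were
genuinely open.

## The data model

An `ExpressionAtlas` is a dense genes × samples matrix with per-sample
metadata. A *sample* is one brain region of one donor; a donor contributes
up to 16 regions (5 subcortical/cerebellar structures plus 11 neocortical
areas). Donor age lives on one signed axis, days relative to birth with
birth at 40 post-conception weeks, so prenatal ages are negative; this one
scale drives both nearest-neighbour imputation and stage assignment. Donors
are grouped into 7 developmental stages (early fetal through adulthood) by a
half-open interval map `[lo, hi)` that ships as an editable default
(`default_stage_map()`) rather than hard-coded truth, because published
stage boundaries are conventions that vary between releases. A `scale` flag
(`rpkm` → `quantile_norm` → `log2`) makes each preprocessing step check it
receives what it expects — the pipeline order is part of the contract.

## Preprocessing

The steps run in a fixed order:

1. **Donor exclusion.** A donor missing strictly more than
   `max_missing_regions` (default 6) of the 16 required regions is dropped;
   a donor missing exactly 6 is kept.
2. **Imputation.** Each remaining missing donor–region sample is copied from
   the donor with minimal |age difference| among donors observed for that
   region; ties go to the younger donor, a deterministic and
   developmental-biology-friendly choice (expression changes fastest early,
   so the younger neighbour is the more conservative template). Imputed
   columns are flagged; observed values are never touched.
3. **Expression filter.** A gene is kept iff its maximum over samples is
   ≥ `min_rpkm` (default 5 RPKM) — genes never reaching the floor are
   treated as quantification noise. Filtering precedes normalization so the
   quantile reference is not distorted by all-zero rows.
4. **Quantile normalization** across samples (classic rank-wise reference
   means; ties receive the mean of the reference values at the tied ranks,
   via `limma::normalizeQuantiles(ties = TRUE)`). For continuous data every
   sample ends with the identical sorted value vector, exactly, and the
   operation is idempotent.
5. **log2(x + offset)** with offset 1 (configurable), since normalized RPKM
   can be 0.
6. **Stage assignment** from donor age.

## Trajectories and temporal modules

For each donor the Spearman correlation of a gene pair is computed across
that donor's 16 regions; the stage value is the arithmetic mean over the
stage's donors. The arithmetic mean (not a Fisher-z average) is used
deliberately: with only 16 regions per donor, per-donor correlations are
noisy, and the mean of raw correlations is the plain summary that the
downstream thresholding is calibrated against. Spearman rather than Pearson
focuses the statistic on the *shape* of regional expression, not its
absolute level.

If either gene is constant across a donor's regions, its rank correlation is
undefined; that donor is skipped for the affected pairs and the divisor
(`n_donors_used`) shrinks. An undefined correlation is never silently
treated as 0 — if every donor of a stage is skipped, the trajectory entry
is missing. Pairs survive to module analysis iff their trajectory exceeds
|ρ| > 0.8 *strictly* at some stage.

Surviving trajectories are clustered with complete linkage on Euclidean
distance and the dendrogram cut to exactly `k` flat modules, `k = 3` by
default. The original cut was guided by visual heatmap inspection, which is
not automatable; fixing `k` trades that judgment for reproducibility, and
`k` is a first-class config parameter. Missing trajectory entries are
imputed to the pair's own mean over its defined stages before the distance
is computed (logged; the alternative of dropping such pairs is available by
filtering first). Clustering is deterministic given input order.

## Transcriptome-wide modules and hubs

All expressed genes are clustered on d = 1 − ρ (Spearman over all 480
samples, complete linkage, cut at `k = 32` by default). The *signed*
transform is the default because modules are interpreted through coherent
average expression profiles, which anticorrelated genes would break;
`one_minus_abs_rho` is available. Constant genes are excluded with a
warning. At full atlas scale (~13.5k genes) the gene × gene correlation is
the memory bottleneck; the package computes it directly at the scales used
here (tests run at ≤ 500 genes) and the correlation step is isolated behind
`gene_cor_matrix()` so a blocked implementation can be swapped in without
touching the clustering contract.

Module graphs connect genes whose Spearman correlation over all samples is
≥ 0.9 (signed, per the convention above; configurable to absolute). Hub
ranking is by degree, descending, alphabetical within ties; all genes tied
at the boundary of the requested top-n are included and flagged rather than
truncated arbitrarily. Degree on the thresholded graph (not the weighted
graph) is used: it is the quantity the graph visualisation conventions this
follows actually display.

## Enrichment and the permutation null

Over-representation uses the hypergeometric *upper tail* P(X ≥ k). (Testing
with the point probability alone would be statistically incoherent for
enrichment; the pmf is nevertheless available behind `mode = "pmf"`.) The
universe is the clustered gene set, and BH-FDR is applied within each query
across modules — matching how results are grouped per figure family — with
a global option. The default significance level is FDR-adjusted p < 0.001.

The pair-survival permutation test draws R random gene sets of the query's
size uniformly from the atlas genes and counts surviving pairs per set. The
empirical p uses the add-one estimator (1 + b)/(1 + R), which is never 0; a
"p < 1/R" claim corresponds to b = 0. The default R = 10,000 matches the
headline analysis; tests and the acceptance script use R = 200, where the
planted-query result (b = 0, p = 1/201) is already unambiguous.

## The synthetic atlas generator

`simulate_atlas()` is first-class, tested code, not a fixture. It emulates
the study geometry — 30 donors allocated (5, 5, 4, 4, 4, 4, 4) across 7
stages, ages uniform within stage intervals, 16 regions, ~5% of
donor–region samples masked (capped at 6 per donor) — and plants three
kinds of structure on the log2 scale before exponentiating to RPKM-like
values:

* **Pair modules** share a per-donor regional latent factor f ~ N(0, 1)
  (one value per region, redrawn per donor) with a stage-scheduled loading
  λ_s = 0.1·√(ρ_s/(1 − ρ_s)). At the reference noise level (the default
  `noise_sd = 0.1`) the expected member-pair Pearson correlation across
  regions is exactly ρ_s; Spearman sits marginally below. The calibration is
  anchored at the reference noise rather than the current `noise_sd` so that
  raising the noise dial degrades planted correlations monotonically, as
  real measurement noise would — both a target-hitting default and a
  noise-sensitivity axis cannot be had if loadings track the noise.
  Shapes: `prenatal_high` (ρ_target in the two prenatal stages, 0 after),
  `postnatal_high` (linear ramp 0 → ρ_target), `flat_noise`.
* **Expression modules** share a region profile (sd 0.037) plus stage
  profile (sd 0.15) plus a per-sample latent factor (sd 0.15), scaled by
  per-gene loadings U(0.85, 1.15); one optional hub gene loads at exactly 2.
  Member genes use a tighter noise level (0.06) than the transcriptome-wide
  default, reflecting that tightly co-regulated genes are less noisy than
  the transcriptome at large. Profile components are rescaled to their exact
  target sd so module strength does not swing with the luck of 7 or 16
  draws.
* **Background genes** are independent noise around their baseline.

One generator subtlety deserves record. Quantile normalization operates on
within-sample ranks, and at desk scale (400 genes) a large planted module
moving coherently drags the ranks of unrelated genes with it — strong
module amplitudes leaked ~0.3 of spurious Spearman correlation into
unplanted gene pairs in early designs. The frozen defaults keep module
amplitudes moderate (≈0.22 sd combined) so this rank-crossing leakage stays
well under the noise floor, while the tighter member noise keeps
within-module correlation above the 0.9 hub-edge threshold after
normalization. The effect shrinks with gene count and is negligible at real
atlas scale (13k+ genes, coherent fractions of a few percent) — which is
also the honest caveat about what passing synthetic tests show: they
validate the statistical machinery and its calibration, not the biology of
any particular atlas. The generator likewise omits negative-binomial count
noise, sex effects, and batch structure; trajectories on real data will be
noisier than their planted counterparts at matched nominal correlation.

`simulate_gene_sets()` derives a query list overlapping the planted pair
modules at a configurable fraction (default 0.8) plus background fillers,
and one marker list per expression module — the roles of a disease
candidate list and of neuron/astrocyte/oligodendrocyte marker panels.

## Numerical choices

* Strict inequalities where the procedure prescribes them: pair survival is
  |ρ| > 0.8, donor exclusion is "> 6 missing"; gene filtering is ≥ 5.
* Stage intervals are half-open `[lo, hi)`; an age equal to a boundary
  belongs to the interval starting there.
* Trajectory entries are clamped to [−1, 1] against floating-point
  excursions from the crossproduct formulation.
* `hclust` tie-breaks follow input order; all partition outputs are sorted
  deterministically before writing, and the end-to-end runner's manifest
  records MD5 hashes so bit-reproducibility is checkable.
* Empirical p values use add-one smoothing; hypergeometric tails come from
  `phyper`, exercised in tests against exhaustive subset enumeration to
  1e-12 for all universes up to N = 15.

## Problem sizes

The validation suite and the acceptance script run the full pipeline at 400
genes × 480 samples, the 455-gene pair-count identity at 455 genes, the
permutation null at R = 200, and clustering recovery at 100–400 genes —
sizes at which every planted property is decisively testable on one CPU in
seconds. All thresholds (0.8 survival, 0.9 hub edges, α = 0.001, k = 3 and
k = 32) are the analysis defaults and are configurable per run.

## Known limitations

* The imputation rule (age-nearest donor, tie to younger) is a declared
  stand-in for the original study's unavailable supplementary scheme.
* Fixed-k dendrogram cuts inherit the arbitrariness of the original visual
  cut; no automatic k selection (gap statistic, stability) is attempted.
* Quantile normalization with within-sample ties does not make sorted
  sample vectors exactly identical (tied ranks receive reference means);
  with continuous expression values this does not arise.
* GO-term enrichment against external term databases is out of scope; the
  over-representation machinery accepts any user-supplied gene-set
  collection (GMT) instead.
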