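---
title: "Methods: molecular subtyping of bronchial premalignant lesions"
author: "AirwaySubtypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: molecular subtyping of bronchial premalignant lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis in one paragraph

Bronchial premalignant lesions (PMLs) are the precursors of lung squamous
cell carcinoma, and their outcome is heterogeneous. `AirwaySubtypes`
implements a discovery pipeline for PML molecular subtypes from bulk
RNA-seq of endobronchial biopsies: co-expression modules are derived
independently in several related datasets (biopsies, matched airway
brushes, a tumor compendium, a carcinogen-exposed mouse model); biopsy
modules whose one-dimensional summaries (first principal components) are
strongly correlated with a module of every other dataset are kept as
*conserved* modules; biopsies are consensus-clustered over the conserved
genes to define subtypes; a small nearest-centroid marker panel classifies
new samples, and a sub-panel calls the Proliferative subtype from
normal-appearing brushes; finally per-sample module activity scores are
tested for association with lesion progression using a repeated-measures
model, because subjects contribute several biopsies.

## The generative model behind the simulator

Every stage is exercised on synthetic data from an additive factor model on
the log2 scale,

$$x_{gj} = \mu_g + \sum_m L_{gm} f_{mj} + \beta_g t_j + b_{g,B(j)} +
u_{S(j)} + \varepsilon_{gj}, \qquad \varepsilon_{gj} \sim N(0, \sigma^2),$$

with gene baselines $\mu_g \sim N(6, 1.5^2)$, module loadings $L_{gm} = L$
for the genes of module $m$ and zero otherwise, standardized RNA-quality
(TIN) slopes $\beta_g$, per-gene batch shifts $b$, an additive
gene-independent subject effect $u$, and unit-variance baseline factor
scores. Under neutral settings the within-module correlation is exactly
$L^2 / (L^2 + \sigma^2)$, which the tests verify by Monte-Carlo; the
defaults $L = 2, \sigma = 1$ put it at 0.8. The factor form was chosen
because every downstream statistic (eigengene, activity score, centroid
discriminant) is monotone in the factor scores, so recovery tests are
well-posed. The subject effect is a scalar per subject — the simplest
structure that makes the exchangeable within-subject correlation of the
association stage identifiable.

Four linked datasets share nine modules (loaded everywhere) and carry two
private modules each (loaded in one dataset only). Biopsy subtype labels
shift the shared-module factors by `subtypeEffect` (default 2 factor SDs)
in the directions of a 4-by-9 template (`subtypePattern()`): Proliferative
up in modules 4, 5, 7 and down in 6; Inflammatory up in 1, 2, 7, 8, down in
4, 5, 6; Secretory up in 6, 8, down in 1, 2, 5, 7; Normal-like up in 1, 6,
down in 8, 9. This template mirrors the directionality reported for the
published subtypes so the cluster-naming logic can be tested against a
known Proliferative analogue. Progression labels
(progressive/persistent : regressive : unknown = 1 : 1 : 2) depress module
9's factor by `progressionEffect = 1.5` SDs in progressive/persistent
biopsies. Matched brushes inherit half (`brushAttenuation = 0.5`) of the
mean subtype shift of their subject-and-procedure biopsies, emulating an
attenuated airway field-of-injury signal — this is what produces the
specific-but-insensitive brush classifier regime.

Default sizes (160 biopsies from 40 subjects, 80 brushes, 120 tumor-like
and 40 mouse-like samples; 800 genes, module size 40) are a desk-scale
rendition of the motivating study's shape; they keep a full pipeline run
under half a minute while leaving every recovery question non-trivial.
What the simulator does **not** emulate: count-level sampling in the main
pipeline (a negative-binomial count layer exists separately to exercise
TMM normalization), gene-gene correlation beyond module structure,
library-composition artifacts, cross-species ortholog ambiguity, and
histology-level label noise. Passing tests therefore demonstrate internal
correctness and recoverability under the factor model, not performance on
real cohorts.

Reproducibility: one master seed; each dataset draws from a substream whose
seed is derived deterministically from the master seed and the dataset
name, so regenerating a single dataset is stable. The brush substream
additionally reads the biopsy truth (it must know the subtype of the
matched biopsies).

## Preprocessing

Counts are TMM-normalized through edgeR (the reference implementation of
the trimmed mean of M-values): reference sample with upper-quartile CPM
closest to the mean upper quartile, 30%/5% trimming on M/A, precision
weights, factors rescaled to geometric mean one, log2-CPM with prior
count 2 on effective library sizes. Genes with zero interquartile range or
row sum at or below one are dropped; the filter is applied to the
normalized matrix by default (the processing order in the source protocol
is ambiguous on this point; a count-scale application is available by
filtering before normalization). Sample QC computes three criteria in one
pass on the full candidate set — mean inter-sample correlation, the first
two principal components (gene-centered, samples as observations), and
TIN — and excludes a sample only when more than one criterion exceeds |z|
\> 2; a single screening pass matches the protocol's one-shot description.
The sex check is an exact one-dimensional 2-means split (all thresholds
scanned) of mean Y-gene expression. Nuisance covariates (TIN, batch) are
removed by per-gene least squares before network construction.

## Module detection

The network is unsigned, $a_{ij} = |r_{ij}|^\beta$ with Pearson
correlation. The soft power is the smallest candidate whose connectivity
distribution reaches a signed scale-free fit of 0.8, with two safeguards
that matter in practice: candidates whose mean connectivity falls below 2
are ineligible (a near-disconnected network looks spuriously scale-free),
and when no candidate reaches the target the selection falls back to the
sample-size default (6 for n ≥ 40 samples, up to 9 below 20) rather than
chasing the fit maximum — block-structured expression is simply not
scale-free, and on planted-module data the fit maximum otherwise drifts to
degenerate powers of 14–20 that destroy recovery.

Topological overlap follows the standard formula; genes are clustered by
average linkage on 1 − TOM. The tree is cut by (i) a static cut placed
just below the top plateau of merge heights (maximum height minus 3% of
the height range) — cross-module and featureless joins concentrate under
the maximum, and a plateau-relative cut is robust whether or not noise
genes are present, unlike a fixed merge-height quantile; (ii) recursive
descent splitting of any branch whose joining height exceeds its mean
internal merge height by more than 0.15 (chained average-linkage merges
can hide several modules under one low join); (iii) a branch-quality rule
requiring at least 0.05 clearance between a branch's mean internal height
and the cut, which is what makes pure-noise trees return zero modules;
and (iv) a core trim dropping genes whose mean within-branch dissimilarity
lies past the midpoint between the branch median and the cut. Modules
below 30 genes are unassigned; modules whose eigengenes correlate above
0.75 are merged iteratively. Eigengenes are unit-variance first principal
components of the z-scored member genes, sign-aligned with the mean module
profile.

## Conservation screening

All modules from all datasets form a compendium of gene sets; each set is
summarized in each dataset by the PC1 of its member genes present there
(undefined when fewer than two are present). Within each dataset the
absolute Pearson correlations between all PC1 pairs are binarized strictly
at 0.85 — a correlation exactly at the threshold contributes zero — and
the binary matrices are summed. A biopsy module is retained only if some
single non-biopsy set exceeds the threshold in *every* dataset (summed
entry equal to the dataset count); the looser reading in which each
dataset may contribute a different partner is available as an option. The
operational description of the summed-matrix construction supports the
same-partner rule, which is also the stricter and therefore safer
screening choice. Retained modules keep only genes present in at least one
partner set.

## Subtype discovery

Consensus clustering subsamples 80% of the biopsies 1000 times (250 in the
test suite, a scale-down that leaves the consensus estimates' standard
error around 0.03), partitions each subsample around medoids (PAM,
deterministic BUILD + SWAP) on 1 − Pearson distance, and averages
co-clustering over co-sampling. The full distance matrix is computed once
and subset per iteration; the only stochasticity is the subsampling
stream, which is seeded. For the number of clusters, A(k) is the area
under the empirical CDF of the consensus entries and Δ(k) its relative
change. The selection rule is: the largest k with Δ(k) ≥ 0.05 **and**
proportion of ambiguous clustering PAC(k) ≤ 0.1 (entries strictly between
0.1 and 0.9). The ambiguity guard is essential: beyond the true cluster
number, PAM must split a genuine cluster, and that split still inflates
the CDF area by roughly 20% relative — a Δ-only rule therefore
systematically overshoots (it picks 3 on clean two-subtype data), while
splits of genuine clusters are unstable under subsampling and are exactly
what PAC detects. Final assignments cut an average-linkage tree of
1 − consensus at the chosen k. Clusters are named by matching the signs of
their significant (FDR < 0.05, repeated-measures one-vs-rest) module-score
shifts against the expected direction template; ambiguous matches are
reported, never silently broken. In simulation mode the pipeline numbers
the conserved modules by best-Jaccard match to the planted modules before
applying the template — the published analysis numbered its modules
manually in the same spirit.

## Classifier

For the marker panel, each conserved-module gene is kept only if its
highest squared correlation among all module eigengenes is to its own
module; the panel slots (22 by default) are divided inversely to each
module's mean retained r² — tightly co-regulated modules are summarized by
fewer markers — using largest-remainder rounding with a floor of one
marker per module (the floor keeps every module's direction observable;
the rounding rule is the standard apportionment choice and is fuzz-tested
to always fill the panel exactly). Within a module the top-r² genes are
taken. The classifier is a nearest-centroid model at zero shrinkage:
z-scored panel expression, class-mean centroids, pooled within-class SD
per gene (floored at 1e-6 with a warning), class-frequency priors, and the
discriminant $\sum_g (x_g - c_{gk})^2 / s_g^2 - 2\log \pi_k$; ties break
deterministically by class order and are flagged. For prediction the
training and test cohorts are combined, batch-adjusted by parametric
empirical-Bayes ComBat when more than one cohort is present, z-scored
jointly, and the centroid statistics re-estimated on the renormalized
training half — so a test set identical to the training set reproduces the
resubstitution confusion exactly. Adjustment before z-scoring follows the
natural reading of "adjusted and z-score normalized"; the EB shrinkage
leaves a few percent of any pure cohort shift as gene-level residual,
which is inherent to the parametric procedure and documented in the tests.
The presence classifier collapses the labels to Proliferative versus rest
and retrains on the panel genes of modules 4–7; brushes are scored against
the biopsies sharing their subject and procedure, positive if any matched
biopsy is Proliferative.

## Module scores and progression

Per-sample module activity uses the kernel-rank random-walk statistic:
Gaussian-kernel CDF estimates per gene (bandwidth sd/4), symmetric rank
weights |p/2 − rank|, a weighted Kolmogorov–Smirnov walk with tau = 1, and
the max-positive-plus-min-negative score combination (the method's default
combination rule; the one-sided alternative is a parameter away). Sets
with fewer than two present genes are marked undefined rather than scored
zero.

Association of scores with progression (and of clusters with module
directions) uses a consensus-correlation generalized-least-squares model:
for each response the exchangeable within-subject correlation is
REML-profiled on a grid (−0.2 to 0.9 in steps of 0.02, quadratically
refined around the maximum), the per-response estimates are combined as
tanh(mean(atanh ρ)), and all responses are refit by GLS at the consensus
value, with ordinary t-tests on the group coefficient and BH correction
across responses. This is a fully specified stand-in for the established
duplicate-correlation procedure; the tests verify agreement with it to
within 0.02 in the consensus correlation and 0.999 correlation of
t-statistics, exact reduction to OLS when every subject has one sample,
type-I error within [0.035, 0.065] at nominal 0.05 under a null with
ρ = 0.3, and unbiased recovery of a planted effect. The grid lower bound
respects positive-definiteness (ρ > −1/(m−1) for the largest subject block
m).

## Numerical choices and degenerate inputs

All correlations are Pearson. Zero-variance genes in the kernel CDF get a
bandwidth floor of 1e-8; singleton gene sets are undefined, not zero;
consensus pairs never co-sampled (possible only for tiny n) are zero with
a logged count; an exhaustive consensus mode enumerates every subsample
once so small instances can be checked against direct enumeration exactly.
Fisher tests are exact up to a table total of 500 and seeded Monte-Carlo
beyond. The exact 1-D 2-means scan makes the sex check deterministic.
Module labels are ordered by size; pipeline artifacts are plain TSV / GMT
/ JSON and byte-reproducible at a fixed master seed.

## Problem sizes in the test suite

The test and acceptance suites run the default study (800 genes, 400
samples across four datasets) for module recovery (20 seeds),
conservation selectivity (20 seeds), subtype recovery with 250 consensus
iterations (20 seeds), classifier and progression checks (5 seeds), and a
500-replicate calibration of the association model at 200 responses and
50 subjects × 3 samples. These sizes were chosen so the full suite
completes in minutes while every statistic retains enough resolution for
its acceptance band.

## Known limitations

Real-data headline numbers of the motivating study (its training accuracy,
brush sensitivity/specificity, progression AUC, module and gene counts)
depend on the deposited cohorts and are not reproduced here. The tree-cut
implementation is a documented plateau-cut-plus-descent variant, not a
port of the dynamic hybrid algorithm; on weak, strongly overlapping
modules it will under-split earlier than the hybrid method. ComBat
adjustment is approximate for location shifts (see above). Per-gene
differential expression with precision weights is out of scope — the
association surface is module-score level.
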