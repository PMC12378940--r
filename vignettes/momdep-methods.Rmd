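---
title: "Methods: multi-evidence metabolomics of depression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-evidence metabolomics of depression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

momdep implements a three-stream analysis of plasma metabolomics in
late-life depression and the rule system that merges the streams into a
tiered pathway classification. This vignette is the package's account of
the underlying methods: the models, their assumptions, the tunable
parameters, and the design choices made where the method description left
the design open.

## Study design being modelled

A community cohort of adults aged 65+ is screened (incomplete
questionnaire, antidepressant use, missing blood sample), depression status
is assigned by the 30-item Geriatric Depression Scale (GDS-30; score > 10 =
clinically significant depression), and cases are 1:1 frequency-matched to
controls on sex and age (±3 years). Plasma metabolite intensities for the
matched sample then feed three parallel evidence streams:

1. **Differential screen** — OPLS-DA with VIP scoring plus per-feature
   t-tests;
2. **Co-expression network** — WGCNA-style modules with module-membership
   (MM) and trait-significance (GS) hub screening;
3. **Mendelian randomization** — two-sample MR of metabolite GWAS
   summary statistics against a depression GWAS.

The three metabolite lists are merged (unweighted union on KEGG compound
IDs) into a high-confidence pool; pathways are scored by hypergeometric
enrichment and relative-betweenness impact; and each pathway is assigned a
Class I/II/III(/III*) tier.

## Cohort arithmetic

`score_gds()` uses the standard GDS-30 keying: 20 positively keyed items
(2–4, 6, 8, 10–14, 16–18, 20, 22–26, 28) score a point on "yes", the 10
remaining items on "no". The complement identity
`score(x) + score(flip(x)) = 30` is tested for every response vector.

`required_n_per_group()` uses the normal approximation
`n = ceiling(2 (z_{1-α/tails} + z_{power})² / d²)`. For d = 0.5, α = 0.05,
power = 0.80 this gives 50 per group one-tailed and 63 two-tailed. The
study this package models reports 49 per group from GPower under the same
inputs; neither a one- nor a two-tailed standard calculation reproduces 49,
so the function documents both conventions and does not force agreement.

Baseline tables use the pooled-variance t-test (the SPSS equal-variances
row; Welch available via a flag) and Pearson chi-square **without**
continuity correction. Counts reconstructed from printed percentages
(`round(pct/100 * n)`) with the uncorrected chi-square reproduce the
published baseline p-values (sex: 0.671; alcohol use: 0.133); with Yates
correction they do not. The reconstruction is lossy by nature and is
documented as such.

Exclusion screening applies the criteria in a fixed order (questionnaire →
antidepressant → blood sample); a participant failing several criteria is
counted once under the first. Matching is greedy on increasing absolute age
difference with seeded tie shuffling, which fixes the closest pairs first
and is deterministic given the seed.

## Differential screen

Intensities are normalized per sample by the mean of the retained internal
standards; an internal standard whose cross-sample relative standard
deviation exceeds 0.3 is excluded from the normalizer, and features may
additionally be filtered on their RSD across QC injections.

`fit_oplsda()` is a NIPALS orthogonal-PLS for a single binary response:
features are autoscaled (centred, unit variance — the convention under
which VIP > 1 is interpretable; Pareto scaling is deliberately not the
default), the class is coded 0/1 and centred, orthogonal components are
deflated first (one by default; configurable), and a single predictive
component is extracted. R²Y is the fraction of class variance explained;
Q² comes from stratified 7-fold cross-validated prediction residuals
(PRESS), folds seeded. The permutation test refits the model under
label permutation and reports `p = (1 + #{perm ≥ obs}) / (n_perm + 1)`,
which cannot reach zero; 200 permutations is the study convention.

VIP over the single predictive component satisfies `mean(VIP²) = 1`
exactly; this identity is asserted on every fit in the test suite. With
zero orthogonal components the fit reduces to one-component PLS1, and the
scores are checked against an independent closed-form oracle
(`w ∝ X'y`).

The screen accepts a feature when `VIP > 1.0` **and** the two-sided
pooled-variance t-test gives `p < 0.05`. The stricter `VIP > 1.5` variant
used at the results stage of the modelled study ships as
`preset = "strict"`. Fold changes are case/control means of normalized
intensities, zeros imputed as half the feature's smallest non-zero value;
no pseudo-count is used since intensities are positive by construction.

## Co-expression network

The network stream follows the WGCNA recipe on the feature-by-sample
matrix: keep the top 50% of features by variance, choose the smallest
soft-thresholding power β whose unsigned adjacency `|cor|^β` gives a
scale-free fit index ≥ 0.6 (signed R² of the log–log connectivity
regression; if no candidate reaches the target the best fit is used with a
warning), form the topological overlap matrix

TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij),

and cluster `1 − TOM` by average linkage. Pearson correlation and the
unsigned network are used throughout (the historical WGCNA defaults).

Full dynamic tree cutting is intentionally not re-implemented. The
original design called for a static cut at the 0.99 quantile of merge
heights, but on planted-block data with noise features the merge heights
pile up just below 1 and that quantile sits above the block-joining merges,
collapsing everything into one module. The cut used instead is the middle
of the **largest gap** between consecutive merge heights in the upper half
of the tree — the point where tight within-module joins end and
between-cluster joins begin. This recovers planted 15/15/15 partitions
exactly (adjusted Rand ≥ 0.9 is asserted in the tests); the quantile cut
remains available via `cut = "quantile"`. Clusters under 10 features go to
grey, and modules whose eigengenes satisfy `1 − cor < 0.25` are merged
iteratively.

Module eigengenes are first principal-component sample scores of the
standardized module submatrix, unit variance, sign-aligned to the module
mean profile. Hubs require `MM > 0.7`, `GS > 0.2`, both correlation
p-values (t transform of r) below 0.05, and a module whose eigengene–trait
correlation is itself significant. The trait is coded DD = 1, ND = 0.
LC-MS and GC-MS matrices are meant to be processed in separate runs and
their hub lists unioned.

## Mendelian randomization

Instruments require exposure `p < 1e-5` and `F = (β/se)² > 10` (the usual
single-SNP approximation to the F statistic). Greedy LD clumping visits
SNPs by ascending p (ties by SNP ID) and keeps a SNP only if `r² < 0.001`
with every kept SNP within a 10,000 kb window; the LD source is a
user-supplied or synthetic r matrix, never a downloaded reference panel.
Harmonization aligns outcome effects to the exposure effect allele,
resolves palindromic SNPs by allele frequency outside the (0.42, 0.58)
ambiguity window and drops them inside it, and removes SNPs whose outcome
association is stronger than the exposure threshold (instruments must not
be outcome loci). Steiger filtering keeps SNPs explaining strictly more
variance in exposure than outcome, `r² ≈ F/(F + n − 2)` per trait.

Estimators: IVW (ratio meta-analysis ≡ weighted least squares through the
origin; multiplicative random effects by default, inflating the fixed
standard error by `sqrt(max(1, Q/(k−1)))`), MR-Egger (weighted regression
with intercept after orienting exposure betas positive; the intercept is
the pleiotropy test), the weighted median (cumulative-weight interpolation
at 0.5, delta-method weights, parametric bootstrap SE), and the simple mode
(kernel density mode of the Wald ratios, bandwidth 1 × the normal-reference
rule). Sensitivity: Cochran's Q with χ² p, leave-one-out IVW, and a
seeded global outlier test comparing the observed weighted residual sum of
squares against simulations under the no-outlier model — reported as
`presso_global` because it implements only the global-test idea of
MR-PRESSO, not its distortion test.

Two consequences of these rules are worth noting. First, at the modelled
outcome GWAS size (≈half a million participants), any exposure with a
strong causal effect produces genome-wide-significant mediated outcome
associations, so the outcome-exclusion rule removes all its instruments;
estimator calibration is therefore assessed with the exclusion disabled,
and the demonstration pipeline simulates a 20,000-sample outcome GWAS.
Second, MR-Egger's intercept is nearly collinear with its slope when all
oriented exposure effects are bounded away from zero (instrument F ≥ 10
guarantees this), so its power against 30% directional pleiotropy is low
at a few dozen instruments; the pleiotropy-detection scenario in the test
suite uses 200 instruments with direct effects of mean 0.1 and SD 0.02,
sized analytically so the intercept z-statistic is ≈2.6, and the planted
direct effects are defined relative to the exposure-increasing allele
(with arbitrary allele orientation, "directional" pleiotropy would be
balanced by construction and undetectable by any method).

## Pathways and tiers

Enrichment is the one-sided hypergeometric upper tail over the pathway
database universe (all compounds of the loaded database, MetaboAnalyst
style; a measured-compound universe can be supplied), BH-corrected across
pathways. Pathway impact is the summed relative betweenness centrality of
the hit nodes divided by the total centrality of the pathway graph —
betweenness, not degree, to match the convention the modelled impact
values imply; graphs are undirected and unweighted, and a graph with zero
total centrality has impact 0.

The evidence pool is the unweighted union of the three KEGG-matched lists
with provenance flags; unmatched names are reported, never silently
dropped. Per pathway and stream, the trend is "up"/"down" when every hit
with a known direction agrees, "mixed" when both occur, "absent" when none
is known.

The tier classifier applies, in order:

* **R0** — any stream internally mixed → III* (the "paradoxical" label);
* **R1** — impact ≥ 0.25, significant in ≥ 2 of the three methods, pool
  enriched, both stream trends known → I;
* **R2** — impact in [0.1, 0.25) and significant by LC/GC-MS or MR → II;
* **R3** — otherwise any p < 0.05 → III;
* **R4** — otherwise unclassified.

Three interpretive choices were genuinely open and are resolved as
follows, because each is the only reading consistent with the published
12-pathway worked example bundled in `inst/extdata/`:
trend consistency is judged **within** each stream, not between streams
(Class I rows carry an up LC/GC-MS arrow with a down MR arrow); mixed
trends dominate everything, including an impact of 0.33; and an absent MR
direction blocks Class I but not Class II. The overlapping impact boundary
in the source criteria (Class I "≥ 0.25" vs Class II "0.1–0.25") is made
half-open so the tiers partition. The classifier reproduces the bundled
reference's level column 12/12; `scripts/acceptance.R` recomputes this.

The rule system is deliberately not monotone in impact for single-method
pathways: one significant method at impact 0.2 is Class II, but at 0.3 it
fails Class I's two-method requirement and falls to Class III. The
monotonicity property test therefore covers the multi-method case only.

## Synthetic data: what it emulates, and what it does not

The generator produces log-normal intensities (Gaussian on the log scale —
internal-standard normalization implies multiplicative noise, the standard
assumption for MS peak areas), with two planted structures: differential
features shifted by a standardized effect in the case group, and correlated
blocks built from a one-factor model `x = sqrt(r)·f + sqrt(1−r)·ε`, whose
population within-block correlation is exactly `r` (verified empirically to
±0.05 at n = 1000). GWAS pairs draw instrument F statistics uniformly over
10–200 (2–30 under the weak-instrument flag), outcome betas as
`causal·β_exp + pleiotropy + noise` at the reported SE, and block-diagonal
AR(1) LD so clumping has a known answer. Toy pathway databases use
path/star/random-tree graphs with KEGG-style `C#####` IDs.

All randomness flows from one master seed through a fixed per-stream
offset scheme, so every output is byte-identical under a repeated seed.

What the generator does **not** emulate: raw spectra, retention times,
adducts, missing-not-at-random intensities, batch effects, genotype-level
data, or real KEGG topology. Passing tests therefore demonstrate that the
statistical machinery recovers planted structure under clean assumptions —
not that the pipeline is robust to the artefacts of real LC/GC-MS data.
The published impact values bundled in the reference fixture depend on real
KEGG graph content and are consumed as *inputs* to the classifier, never
recomputed from the toy database.

## Problem sizes and determinism

The demonstration pipeline (`run_pipeline()`) defaults to the modelled
study's shape — 49 samples per group, 1,458 features, a 379-participant
roster screening to 368 and matching to 98 — with three simulated GWAS
exposures and a 12-pathway toy database. The test suite exercises the same
code at reduced sizes (tens of features, 20–100 samples, ≤ 200 SNPs) with
brute-force oracles on instances small enough to enumerate: exhaustive
shortest-path betweenness at ≤ 12 nodes, double-loop TOM at ≤ 30 nodes,
exact hypergeometric enumeration at N ≤ 25, and 50-replicate IVW
calibration. Every stochastic test fixes its seed; the pipeline manifest
records MD5 hashes of all outputs and is identical across runs with the
same configuration and seed.
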