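# momdep

A multi-omics metabolomics pipeline for late-life depression, built for
analysts who want the full chain — cohort screening, differential
metabolite detection, co-expression modules, Mendelian randomization,
pathway scoring, and multi-evidence pathway tiering — as tested, reusable,
offline-runnable R functions rather than a one-off script stack.

## What it computes

Three evidence streams over a plasma metabolite matrix of depressed (DD)
and non-depressed (ND) older adults:

1. **Differential screen** — OPLS-DA (NIPALS, one predictive + orthogonal
   components, autoscaled) with permutation validation; a feature is kept
   when VIP > 1.0 and the two-sided t-test gives p < 0.05, where VIP
   satisfies mean(VIP²) = 1 over features.
2. **Co-expression network** — WGCNA-style: unsigned adjacency |cor|^β
   with β chosen by scale-free fit R² ≥ 0.6, topological overlap
   TOM_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i,k_j) + 1 − a_ij), average-linkage
   modules (min size 10, eigengene merge at 0.25), hubs at MM > 0.7,
   GS > 0.2, p < 0.05.
3. **Two-sample MR** — instruments at p < 1e-5 and F > 10, LD clumping
   (r² < 0.001 in 10,000 kb), harmonization, Steiger filtering, then IVW
   β = Σ β_X β_Y / se_Y² ÷ Σ β_X²/se_Y² with MR-Egger, weighted-median,
   simple-mode, Cochran's Q, leave-one-out and a global outlier test.

The streams merge into a high-confidence metabolite pool (unweighted union
on KEGG IDs); pathways get a hypergeometric enrichment p and a
relative-betweenness impact (Σ centrality of hit nodes / Σ all nodes); and
each pathway is assigned a tier:

* **Class I** — impact ≥ 0.25, significant in ≥ 2 methods, pool-enriched,
  consistent within-stream trends;
* **Class II** — impact in [0.1, 0.25), significant by LC/GC-MS or MR;
* **Class III** — otherwise significant (p < 0.05);
* **Class III\*** — internally contradictory metabolite trends, whatever
  the impact.

A synthetic-data module generates every input (abundances with planted
differential features and correlated blocks, GWAS pairs with a planted
causal effect and LD, toy pathway graphs, a screening roster) with known
ground truth, so the whole pipeline runs and is tested without any
download.

## Worked example: tier classification

The package bundles a reference set of 12 depression-associated metabolic
pathways with published impact scores, p-values, per-stream trends and
expected tiers:

```r
library(momdep)
ref <- load_tier_reference()
out <- classify_tiers(ref)
out[, c("pathway", "impact", "tier")]
```

```
   pathway                                     impact tier
1  Glycine, serine and threonine metabolism    0.29   I
2  Cysteine and methionine metabolism          0.30   I
3  Alanine, aspartate and glutamate metabolism 0.20   II
4  Glycerophospholipid metabolism              0.22   II
5  Purine metabolism                           0.21   II
6  Glutathione metabolism                      0.04   III
7  One carbon pool by folate                   0.06   III
8  Butanoate metabolism                        0.00   III
9  Sphingolipid metabolism                     0.06   III
10 Arginine and proline metabolism             0.07   III
11 alpha-Linolenic acid metabolism             0.33   III*
12 Glyoxylate and dicarboxylate metabolism     0.09   III*
```

All 12 assigned tiers match the published levels. Note the two III\* rows:
alpha-linolenic acid metabolism has the *highest* impact of the table
(0.33) yet lands in the paradoxical class because its hits move in
opposite directions — the mixed-trend rule dominates impact.

## Worked example: end-to-end on synthetic data

```r
cfg <- pipeline_config(seed = 7, n_per_group = 20, n_features = 150,
                       n_diff = 25, block_sizes = c(20L, 15L), n_perm = 50L,
                       min_module = 8L, out_dir = tempfile())
res <- run_pipeline(cfg)
```

```
[momdep] simulated 150 features x 40 samples, 12 pathways
[momdep] roster 379 -> eligible 368 (excluded: questionnaire 8, antidepressant 2, blood_sample 1)
[momdep] matched 49 case-control pairs (98 participants)
[momdep] OPLS-DA R2Y 0.916 Q2 0.238; 10/150 features pass the screen
[momdep] network beta 5; 2 modules; 0 hub features
[momdep] MR: 2/3 exposures causal at p<0.05
[momdep] evidence pool: 11 compounds
[momdep] tiers: III=1, III*=1
```

The log mirrors the auditable cohort flow (379 recruited → 368 eligible →
98 matched), then reports each stage's yield: the OPLS-DA fit quality, how
many features pass the VIP/p screen, the chosen soft threshold and module
count, how many simulated exposures come out causal, the pooled evidence
size, and the final tier table. Every output lands as a TSV in
`cfg$out_dir` beside a `manifest.json` of config, counts and MD5 hashes;
re-running with the same seed reproduces the hashes byte-for-byte.

## Layout

* `R/synthetic_data.R` — generators with ground truth (+ roster)
* `R/cohort.R` — GDS-30 scoring, exclusions, matching, power, baselines
* `R/metabolomics_stats.R` — normalization, OPLS-DA, VIP, screen
* `R/coexpression.R` — soft threshold, TOM, modules, eigengenes, hubs
* `R/mr.R` — instruments, clumping, harmonization, estimators, sensitivity
* `R/pathways.R` — GMT/graph IO, KEGG matching, enrichment, impact
* `R/integration.R` — evidence pool, trends, tier classifier
* `R/pipeline.R` — configuration, validation, orchestration, manifest

See `vignettes/momdep-methods.Rmd` for the models, assumptions, parameter
defaults and design decisions, including what the synthetic data does and
does not emulate.
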