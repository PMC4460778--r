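---
title: "Methods: transnosological coexpression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transnosological coexpression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the model

Several neurodegenerative and psychiatric disorders overlap clinically,
and treatments are often used across diagnostic boundaries.  `transcoex`
asks the corresponding molecular question: which *groups of genes* are
coexpressed in one or several brain diseases but not in controls (gain of
coexpression), or in controls but not in disease (loss)?  The unit of
analysis is therefore not a gene but a **bicluster**: a gene set G and a
sample set S such that the mean over all unordered gene pairs of the
Pearson correlation across S — the *average PCC* — is at least a
threshold.  Coexpression differences are scored per refined gene set as

Δ = avg PCC(G, disease samples) − avg PCC(G, control samples),

and calibrated against a permutation null of random gene groups of the
same size over the same disease samples.

Assumptions worth stating explicitly: correlations are computed on
batch-adjusted, quantile-normalized intensities and are linear (Pearson);
a disease "carries" a gene set only when the bicluster contains *every*
sample of that disease class, which treats classes as homogeneous; and
the null distribution conditions on set size and disease combination but
not on gene-specific variance structure.

## Stage parameters

| Parameter | Default | Why |
|---|---|---|
| `pcc_threshold` | 0.7 | An arbitrary gene pair over an arbitrary sample subset reaches average PCC ≥ 0.7 only rarely; the search keeps every emitted block at or above it. |
| `max_genes` | 50 | Caps the gene direction so the search favors blocks spreading over many samples (and hence many diseases); samples are deliberately uncapped. |
| `min_genes`, `min_samples` | 2, 3 | Minimum dimensions for a meaningful pairwise correlation. |
| `seed_window` | 5 | Width of the within-sample rank windows used for identity seeding. |
| `cor_seed_alpha` | 1e-5 | Per-pair one-sided significance of the Fisher-z gate in correlation seeding; keeps chance seed pairs to a handful per cohort. |
| refinement `alpha` | 0.005 | BH-adjusted q-value cut for reporting a gain/loss set. |
| `n_draws` | 100,000 | Null draws per (size, combination); tests and the acceptance script scale this to 10,000–20,000 for runtime, which only coarsens the attainable minimum p (add-one estimator: 1/(n+1)). |
| enrichment `alpha` | 0.005 / 0.01 | Per-term reporting cut vs the softer cut used for the shared-vs-specific category comparison. |

## Seeding: why two mechanisms

The classic seed rule orders each sample's expression values, cuts the
ranking into `seed_window`-gene windows, and collects samples in which an
*identical* window recurs.  That rule is implemented and tested
(`sample_seed_clusters()`, `find_seeds()`), but it only has power when
gene baselines dominate within-gene variation, so that rankings are
stable across samples.  In a cohort whose informative structure is purely
correlational — which is exactly what the synthetic world below plants —
identical windows essentially never recur: gene-wise multiplicative batch
effects break even the ties of a noiseless module, and a window's
membership churns with every sample.  Measured on the default synthetic
cohort, zero windows recur across three or more samples.

`run_biclic()` therefore adds **correlation seeds** (`correlation_seeds()`,
`cor_seeds = TRUE`): within every class stratum with enough samples, gene
pairs whose stratum PCC exceeds both the bicluster threshold and the
Fisher-z critical value at `cor_seed_alpha` are linked, and connected
components of that graph become seeds over the stratum's samples.  The
z-gate adapts to stratum size — ten samples demand r ≳ 0.92, fifty-five
demand only the 0.7 floor — so small strata do not flood the search with
chance pairs.  Class strata are used as *candidate* sample groupings
only; expansion and optimization freely cross class boundaries, and the
downstream class-completeness rule is what ties results to diseases.

## Expansion, optimization, and the compatibility gate

From each seed, the gene direction and the sample direction are expanded
separately and greedily (best candidate first, lexicographic
tie-breaks), keeping the average PCC at or above threshold; the two
expansions span a search space from which single elements are removed —
genes preferentially, to retain samples — until the average first
reaches the threshold (`optimize_bicluster()`); spaces that stall below
threshold are discarded.

Gene expansion applies one extra rule: a candidate must itself have mean
correlation ≥ `pcc_threshold` with the current genes.  Without it the
constraint "average stays above 0.7" lets a strong module absorb roughly
20% unrelated genes before its average dips below the threshold (for a
perfect k-gene block, k(k−1)/((k+j)(k+j−1)) ≥ 0.7 allows j ≈ 0.195k),
which blurs every discovered module by construction.  The gate keeps
blocks interpretable as *mutually* coexpressed gene sets and does not
affect colinear growth or the 50-gene cap.

Sample expansion has no analogous gate: with few genes, samples that
happen to extend the pattern are accepted, so emitted biclusters —
especially 2-gene ones — can carry generous cherry-picked sample sets at
near-threshold correlation.  This is a property of the method, not a
defect; the refinement stage's class-completeness rule and permutation
test are what separate such blocks from disease biology.

## Refinement conventions

* Disease combination = the classes whose samples are *all* inside the
  bicluster; samples of partially covered classes (including partial
  controls) are trimmed away.
* Biclusters whose only complete class is the control class carry no
  disease combination under this scheme; they are counted and reported
  (`n_ctrl_only`) but not tested.  Loss of coexpression is captured by
  disease-complete sets with negative Δ.
* p-values use the add-one two-sided estimator
  p = (1 + #{|d| ≥ |Δ|}) / (n_draws + 1): both gain and loss are of
  interest, and p stays in (0, 1].
* Nulls are cached per (set size, combination) and their seeds are
  derived deterministically from the master seed and the cache key, so
  results are independent of evaluation order.
* BH correction is applied once, jointly over all tested sets.

## The synthetic world

`generate_dataset()` draws background genes as independent Gaussian noise
(sd `noise_sd` = 1) and each planted module as a unit-loading
single-factor model on its member-class samples, x = (f + ε)/√(1+σ²)
with σ solved from the requested correlation (expected pairwise
PCC = 1/(1+σ²)); values are rescaled to unit variance so module and
background genes share a scale.  Batch effects are per-(gene, batch):
an additive shift (sd 1, comparable to biological variance — typical of
cross-platform microarray merges) and a lognormal scale factor (log-sd
0.25).  The default layout reproduces the three-cohort brain study the
package emulates: 118 + 61 + 58 = 237 samples with the published
per-class counts.

What the generator deliberately does **not** emulate: gene-specific
baseline expression (real rankings are far more stable), probe-level
redundancy, platform intensity distributions, heavy-tailed noise, and
correlated background structure.  A green recovery test therefore
establishes that the pipeline finds class-restricted correlation
structure through realistic batch effects and its own preprocessing —
not that it reproduces any particular inventory of gene sets from real
cohorts, which also depends on annotation versions and unstated
implementation details of the original software.

## Numerical choices

* Un-logging uses base 2 by default (`unlog_transform(base = 2)`): the
  transformed dataset in the emulated study was log2-scaled, and the
  base is a parameter for other conventions.
* Quantile normalization delegates to `limma::normalizeQuantiles(ties =
  TRUE)`; ties receive the mean of the reference values at tied ranks.
* Zero-variance genes contribute 0 (not NA) to every pairwise
  correlation, so degenerate rows can never inflate a bicluster; in
  batch adjustment they are passed through unchanged with a warning.
* The batch adjustment is the parametric empirical-Bayes location/scale
  model without biological covariates (class labels are withheld from
  the batch model to avoid leakage).  Shrinkage implies a finite
  residual: a per-gene location shift is attenuated by the factor
  d/(t²n + d), not removed to machine precision, and adjusting data
  with *no* batch effect perturbs values by the shrunken estimation
  noise (≈ 0.5/√n RMS).  The implementation matches an independently
  written reference run to < 1e-6 on a frozen two-batch fixture.
* Gene order after merging is lexicographic; all rankings break ties
  lexicographically; one master seed derives per-stage and per-null
  seeds by stable key hashing.  End-to-end runs with equal config and
  seed are byte-identical.

## Known limitations

* Greedy expansion/trimming carries no optimality guarantee; on small
  random spaces the exhaustive optimum can retain more samples (the test
  suite logs such shortfalls rather than hiding them).
* The class-completeness rule is all-or-nothing: one outlying sample
  excludes its whole class from a set's combination.
* The permutation null draws gene groups uniformly, ignoring the
  selection step that produced the tested sets; tested sets selected for
  high disease-stratum correlation therefore get optimistic p-values,
  which is inherent to the emulated design and is why the joint BH
  correction and the class-completeness gate both matter.
* Pairwise disease counts use the inclusive reading (a set spanning
  three diseases contributes to all three pairs).
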